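#' Gene-set over-representation analysis
#'
#' One-sided hypergeometric (Fisher exact upper-tail) test of each gene set
#' against a query list within a finite universe, with Benjamini-Hochberg
#' correction across sets. The `ease` variant is the conservative EASE score:
#' the overlap is decremented by one before the tail probability is taken (an
#' overlap of one therefore scores p = 1).
#'
#' @param list_genes character vector of query genes; must be a subset of
#'   `universe`.
#' @param gene_sets named list of character vectors (e.g. from [read_gmt()]);
#'   each set is intersected with the universe before testing.
#' @param universe character vector of all assayed genes.
#' @param variant `"fisher"` (default) or `"ease"`.
#' @return tibble with columns `set_name`, `overlap`, `set_size`,
#'   `list_size`, `universe_size`, `p_value`, `q_value`, sorted by p.
#' @export
enrich <- function(list_genes, gene_sets, universe,
                   variant = c("fisher", "ease")) {
  variant <- match.arg(variant)
  universe <- unique(universe)
  if (length(universe) == 0) stop("enrich: empty universe")
  list_genes <- unique(list_genes)
  if (!all(list_genes %in% universe)) {
    stop("enrich: query list contains genes outside the universe")
  }
  n_u <- length(universe)
  n_l <- length(list_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(list_genes, s))
    kk <- if (variant == "ease") max(k - 1L, 0L) else k
    p <- phyper(kk - 1, length(s), n_u - length(s), n_l, lower.tail = FALSE)
    tibble::tibble(
      set_name = nm, overlap = k, set_size = length(s),
      list_size = n_l, universe_size = n_u, p_value = p
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      set_name = character(0), overlap = integer(0), set_size = integer(0),
      list_size = integer(0), universe_size = integer(0),
      p_value = numeric(0), q_value = numeric(0)
    ))
  }
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$set_name), , drop = FALSE]
}
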