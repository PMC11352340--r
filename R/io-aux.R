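#' Read a long-format FPKM expression table
#'
#' Expects a TSV with columns `gene`, `sample`, `role` (one of `T`, `N`, `C`)
#' and `fpkm`. Each gene must have exactly one tumor (`T`) and one matched
#' normal (`N`) measurement and at least two control-normal (`C`)
#' measurements. Returns one row per gene with `fpkm_c` kept as a list-column
#' of the individual control values (needed by [compute_significance()]) and
#' `fpkm_c_mean` their arithmetic mean. The p-value columns are `NA` on read
#' and are filled by [compute_significance()].
#'
#' @param path TSV file path.
#' @return an expression-profile tibble with columns `gene`, `fpkm_t`,
#'   `fpkm_n`, `fpkm_c` (list), `fpkm_c_mean`, `p_t_vs_n`, `p_n_vs_c`,
#'   `p_t_vs_c`.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(),
    sample = readr::col_character(),
    role = readr::col_character(),
    fpkm = readr::col_double()
  ))
  if (nrow(x) == 0) return(empty_expression_profiles())
  if (!all(x$role %in% c("T", "N", "C"))) {
    stop("expression table: role must be one of T, N, C")
  }
  if (any(is.na(x$fpkm) | x$fpkm < 0)) {
    stop("expression table: FPKM values must be present and >= 0")
  }
  if (anyDuplicated(paste(x$gene, x$sample)) > 0) {
    stop("expression table: duplicated (gene, sample) row")
  }
  build_expression_profiles(x)
}

build_expression_profiles <- function(x) {
  split_gene <- split(x, x$gene)
  rows <- lapply(split_gene, function(g) {
    n_t <- sum(g$role == "T"); n_n <- sum(g$role == "N"); n_c <- sum(g$role == "C")
    if (n_t != 1 || n_n != 1 || n_c < 2) {
      stop("expression table: gene ", g$gene[1],
           " must have one T, one N and >= 2 C samples (got ",
           n_t, "/", n_n, "/", n_c, ")")
    }
    cvals <- g$fpkm[g$role == "C"]
    tibble::tibble(
      gene = g$gene[1],
      fpkm_t = g$fpkm[g$role == "T"],
      fpkm_n = g$fpkm[g$role == "N"],
      fpkm_c = list(cvals),
      fpkm_c_mean = mean(cvals),
      p_t_vs_n = NA_real_, p_n_vs_c = NA_real_, p_t_vs_c = NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

empty_expression_profiles <- function() {
  tibble::tibble(
    gene = character(0), fpkm_t = numeric(0), fpkm_n = numeric(0),
    fpkm_c = list(), fpkm_c_mean = numeric(0),
    p_t_vs_n = numeric(0), p_n_vs_c = numeric(0), p_t_vs_c = numeric(0)
  )
}

#' Read a gene list (one symbol per line)
#'
#' Used for cancer-predisposition gene panels. Blank lines and lines starting
#' with `#` are ignored; symbols are returned as given (matching elsewhere is
#' case-insensitive).
#'
#' @param path text file path.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file path (one named, tab-separated gene set per line).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fgsea::gmtPathways(path)
}

#' Read a protein-interaction edge list
#'
#' A two- or three-column TSV (`gene_a`, `gene_b`, optional `label` carrying
#' the evidence provenance). Edges are undirected; duplicates and
#' orientation-swapped copies are collapsed and self-loops dropped.
#'
#' @param path TSV file path (header optional; detected by non-gene-like
#'   first row is not attempted — a header line `gene_a<TAB>gene_b[<TAB>label]`
#'   is recognized literally).
#' @return tibble with columns `gene_a`, `gene_b`, `label`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  has_header <- grepl("^gene_a\\t", first)
  x <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    names(x)[1:2] <- c("gene_a", "gene_b")
    if (ncol(x) >= 3) names(x)[3] <- "label"
  }
  if (ncol(x) < 3) x$label <- NA_character_
  normalize_edges(tibble::as_tibble(x[, c("gene_a", "gene_b", "label")]))
}

normalize_edges <- function(edges) {
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  out <- tibble::tibble(gene_a = a, gene_b = b, label = edges$label)
  out[!duplicated(paste(out$gene_a, out$gene_b)), , drop = FALSE]
}

#' Fusion candidate tables
#'
#' A fusion-candidate table has columns `gene5`, `gene3`,
#' `spanning_reads_tumor`, `spanning_reads_normal`. See
#' [filter_cancer_fusions()].
#'
#' @param gene5,gene3 5' and 3' partner gene symbols (`gene5 != gene3`).
#' @param spanning_reads_tumor,spanning_reads_normal spanning-read support in
#'   tumor and matched normal tissue (integer >= 0).
#' @return a tibble of fusion candidates.
#' @export
fusion_candidates <- function(gene5, gene3, spanning_reads_tumor,
                              spanning_reads_normal) {
  x <- tibble::tibble(
    gene5 = as.character(gene5), gene3 = as.character(gene3),
    spanning_reads_tumor = as.integer(spanning_reads_tumor),
    spanning_reads_normal = as.integer(spanning_reads_normal)
  )
  if (any(x$gene5 == x$gene3)) stop("fusion candidates: gene5 must differ from gene3")
  if (any(x$spanning_reads_tumor < 0 | x$spanning_reads_normal < 0)) {
    stop("fusion candidates: spanning read counts must be >= 0")
  }
  x
}
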