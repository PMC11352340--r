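#' Build the candidate-gene interaction network
#'
#' Induces the subgraph of a user-supplied protein-interaction edge list on
#' the cohort's candidate genes. Connected components of size >= 2 are the
#' reported "networks"; each is labeled with the set of cases whose candidate
#' genes it contains.
#'
#' @param candidates_by_case named list mapping case id to its candidate gene
#'   symbols.
#' @param edges edge tibble (`gene_a`, `gene_b`, `label`), e.g. from
#'   [read_edge_list()]; symmetrized and de-duplicated on input.
#' @return an object of class `candidate_network`: list with `nodes` (tibble
#'   `gene`, `cases` list-column), `edges` (induced edge tibble),
#'   `components` (list of tibbles, one per component of size >= 2, with the
#'   component's genes and owning case set).
#' @export
build_candidate_network <- function(candidates_by_case, edges) {
  edges <- normalize_edges(edges)
  genes <- unique(unlist(candidates_by_case, use.names = FALSE))
  case_of <- lapply(
    setNames(genes, genes),
    function(g) names(candidates_by_case)[vapply(candidates_by_case,
                                                 function(v) g %in% v, logical(1))]
  )
  induced <- edges[edges$gene_a %in% genes & edges$gene_b %in% genes, , drop = FALSE]
  graph <- igraph::graph_from_data_frame(
    induced[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = genes, stringsAsFactors = FALSE)
  )
  comp <- igraph::components(graph)
  comp_list <- list()
  for (ci in seq_len(comp$no)) {
    members <- sort(names(comp$membership)[comp$membership == ci])
    if (length(members) < 2) next
    comp_list[[length(comp_list) + 1]] <- tibble::tibble(
      genes = list(members),
      cases = list(sort(unique(unlist(case_of[members]))))
    )
  }
  structure(
    list(
      nodes = tibble::tibble(gene = genes, cases = unname(case_of[genes])),
      edges = induced,
      components = comp_list
    ),
    class = "candidate_network"
  )
}

#' Expand a candidate network with top-ranked interactors
#'
#' Adds up to `k` non-candidate neighbor genes from the full edge list,
#' ranked by their number of connections to the current network nodes, with
#' ties broken by total degree in the edge list and then by symbol order, and
#' recomputes the induced subgraph and its components. Added nodes carry an
#' empty case set. Adding nodes never disconnects an existing component.
#'
#' @param net a `candidate_network` from [build_candidate_network()].
#' @param edges the full edge tibble.
#' @param k maximum number of interactors to add (default 20).
#' @return an expanded `candidate_network`.
#' @export
expand_network <- function(net, edges, k = 20) {
  if (k < 0) stop("k must be >= 0")
  edges <- normalize_edges(edges)
  current <- net$nodes$gene
  if (k == 0) return(net)
  touching <- edges[edges$gene_a %in% current | edges$gene_b %in% current, ,
                    drop = FALSE]
  neigh <- c(touching$gene_a, touching$gene_b)
  neigh <- neigh[!neigh %in% current]
  if (length(neigh) == 0) return(net)
  conn <- sort(table(neigh), decreasing = TRUE)
  all_deg <- table(c(edges$gene_a, edges$gene_b))
  cand <- names(conn)
  ord <- order(-as.integer(conn),
               -as.integer(all_deg[cand]),
               cand)
  add <- head(cand[ord], k)
  genes <- c(current, add)
  induced <- edges[edges$gene_a %in% genes & edges$gene_b %in% genes, , drop = FALSE]
  case_of <- c(
    setNames(net$nodes$cases, net$nodes$gene),
    setNames(rep(list(character(0)), length(add)), add)
  )
  graph <- igraph::graph_from_data_frame(
    induced[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = genes, stringsAsFactors = FALSE)
  )
  comp <- igraph::components(graph)
  comp_list <- list()
  for (ci in seq_len(comp$no)) {
    members <- sort(names(comp$membership)[comp$membership == ci])
    if (length(members) < 2) next
    comp_list[[length(comp_list) + 1]] <- tibble::tibble(
      genes = list(members),
      cases = list(sort(unique(unlist(case_of[members]))))
    )
  }
  structure(
    list(
      nodes = tibble::tibble(gene = genes, cases = unname(case_of[genes])),
      edges = induced,
      components = comp_list
    ),
    class = "candidate_network"
  )
}

#' @export
print.candidate_network <- function(x, ...) {
  cat(sprintf("<candidate_network> %d nodes, %d edges, %d components (size >= 2)\n",
              nrow(x$nodes), nrow(x$edges), length(x$components)))
  for (comp in x$components) {
    cat("  -", paste(comp$genes[[1]], collapse = ", "),
        " [cases: ", paste(comp$cases[[1]], collapse = ", "), "]\n", sep = "")
  }
  invisible(x)
}

#' Export a candidate network
#'
#' Writes the induced edges as TSV and the components (gene and case sets)
#' as JSON.
#'
#' @param net a `candidate_network`.
#' @param edge_path,component_path output paths (either may be `NULL`).
#' @return invisibly, `NULL`.
#' @export
write_network <- function(net, edge_path = NULL, component_path = NULL) {
  if (!is.null(edge_path)) readr::write_tsv(net$edges, edge_path)
  if (!is.null(component_path)) {
    jsonlite::write_json(
      lapply(net$components, function(comp) {
        list(genes = comp$genes[[1]], cases = comp$cases[[1]])
      }),
      component_path, auto_unbox = FALSE
    )
  }
  invisible(NULL)
}
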