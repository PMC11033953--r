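#' Build the bipartite snoRNA-disease graph from selected pairs
#'
#' The graph covers all indexed nodes of the table (isolated nodes allowed)
#' and contains exactly the given pairs as edges. Adjacency is stored sparsely
#' together with neighbor sets and degrees for both families.
#'
#' @param table an [association_table()].
#' @param pairs pair-index vector into `table$pairs`; defaults to all pairs.
#' @return An object of class `sda_graph`: `N`, `M`, sparse `adj` (N x M),
#'   `deg_snorna`, `deg_disease`, neighbor lists `nbrs_of_snorna`,
#'   `nbrs_of_disease`, and the `edges` data frame.
#' @export
build_graph <- function(table, pairs = NULL) {
  stopifnot(inherits(table, "association_table"))
  idx <- pairs %||% seq_len(nrow(table$pairs))
  if (length(idx) > 0 &&
      (min(idx) < 1 || max(idx) > nrow(table$pairs)))
    stop("pair indices out of bounds")
  P <- table$pairs[idx, , drop = FALSE]
  adj <- Matrix::sparseMatrix(i = P$snorna_idx, j = P$disease_idx, x = 1,
                              dims = c(table$N, table$M))
  structure(
    list(
      N = table$N, M = table$M, adj = adj,
      deg_snorna = Matrix::rowSums(adj),
      deg_disease = Matrix::colSums(adj),
      nbrs_of_snorna = split(P$disease_idx,
                             factor(P$snorna_idx, levels = seq_len(table$N))),
      nbrs_of_disease = split(P$snorna_idx,
                              factor(P$disease_idx, levels = seq_len(table$M))),
      edges = data.frame(snorna_idx = P$snorna_idx, disease_idx = P$disease_idx)
    ),
    class = "sda_graph"
  )
}

#' @export
print.sda_graph <- function(x, ...) {
  cat(sprintf("sda_graph: %d snoRNAs x %d diseases, %d edges\n",
              x$N, x$M, nrow(x$edges)))
  invisible(x)
}

#' Symmetric degree-normalization weight of an edge
#'
#' Returns `1 / (sqrt(deg(r)) * sqrt(deg(d)))`, the Laplace normalization
#' applied to each edge during neighbor aggregation, computed on the current
#' graph's degrees.
#'
#' @param graph an [build_graph()] object.
#' @param r snoRNA index.
#' @param d disease index.
#' @return A non-negative scalar.
#' @export
norm_weight <- function(graph, r, d) {
  stopifnot(inherits(graph, "sda_graph"))
  if (r < 1 || r > graph$N || d < 1 || d > graph$M || graph$adj[r, d] <= 0)
    stop(sprintf("edge (%d, %d) does not exist", r, d))
  dr <- graph$deg_snorna[r]
  dd <- graph$deg_disease[d]
  stopifnot(dr > 0, dd > 0)
  1 / (sqrt(dr) * sqrt(dd))
}

# Degree-normalized adjacency D_r^{-1/2} A D_d^{-1/2}; zero rows/cols for
# isolated nodes.
.norm_adjacency <- function(graph) {
  inv_r <- ifelse(graph$deg_snorna > 0, 1 / sqrt(graph$deg_snorna), 0)
  inv_d <- ifelse(graph$deg_disease > 0, 1 / sqrt(graph$deg_disease), 0)
  Matrix::Diagonal(x = inv_r) %*% graph$adj %*% Matrix::Diagonal(x = inv_d)
}

#' Per-subgraph restricted views of the bipartite graph
#'
#' Every snoRNA lives in exactly one subgraph and takes all of its disease
#' neighbors with it; a disease therefore appears in every subgraph holding at
#' least one of its snoRNA neighbors, with its neighbor set partitioned across
#' those views. The snoRNA-side degree is unchanged by construction.
#'
#' @param graph an [build_graph()] object.
#' @param assignment an [assign_subgraphs()] result (or an integer vector of
#'   subgraph ids in `1..n_subgraphs`, one per snoRNA).
#' @param n_subgraphs required when `assignment` is a bare vector.
#' @return A list of `subgraph_view` objects, one per subgraph id, each with
#'   `id`, `member_snornas`, `member_diseases`, the restricted neighbor list
#'   `restricted_nbrs_of_disease`, and restricted degrees `deg_restricted`
#'   (length-M vector, zero for non-member diseases).
#' @export
subgraph_views <- function(graph, assignment, n_subgraphs = NULL) {
  stopifnot(inherits(graph, "sda_graph"))
  if (inherits(assignment, "subgraph_assignment")) {
    hard <- assignment$hard
    ns <- assignment$n_subgraphs
  } else {
    hard <- as.integer(assignment)
    ns <- as.integer(n_subgraphs %||% max(hard))
  }
  if (length(hard) != graph$N)
    stop("assignment must cover every snoRNA")
  lapply(seq_len(ns), function(s) {
    members <- which(hard == s)
    restricted <- lapply(graph$nbrs_of_disease, function(nb)
      nb[nb %in% members])
    deg <- unname(vapply(restricted, length, integer(1)))
    structure(
      list(id = s,
           member_snornas = members,
           member_diseases = which(deg > 0),
           restricted_nbrs_of_disease = restricted,
           deg_restricted = deg),
      class = "subgraph_view"
    )
  })
}

#' Export the graph as an edge list with normalization weights
#'
#' Debug aid: writes one row per edge with the symmetric normalization weight
#' used during first-order aggregation.
#'
#' @param graph an [build_graph()] object.
#' @param path output TSV path.
#' @param table optional [association_table()] used to attach node names.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, table = NULL) {
  stopifnot(inherits(graph, "sda_graph"))
  e <- graph$edges
  w <- 1 / (sqrt(graph$deg_snorna[e$snorna_idx]) *
              sqrt(graph$deg_disease[e$disease_idx]))
  out <- data.frame(
    snorna = if (is.null(table)) e$snorna_idx else table$snornas[e$snorna_idx],
    disease = if (is.null(table)) e$disease_idx else table$diseases[e$disease_idx],
    weight = sprintf("%.17g", w)
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
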