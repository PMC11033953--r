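#' Generate a planted-block bipartite association table
#'
#' Emulates the premise that similar snoRNAs share disease neighborhoods:
#' snoRNAs and diseases are divided into `n_blocks` co-blocks and each
#' (snoRNA, disease) cell is associated with probability `p_in` within a
#' block and `p_out` across blocks. Nodes left without any association are
#' re-sampled once and then dropped with a warning, so every node in the
#' returned table has degree >= 1. The true block labels are returned for
#' assignment-recovery tests.
#'
#' @param n_blocks number of blocks B (>= 1).
#' @param snornas_per_block,diseases_per_block block sizes.
#' @param p_in within-block association probability.
#' @param p_out cross-block association probability (`p_out <= p_in`).
#' @param seed integer seed.
#' @return List with the [association_table()] `table`, integer vectors
#'   `snorna_blocks` and `disease_blocks` aligned with the table's index
#'   order, and the config echo.
#' @export
generate_planted <- function(n_blocks = 4L, snornas_per_block = 10L,
                             diseases_per_block = 8L, p_in = 0.6,
                             p_out = 0.02, seed = 1L) {
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1))
    stop("need 0 <= p_out <= p_in <= 1")
  N <- n_blocks * snornas_per_block
  M <- n_blocks * diseases_per_block
  if (N < 1 || M < 1) stop("block sizes must be positive")
  rb <- rep(seq_len(n_blocks), each = snornas_per_block)
  db <- rep(seq_len(n_blocks), each = diseases_per_block)
  Pmat <- matrix(p_out, N, M)
  Pmat[outer(rb, db, `==`)] <- p_in
  if (sum(Pmat) == 0) stop("expected edge count is zero")
  SD <- withr::with_seed(seed, {
    SD <- matrix(rbinom(N * M, 1, as.vector(Pmat)), N, M)
    for (i in which(rowSums(SD) == 0)) SD[i, ] <- rbinom(M, 1, Pmat[i, ])
    for (j in which(colSums(SD) == 0)) SD[, j] <- rbinom(N, 1, Pmat[, j])
    SD
  })
  drop_r <- which(rowSums(SD) == 0)
  drop_d <- which(colSums(SD) == 0)
  if (length(drop_r) + length(drop_d) > 0) {
    warning(sprintf("dropped %d snoRNA(s) and %d disease(s) with no associations",
                    length(drop_r), length(drop_d)))
    keep_r <- setdiff(seq_len(N), drop_r)
    keep_d <- setdiff(seq_len(M), drop_d)
    SD <- SD[keep_r, keep_d, drop = FALSE]
    rb <- rb[keep_r]; db <- db[keep_d]
  } else {
    keep_r <- seq_len(N); keep_d <- seq_len(M)
  }
  r_names <- sprintf("sno%03d", keep_r)
  d_names <- sprintf("dis%03d", keep_d)
  hits <- which(SD == 1, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  tab <- association_table(r_names[hits[, 1]], d_names[hits[, 2]])
  list(
    table = tab,
    snorna_blocks = setNames(rb[match(tab$snornas, r_names)], tab$snornas),
    disease_blocks = setNames(db[match(tab$diseases, d_names)], tab$diseases),
    config = list(n_blocks = n_blocks, snornas_per_block = snornas_per_block,
                  diseases_per_block = diseases_per_block,
                  p_in = p_in, p_out = p_out, seed = as.integer(seed))
  )
}

#' Chance-corrected recovery of planted blocks by the subgraph assignment
#'
#' Adjusted Rand index between the learned subgraph ids and the planted block
#' labels: 1 for identical partitions (up to relabeling), about 0 for random
#' assignments.
#'
#' @param assignment an [assign_subgraphs()] result or an integer label
#'   vector.
#' @param true_labels integer vector of planted block labels, same length.
#' @return Scalar ARI.
#' @export
assignment_recovery_score <- function(assignment, true_labels) {
  labels <- if (inherits(assignment, "subgraph_assignment")) assignment$hard
            else as.integer(assignment)
  stopifnot(length(labels) == length(true_labels))
  mclust::adjustedRandIndex(labels, as.integer(true_labels))
}
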