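# Model core: embedding tables, first-order propagation, subgraph generation,
# subgraph-restricted high-order propagation, layer combination, scoring.
#
# Conventions: embedding matrices are row-per-node (N x L, M x L). Layer lists
# use R index j = network layer j-1, so X[[1]] is the layer-0 table.

.lrelu <- function(x, slope) {
  x * (x >= 0) + (slope * x) * (x < 0)
}

.dlrelu <- function(x, slope) {
  (x >= 0) + slope * (x < 0)
}

.softmax_rows <- function(O) {
  m <- apply(O, 1, max)
  E <- exp(O - m)
  E / rowSums(E)
}

.onehot <- function(hard, n_subgraphs) {
  G <- matrix(0, length(hard), n_subgraphs)
  G[cbind(seq_along(hard), hard)] <- 1
  G
}

#' Initialize layer-0 embedding lookup tables
#'
#' Entries are drawn i.i.d. normal with standard deviation 0.1; the draw is
#' deterministic under `seed`.
#'
#' @param N,M snoRNA and disease counts.
#' @param L embedding dimension.
#' @param seed integer seed.
#' @return List with matrices `snorna` (N x L) and `disease` (M x L).
#' @export
init_embeddings <- function(N, M, L, seed = 1L) {
  stopifnot(N >= 1, M >= 1, L >= 1)
  withr::with_seed(seed, list(
    snorna = matrix(rnorm(N * L, 0, 0.1), N, L),
    disease = matrix(rnorm(M * L, 0, 0.1), M, L)
  ))
}

.xavier <- function(nout, nin) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nout * nin, -lim, lim), nout, nin)
}

#' Initialize all model parameters
#'
#' Layer-0 embeddings are normal(0, 0.1); the fusion and MLP weights are
#' Xavier-uniform with zero biases.
#'
#' @param N,M snoRNA and disease counts.
#' @param config a [model_config()].
#' @return A named list of parameter matrices/vectors: `E_r`, `E_d`, `W1`,
#'   `b1`, `W2`, `b2`, `W3`, `b3`.
#' @export
init_model_params <- function(N, M, config = model_config()) {
  L <- config$L
  H <- config$mlp_hidden
  Ns <- config$n_subgraphs
  withr::with_seed(config$seed, {
    list(
      E_r = matrix(rnorm(N * L, 0, 0.1), N, L),
      E_d = matrix(rnorm(M * L, 0, 0.1), M, L),
      W1 = .xavier(L, L), b1 = numeric(L),
      W2 = .xavier(H, L), b2 = numeric(H),
      W3 = .xavier(Ns, H), b3 = numeric(Ns)
    )
  })
}

#' First-order neighbor aggregation on the full bipartite graph
#'
#' Each node's layer-1 embedding is the degree-normalized sum of its
#' neighbors' layer-0 embeddings; isolated nodes get zero rows.
#'
#' @param e_r0 N x L snoRNA layer-0 matrix.
#' @param e_d0 M x L disease layer-0 matrix.
#' @param graph an [build_graph()] object.
#' @return List with matrices `snorna` (layer-1 snoRNA) and `disease`
#'   (layer-1 disease).
#' @export
propagate_first_order <- function(e_r0, e_d0, graph) {
  Ahat <- .norm_adjacency(graph)
  list(snorna = as.matrix(Ahat %*% e_d0),
       disease = as.matrix(Matrix::t(Ahat) %*% e_r0))
}

#' Fuse layer-0 and layer-1 snoRNA features
#'
#' `F[r] = LeakyReLU(W1 (e_r^0 + e_r^1) + b1)`, the input to the subgraph
#' generator.
#'
#' @param e_r0,e_r1 N x L snoRNA embedding matrices.
#' @param W1 L x L fusion weight; `b1` length-L bias.
#' @param b1 bias vector.
#' @param leaky_slope LeakyReLU negative slope.
#' @return N x L fused feature matrix.
#' @export
fuse_features <- function(e_r0, e_r1, W1, b1, leaky_slope = 0.01) {
  Z <- sweep((e_r0 + e_r1) %*% t(W1), 2, b1, `+`)
  .lrelu(Z, leaky_slope)
}

#' Assign each snoRNA to a subgraph with a 2-layer MLP
#'
#' Computes the prediction vector `O[r] = W3 LeakyReLU(W2 F[r] + b2) + b3`
#' and takes its argmax as the hard subgraph id (lowest index on ties). In
#' the relaxed modes the row-softmax of `O / temperature` is kept as soft
#' membership weights.
#'
#' @param F N x L fused feature matrix from [fuse_features()].
#' @param params parameter list holding `W2`, `b2`, `W3`, `b3` (e.g. from
#'   [init_model_params()]).
#' @param mode `"hard"`, `"straight_through"` or `"soft"`.
#' @param temperature softmax temperature.
#' @param leaky_slope LeakyReLU negative slope.
#' @return An object of class `subgraph_assignment`: `hard` (integer vector
#'   of ids in `1..n_subgraphs`), `n_subgraphs`, `soft` (N x N_s matrix or
#'   `NULL` in hard mode), and the raw scores `O`.
#' @export
assign_subgraphs <- function(F, params, mode = "hard", temperature = 1.0,
                             leaky_slope = 0.01) {
  Z2 <- sweep(F %*% t(params$W2), 2, params$b2, `+`)
  H <- .lrelu(Z2, leaky_slope)
  O <- sweep(H %*% t(params$W3), 2, params$b3, `+`)
  hard <- max.col(O, ties.method = "first")
  soft <- if (mode == "hard") NULL else .softmax_rows(O / temperature)
  structure(
    list(hard = hard, n_subgraphs = ncol(O), soft = soft, O = O),
    class = "subgraph_assignment"
  )
}

# Membership weight matrix for propagation: one-hot rows in hard and
# straight-through modes, softmax rows in soft mode.
.membership <- function(assignment, mode) {
  if (mode == "soft") assignment$soft
  else .onehot(assignment$hard, assignment$n_subgraphs)
}

# Soft-degree of disease d restricted to subgraph s: t(A) %*% G, with the
# inverse square root zeroed where the degree vanishes.
.restricted_degrees <- function(graph, G) {
  dds <- as.matrix(Matrix::t(graph$adj) %*% G)
  inv <- ifelse(dds > 0, 1 / sqrt(dds), 0)
  list(dds = dds, inv = inv)
}

# Restricted normalized adjacency for subgraph s:
# B_s[r, d] = A[r, d] G[r, s] / (sqrt(deg_r) sqrt(deg_ds)).
.restricted_adjacency <- function(graph, g_col, inv_dr, inv_dds_col) {
  Matrix::Diagonal(x = g_col * inv_dr) %*% graph$adj %*%
    Matrix::Diagonal(x = inv_dds_col)
}

#' Split the first-order disease aggregation across subgraphs
#'
#' Restricts the first-order disease sum to each subgraph's member snoRNAs
#' while keeping the full-graph normalization, so the per-subgraph pieces add
#' up exactly to the first-order disease embeddings. These pieces seed the
#' subgraph-restricted high-order layers.
#'
#' @param e_r0 N x L snoRNA layer-0 matrix.
#' @param graph an [build_graph()] object.
#' @param assignment an [assign_subgraphs()] result.
#' @param mode membership mode; defaults to hard one-hot weights.
#' @return A list of N_s matrices (M x L), zero rows for non-member diseases.
#' @export
split_first_order <- function(e_r0, graph, assignment, mode = "hard") {
  G <- .membership(assignment, mode)
  Ahat <- .norm_adjacency(graph)
  lapply(seq_len(ncol(G)), function(s)
    as.matrix(Matrix::t(Ahat) %*% (G[, s] * e_r0)))
}

#' One subgraph-restricted high-order propagation step
#'
#' Within each subgraph the disease update sums member-snoRNA embeddings with
#' the restriction-aware normalization `1/(sqrt(deg_ds) sqrt(deg_r))`, and
#' each snoRNA aggregates the subgraph-local embeddings of its own diseases.
#' The full disease embedding of the new layer is the sum of its per-subgraph
#' pieces.
#'
#' @param e_r_k N x L snoRNA embeddings at layer k.
#' @param e_ds_k list of N_s subgraph-local disease matrices at layer k.
#' @param graph an [build_graph()] object.
#' @param assignment an [assign_subgraphs()] result.
#' @param mode membership mode (`"hard"` or `"soft"`).
#' @return List with `snorna` (layer k+1), `disease_sub` (per-subgraph list)
#'   and `disease` (their sum).
#' @export
propagate_high_order <- function(e_r_k, e_ds_k, graph, assignment,
                                 mode = "hard") {
  G <- .membership(assignment, mode)
  if (length(e_ds_k) != ncol(G))
    stop("subgraph-local layers do not match the assignment")
  inv_dr <- ifelse(graph$deg_snorna > 0, 1 / sqrt(graph$deg_snorna), 0)
  rd <- .restricted_degrees(graph, G)
  L <- ncol(e_r_k)
  x_next <- matrix(0, graph$N, L)
  yds_next <- vector("list", ncol(G))
  for (s in seq_len(ncol(G))) {
    B <- .restricted_adjacency(graph, G[, s], inv_dr, rd$inv[, s])
    x_next <- x_next + as.matrix(B %*% e_ds_k[[s]])
    yds_next[[s]] <- as.matrix(Matrix::t(B) %*% e_r_k)
  }
  list(snorna = x_next, disease_sub = yds_next,
       disease = Reduce(`+`, yds_next))
}

#' Average embeddings across propagation layers
#'
#' The final representation is the arithmetic mean of the layer-0..K
#' embeddings.
#'
#' @param layers list of equal-shape matrices (layers 0..K).
#' @return The mean matrix.
#' @export
combine_layers <- function(layers) {
  stopifnot(length(layers) >= 1)
  Reduce(`+`, layers) / length(layers)
}

#' Inner-product association scores
#'
#' @param e_r N x L final snoRNA embeddings.
#' @param e_d M x L final disease embeddings.
#' @return `score_all`: the dense N x M score matrix.
#' @export
score_all <- function(e_r, e_d) {
  e_r %*% t(e_d)
}

#' @rdname score_all
#' @param r,d index vectors (recycled to equal length).
#' @return `score_pairs`: the vector of scores for the given (r, d) pairs.
#' @export
score_pairs <- function(e_r, e_d, r, d) {
  rowSums(e_r[r, , drop = FALSE] * e_d[d, , drop = FALSE])
}

# Full forward pass. Returns final embeddings plus every intermediate needed
# for backpropagation. `assignment` freezes the subgraph assignment (used in
# isolation tests); otherwise it is recomputed from the current embeddings.
.forward <- function(params, graph, config, assignment = NULL) {
  K <- config$K
  Ahat <- .norm_adjacency(graph)
  X <- vector("list", K + 1)
  Y <- vector("list", K + 1)
  X[[1]] <- params$E_r
  Y[[1]] <- params$E_d
  X[[2]] <- as.matrix(Ahat %*% Y[[1]])
  Y[[2]] <- as.matrix(Matrix::t(Ahat) %*% X[[1]])

  if (config$ablation_lightgcn) {
    if (K >= 2) for (j in 3:(K + 1)) {
      X[[j]] <- as.matrix(Ahat %*% Y[[j - 1]])
      Y[[j]] <- as.matrix(Matrix::t(Ahat) %*% X[[j - 1]])
    }
    return(structure(
      list(e_r = combine_layers(X), e_d = combine_layers(Y),
           assignment = NULL, X = X, Y = Y, Yds = NULL,
           Ahat = Ahat, config = config, plain = TRUE),
      class = "sda_forward"))
  }

  mode <- config$assignment_mode
  Z1 <- sweep((X[[1]] + X[[2]]) %*% t(params$W1), 2, params$b1, `+`)
  F <- .lrelu(Z1, config$leaky_slope)
  Z2 <- sweep(F %*% t(params$W2), 2, params$b2, `+`)
  Hm <- .lrelu(Z2, config$leaky_slope)
  O <- sweep(Hm %*% t(params$W3), 2, params$b3, `+`)
  if (is.null(assignment)) {
    assignment <- structure(
      list(hard = max.col(O, ties.method = "first"),
           n_subgraphs = config$n_subgraphs,
           soft = if (mode == "hard") NULL
                  else .softmax_rows(O / config$temperature),
           O = O),
      class = "subgraph_assignment")
  }
  G <- .membership(assignment, mode)

  inv_dr <- ifelse(graph$deg_snorna > 0, 1 / sqrt(graph$deg_snorna), 0)
  rd <- .restricted_degrees(graph, G)
  Yds <- vector("list", K + 1)
  Yds[[2]] <- lapply(seq_len(ncol(G)), function(s)
    as.matrix(Matrix::t(Ahat) %*% (G[, s] * X[[1]])))
  if (K >= 2) for (j in 3:(K + 1)) {
    x_next <- matrix(0, graph$N, config$L)
    yds_next <- vector("list", ncol(G))
    for (s in seq_len(ncol(G))) {
      B <- .restricted_adjacency(graph, G[, s], inv_dr, rd$inv[, s])
      x_next <- x_next + as.matrix(B %*% Yds[[j - 1]][[s]])
      yds_next[[s]] <- as.matrix(Matrix::t(B) %*% X[[j - 1]])
    }
    X[[j]] <- x_next
    Yds[[j]] <- yds_next
    Y[[j]] <- Reduce(`+`, yds_next)
  }

  structure(
    list(e_r = combine_layers(X), e_d = combine_layers(Y),
         assignment = assignment, X = X, Y = Y, Yds = Yds,
         F = F, Z1 = Z1, Z2 = Z2, Hm = Hm, O = O, G = G,
         dds = rd$dds, inv_dds = rd$inv, inv_dr = inv_dr,
         Ahat = Ahat, config = config, plain = FALSE),
    class = "sda_forward")
}

#' Run the full model forward pass
#'
#' Executes first-order aggregation, subgraph generation, the K-1
#' subgraph-restricted high-order layers, and layer combination. The subgraph
#' assignment is recomputed from the current embeddings on every call unless
#' one is supplied. With `ablation_lightgcn` set in the config, the subgraph
#' machinery is skipped and K plain LightGCN layers run on the full graph.
#'
#' @param params parameter list from [init_model_params()].
#' @param graph an [build_graph()] object.
#' @param config a [model_config()].
#' @param assignment optional frozen [assign_subgraphs()] result.
#' @return An object of class `sda_forward` with final embeddings `e_r`,
#'   `e_d`, the `assignment`, and per-layer matrices `X`, `Y`, `Yds`
#'   (subgraph-local disease layers).
#' @export
sda_forward <- function(params, graph, config = model_config(),
                        assignment = NULL) {
  stopifnot(inherits(graph, "sda_graph"), inherits(config, "model_config"))
  .forward(params, graph, config, assignment = assignment)
}
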