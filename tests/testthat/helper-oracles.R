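# Independent reference implementations used as oracles. These are written
# with explicit per-edge loops, deliberately sharing no code with the
# package's sparse-matrix implementation.

# Plain LightGCN: K layers of degree-normalized neighbor aggregation on the
# full bipartite graph, then layer averaging.
lightgcn_reference <- function(E_r, E_d, edges, K) {
  N <- nrow(E_r); M <- nrow(E_d); L <- ncol(E_r)
  deg_r <- tabulate(edges[, 1], N)
  deg_d <- tabulate(edges[, 2], M)
  Xs <- list(E_r)
  Ys <- list(E_d)
  for (k in seq_len(K)) {
    Xk <- matrix(0, N, L)
    Yk <- matrix(0, M, L)
    for (e in seq_len(nrow(edges))) {
      r <- edges[e, 1]; d <- edges[e, 2]
      w <- 1 / sqrt(deg_r[r] * deg_d[d])
      Xk[r, ] <- Xk[r, ] + w * Ys[[k]][d, ]
      Yk[d, ] <- Yk[d, ] + w * Xs[[k]][r, ]
    }
    Xs[[k + 1]] <- Xk
    Ys[[k + 1]] <- Yk
  }
  list(e_r = Reduce(`+`, Xs) / (K + 1), e_d = Reduce(`+`, Ys) / (K + 1))
}

# Subgraph-restricted propagation with a fixed hard assignment, computed
# per-edge from the definitions: layer 1 splits the disease sum across
# subgraphs under full normalization; layers >= 2 use restricted degrees.
subgraph_reference <- function(E_r, E_d, edges, hard, n_sub, K) {
  N <- nrow(E_r); M <- nrow(E_d); L <- ncol(E_r)
  deg_r <- tabulate(edges[, 1], N)
  deg_d <- tabulate(edges[, 2], M)
  dds <- matrix(0, M, n_sub)
  for (e in seq_len(nrow(edges)))
    dds[edges[e, 2], hard[edges[e, 1]]] <-
      dds[edges[e, 2], hard[edges[e, 1]]] + 1
  X <- list(E_r)
  Y <- list(E_d)
  X1 <- matrix(0, N, L); Y1 <- matrix(0, M, L)
  Yds <- list()
  Yds[[2]] <- replicate(n_sub, matrix(0, M, L), simplify = FALSE)
  for (e in seq_len(nrow(edges))) {
    r <- edges[e, 1]; d <- edges[e, 2]
    w <- 1 / sqrt(deg_r[r] * deg_d[d])
    X1[r, ] <- X1[r, ] + w * E_d[d, ]
    Y1[d, ] <- Y1[d, ] + w * E_r[r, ]
    s <- hard[r]
    Yds[[2]][[s]][d, ] <- Yds[[2]][[s]][d, ] + w * E_r[r, ]
  }
  X[[2]] <- X1; Y[[2]] <- Y1
  if (K >= 2) for (j in 3:(K + 1)) {
    Xk <- matrix(0, N, L)
    Ydsk <- replicate(n_sub, matrix(0, M, L), simplify = FALSE)
    for (e in seq_len(nrow(edges))) {
      r <- edges[e, 1]; d <- edges[e, 2]
      s <- hard[r]
      w <- 1 / sqrt(deg_r[r] * dds[d, s])
      Xk[r, ] <- Xk[r, ] + w * Yds[[j - 1]][[s]][d, ]
      Ydsk[[s]][d, ] <- Ydsk[[s]][d, ] + w * X[[j - 1]][r, ]
    }
    X[[j]] <- Xk
    Yds[[j]] <- Ydsk
    Y[[j]] <- Reduce(`+`, Ydsk)
  }
  list(e_r = Reduce(`+`, X) / (K + 1), e_d = Reduce(`+`, Y) / (K + 1),
       X = X, Y = Y, Yds = Yds)
}

# AUC by exhaustive comparison of all positive/negative score pairs,
# ties counted one half.
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Random association table over N x M cells with edge probability p;
# guaranteed non-empty.
random_table <- function(N, M, p, seed) {
  withr::with_seed(seed, {
    A <- matrix(rbinom(N * M, 1, p), N, M)
    if (sum(A) == 0) A[sample(N, 1), sample(M, 1)] <- 1
  })
  hits <- which(A == 1, arr.ind = TRUE)
  association_table(sprintf("r%03d", hits[, 1]), sprintf("d%03d", hits[, 2]))
}

# Synthetic benchmark-sized table: exactly 1095 distinct pairs over
# 471 snoRNAs x 84 diseases.
table_1095 <- function(seed = 20) {
  cells <- withr::with_seed(seed, sample(471L * 84L, 1095L))
  r <- (cells - 1L) %% 471L + 1L
  d <- (cells - 1L) %/% 471L + 1L
  association_table(sprintf("sno%03d", r), sprintf("dis%02d", d))
}

# Frozen subgraph assignment from a bare id vector.
frozen_assignment <- function(hard, n_sub = max(hard)) {
  structure(list(hard = as.integer(hard), n_subgraphs = as.integer(n_sub),
                 soft = NULL, O = NULL),
            class = "subgraph_assignment")
}

# Random model parameters (independent of init_model_params defaults).
random_params <- function(N, M, cfg, seed) {
  withr::with_seed(seed, list(
    E_r = matrix(rnorm(N * cfg$L, 0, 0.3), N, cfg$L),
    E_d = matrix(rnorm(M * cfg$L, 0, 0.3), M, cfg$L),
    W1 = matrix(rnorm(cfg$L^2, 0, 0.2), cfg$L, cfg$L),
    b1 = rnorm(cfg$L, 0, 0.1),
    W2 = matrix(rnorm(cfg$mlp_hidden * cfg$L, 0, 0.2), cfg$mlp_hidden, cfg$L),
    b2 = rnorm(cfg$mlp_hidden, 0, 0.1),
    W3 = matrix(rnorm(cfg$n_subgraphs * cfg$mlp_hidden, 0, 0.2),
                cfg$n_subgraphs, cfg$mlp_hidden),
    b3 = rnorm(cfg$n_subgraphs, 0, 0.1)
  ))
}

# Central finite differences of the training loss wrt selected parameter
# entries, compared against the analytic gradient; returns worst relative
# error.
fd_worst_error <- function(params, graph, cfg, trip, lambda,
                           n_per_param = 8, h = 1e-6, seed = 1) {
  lg <- snograph:::.loss_and_grads(params, graph, cfg, trip, lambda)
  worst <- 0
  withr::with_seed(seed, {
    for (nm in names(params)) {
      idx <- if (length(params[[nm]]) <= n_per_param) seq_along(params[[nm]])
             else sample(length(params[[nm]]), n_per_param)
      for (i in idx) {
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
        num <- (snograph:::.loss_and_grads(pp, graph, cfg, trip, lambda)$loss -
                  snograph:::.loss_and_grads(pm, graph, cfg, trip, lambda)$loss) /
          (2 * h)
        worst <- max(worst, abs(num - lg$grads[[nm]][i]) / max(1, abs(num)))
      }
    }
  })
  worst
}
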