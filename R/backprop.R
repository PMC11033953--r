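# Reverse-mode gradients for the forward pass in model.R.
#
# Given a fixed subgraph assignment the propagation is linear in the layer-0
# embeddings, so those gradients are plain transposes of the forward maps.
# The discrete assignment itself is handled by the straight-through scheme:
# the forward pass uses the hard argmax memberships, while the backward pass
# differentiates the degree-soft relaxation (membership weights G entering
# both the edge masks and the restricted degrees) and chains through the
# softmax of the MLP scores. In "soft" mode the same formulas are evaluated
# at G = softmax(O / temperature), which makes the whole loss differentiable
# and is exploited by the finite-difference tests.

.zero_like_params <- function(params) {
  lapply(params, function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
         else numeric(length(p)))
}

# Structural gradient of sum_{r,d} B_s[r,d] * C_s[r,d] with respect to the
# membership column g = G[, s], where
#   B_s[r,d] = A[r,d] g[r] deg_r[r]^{-1/2} dds[d]^{-1/2},
#   dds[d]   = sum_r A[r,d] g[r].
# W_full = A * deg_r^{-1/2} (dense, row-scaled); inv3 = dds^{-3/2}.
.struct_grad_col <- function(W_full, C_s, g_col, inv_dds_col, Adense) {
  WC <- W_full * C_s
  direct <- as.vector(WC %*% inv_dds_col)
  T_d <- colSums(WC * g_col)
  degree <- as.vector(Adense %*% (inv_dds_col^3 * T_d))
  direct - 0.5 * degree
}

# Backpropagate gradients of the loss with respect to the final embeddings
# through the whole forward pass. Returns a parameter-shaped gradient list.
.backward <- function(fw, params, graph, config, gEr_final, gEd_final) {
  K <- config$K
  c1 <- 1 / (K + 1)
  grads <- .zero_like_params(params)
  gX <- lapply(seq_len(K + 1), function(j) gEr_final * c1)
  gY <- lapply(seq_len(K + 1), function(j) gEd_final * c1)
  Ahat <- fw$Ahat

  if (isTRUE(fw$plain)) {
    for (j in seq(K + 1, 2)) {
      gY[[j - 1]] <- gY[[j - 1]] + as.matrix(Matrix::t(Ahat) %*% gX[[j]])
      gX[[j - 1]] <- gX[[j - 1]] + as.matrix(Ahat %*% gY[[j]])
    }
    grads$E_r <- gX[[1]]
    grads$E_d <- gY[[1]]
    return(grads)
  }

  mode <- config$assignment_mode
  G <- fw$G
  Ns <- ncol(G)
  want_struct <- mode != "hard"
  Adense <- if (want_struct) as.matrix(graph$adj) else NULL
  W_full <- if (want_struct) Adense * fw$inv_dr else NULL
  gG <- matrix(0, graph$N, Ns)

  gYds <- vector("list", K + 1)
  for (j in 2:(K + 1)) gYds[[j]] <- lapply(seq_len(Ns), function(s)
    matrix(0, graph$M, config$L))

  Bs <- lapply(seq_len(Ns), function(s)
    .restricted_adjacency(graph, G[, s], fw$inv_dr, fw$inv_dds[, s]))

  if (K >= 2) for (j in seq(K + 1, 3)) {
    for (s in seq_len(Ns)) {
      gYds[[j]][[s]] <- gYds[[j]][[s]] + gY[[j]]
      gX[[j - 1]] <- gX[[j - 1]] + as.matrix(Bs[[s]] %*% gYds[[j]][[s]])
      gYds[[j - 1]][[s]] <- gYds[[j - 1]][[s]] +
        as.matrix(Matrix::t(Bs[[s]]) %*% gX[[j]])
      if (want_struct) {
        C_s <- (tcrossprod(gX[[j]], fw$Yds[[j - 1]][[s]]) +
                  tcrossprod(fw$X[[j - 1]], gYds[[j]][[s]])) * Adense
        gG[, s] <- gG[, s] +
          .struct_grad_col(W_full, C_s, G[, s], fw$inv_dds[, s], Adense)
      }
    }
  }

  # layer-1 subgraph split: Yds[[2]][[s]] = t(Ahat) (G[,s] * X0)
  Ahat_dense <- if (want_struct) as.matrix(Ahat) else NULL
  for (s in seq_len(Ns)) {
    gX[[1]] <- gX[[1]] + G[, s] * as.matrix(Ahat %*% gYds[[2]][[s]])
    if (want_struct) {
      gG[, s] <- gG[, s] +
        rowSums(Ahat_dense * tcrossprod(fw$X[[1]], gYds[[2]][[s]]))
    }
  }
  # full first-order disease layer: Y1 = t(Ahat) X0
  gX[[1]] <- gX[[1]] + as.matrix(Ahat %*% gY[[2]])

  if (want_struct) {
    # straight-through / soft: chain gG through softmax(O / temperature)
    P <- if (mode == "soft") G else fw$assignment$soft
    inner <- rowSums(P * gG)
    gO <- (P * (gG - inner)) / config$temperature
    bw <- config$balance_weight %||% 0
    if (bw > 0) {
      # usage-balance term: KL(colMeans(P) || uniform); counters the
      # aggregate winner-take-all feedback that otherwise empties all but
      # one subgraph early in training
      u <- colMeans(P)
      v <- matrix(bw * (log(u) + 1) / nrow(P), nrow(P), length(u),
                  byrow = TRUE)
      gO <- gO + (P * (v - rowSums(P * v))) / config$temperature
    }
    gHm <- gO %*% params$W3
    grads$W3 <- grads$W3 + crossprod(gO, fw$Hm)
    grads$b3 <- grads$b3 + colSums(gO)
    gZ2 <- gHm * .dlrelu(fw$Z2, config$leaky_slope)
    grads$W2 <- grads$W2 + crossprod(gZ2, fw$F)
    grads$b2 <- grads$b2 + colSums(gZ2)
    gF <- gZ2 %*% params$W2
    gZ1 <- gF * .dlrelu(fw$Z1, config$leaky_slope)
    grads$W1 <- grads$W1 + crossprod(gZ1, fw$X[[1]] + fw$X[[2]])
    grads$b1 <- grads$b1 + colSums(gZ1)
    gS <- gZ1 %*% params$W1
    gX[[1]] <- gX[[1]] + gS
    gX[[2]] <- gX[[2]] + gS
  }

  # first-order snoRNA layer: X1 = Ahat Y0
  gY[[1]] <- gY[[1]] + as.matrix(Matrix::t(Ahat) %*% gX[[2]])

  grads$E_r <- grads$E_r + gX[[1]]
  grads$E_d <- grads$E_d + gY[[1]]
  grads
}

.softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# Loss and full parameter gradients for one batch of triplets.
# triplets: data frame with columns snorna, pos, neg (integer indices).
.loss_and_grads <- function(params, graph, config, triplets, lambda,
                            assignment = NULL) {
  fw <- .forward(params, graph, config, assignment = assignment)
  r <- triplets$snorna
  dp <- triplets$pos
  dn <- triplets$neg
  nT <- length(r)
  diff <- score_pairs(fw$e_r, fw$e_d, r, dp) - score_pairs(fw$e_r, fw$e_d, r, dn)
  bpr <- mean(.softplus(-diff))
  coef <- -plogis(-diff) / nT

  gEr_final <- matrix(0, graph$N, config$L)
  acc_r <- rowsum((fw$e_d[dp, , drop = FALSE] - fw$e_d[dn, , drop = FALSE]) *
                    coef, group = r)
  gEr_final[as.integer(rownames(acc_r)), ] <- acc_r
  gEd_final <- matrix(0, graph$M, config$L)
  acc_d <- rowsum(rbind(fw$e_r[r, , drop = FALSE] * coef,
                        -fw$e_r[r, , drop = FALSE] * coef),
                  group = c(dp, dn))
  gEd_final[as.integer(rownames(acc_d)), ] <- acc_d

  grads <- .backward(fw, params, graph, config, gEr_final, gEd_final)

  # L2 on the batch's ego (layer-0) embeddings, averaged per triplet.
  # Penalizing the generator MLP weights as well (at lambda = 0.1) drives
  # them to zero within a few hundred Adam steps, which ties every argmax
  # and collapses the assignment to a single subgraph; the generator is
  # therefore excluded from the penalty (see the methods vignette).
  cnt_r <- tabulate(r, graph$N)
  cnt_d <- tabulate(c(dp, dn), graph$M)
  reg_ego <- (sum(cnt_r * rowSums(params$E_r^2)) +
                sum(cnt_d * rowSums(params$E_d^2))) / nT
  if (lambda > 0) {
    grads$E_r <- grads$E_r + (2 * lambda / nT) * (cnt_r * params$E_r)
    grads$E_d <- grads$E_d + (2 * lambda / nT) * (cnt_d * params$E_d)
  }
  if (isTRUE(fw$plain) || config$assignment_mode == "hard") {
    for (nm in c("W1", "b1", "W2", "b2", "W3", "b3"))
      grads[[nm]] <- grads[[nm]] * 0
  }

  balance <- 0
  bw <- config$balance_weight %||% 0
  if (bw > 0 && !isTRUE(fw$plain) && config$assignment_mode != "hard") {
    u <- colMeans(fw$assignment$soft)
    balance <- bw * sum(u * log(u * length(u)))
  }

  list(loss = bpr + lambda * reg_ego + balance, bpr = bpr,
       reg = reg_ego, balance = balance, grads = grads, forward = fw)
}
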