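#' Sample BPR triplets from the training graph
#'
#' One pass over all training positives: for every observed association
#' `(r, d+)`, `neg_per_pos` negative diseases are drawn uniformly from the
#' diseases not associated with `r` in the training graph. snoRNAs linked to
#' every disease are skipped with a warning.
#'
#' @param graph an [build_graph()] object (training edges).
#' @param neg_per_pos negatives per positive (default 1).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return Data frame with integer columns `snorna`, `pos`, `neg`.
#' @export
sample_triplets <- function(graph, neg_per_pos = 1L, seed = NULL) {
  stopifnot(inherits(graph, "sda_graph"))
  draw <- function() {
    out_r <- integer(0); out_p <- integer(0); out_n <- integer(0)
    skipped <- 0L
    all_d <- seq_len(graph$M)
    for (r in which(graph$deg_snorna > 0)) {
      nbr <- graph$nbrs_of_snorna[[r]]
      free <- all_d[-nbr]
      if (length(free) == 0) {
        skipped <- skipped + 1L
        next
      }
      npos <- length(nbr)
      pos <- rep(nbr, each = neg_per_pos)
      neg <- free[sample.int(length(free), npos * neg_per_pos, replace = TRUE)]
      out_r <- c(out_r, rep.int(r, npos * neg_per_pos))
      out_p <- c(out_p, pos)
      out_n <- c(out_n, neg)
    }
    if (skipped > 0)
      warning(sprintf("%d snoRNA(s) associated with every disease were skipped",
                      skipped))
    data.frame(snorna = out_r, pos = out_p, neg = out_n)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Bayesian Personalized Ranking loss
#'
#' Mean over triplets of `-ln sigma(score_pos - score_neg)` plus
#' `lambda * reg_term`, evaluated in the numerically stable softplus form.
#' With all scores equal and `lambda = 0` the loss is exactly `ln 2`.
#'
#' @param scores_pos,scores_neg equal-length score vectors.
#' @param reg_term scalar regularization term (e.g. the squared L2 norm of
#'   the batch's layer-0 embeddings averaged per triplet).
#' @param lambda L2 strength.
#' @return Scalar loss.
#' @export
bpr_loss <- function(scores_pos, scores_neg, reg_term = 0, lambda = 0) {
  stopifnot(length(scores_pos) == length(scores_neg))
  mean(.softplus(-(scores_pos - scores_neg))) + lambda * reg_term
}

.adam_init <- function(params) {
  list(m = .zero_like_params(params), v = .zero_like_params(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the model with BPR and Adam
#'
#' Per epoch: full forward pass (the subgraph assignment is recomputed from
#' the current embeddings), one pass of triplet sampling over all training
#' positives, loss evaluation and an Adam update (full-batch by default).
#' When validation pairs are supplied, validation AUC is tracked every
#' `eval_every` epochs and training stops early after `patience` epochs
#' without improvement, restoring the best parameters.
#'
#' @param graph training [build_graph()] object.
#' @param config a [model_config()].
#' @param tconfig a [train_config()].
#' @param val_pairs optional 2-column matrix/data frame of held-out
#'   (snorna_idx, disease_idx) pairs for early stopping.
#' @param table optional [association_table()] carried along for name-aware
#'   downstream tools ([rank_candidates()], [top_bottom_similarity()]).
#' @param verbose print the loss every 100 epochs.
#' @return An object of class `sda_model`: `params`, final embeddings `e_r`,
#'   `e_d`, the final `assignment`, `history` (per-epoch loss and optional
#'   validation AUC), plus the `graph`, `config`, `tconfig` and `table`.
#' @export
train_model <- function(graph, config = model_config(),
                        tconfig = train_config(), val_pairs = NULL,
                        table = NULL, verbose = FALSE) {
  stopifnot(inherits(graph, "sda_graph"))
  if (nrow(graph$edges) == 0) stop("training graph has no edges")
  params <- init_model_params(graph$N, graph$M, config)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_auc = numeric(0))
  run <- function() {
    state <- .adam_init(params)
    best <- list(params = params, auc = -Inf, epoch = 0L)
    since_best <- 0L
    for (epoch in seq_len(tconfig$epochs)) {
      trip <- sample_triplets(graph, tconfig$neg_per_pos)
      if (is.null(tconfig$batch_size) || tconfig$batch_size >= nrow(trip)) {
        lg <- .loss_and_grads(params, graph, config, trip, tconfig$lambda)
        if (!is.finite(lg$loss))
          stop(sprintf("non-finite loss at epoch %d (loss=%g)", epoch, lg$loss))
        upd <- .adam_step(params, lg$grads, state, tconfig$lr)
        params <- upd$params; state <- upd$state
        epoch_loss <- lg$loss
      } else {
        ord <- sample.int(nrow(trip))
        chunks <- split(ord, ceiling(seq_along(ord) / tconfig$batch_size))
        losses <- numeric(length(chunks))
        for (ci in seq_along(chunks)) {
          lg <- .loss_and_grads(params, graph, config,
                                trip[chunks[[ci]], , drop = FALSE],
                                tconfig$lambda)
          if (!is.finite(lg$loss))
            stop(sprintf("non-finite loss at epoch %d (loss=%g)", epoch, lg$loss))
          upd <- .adam_step(params, lg$grads, state, tconfig$lr)
          params <- upd$params; state <- upd$state
          losses[ci] <- lg$loss
        }
        epoch_loss <- mean(losses)
      }
      val_auc <- NA_real_
      if (!is.null(val_pairs) && epoch %% tconfig$eval_every == 0) {
        fw <- .forward(params, graph, config)
        S <- score_all(fw$e_r, fw$e_d)
        val_auc <- .holdout_auc(S, graph, val_pairs)
        if (val_auc > best$auc) {
          best <- list(params = params, auc = val_auc, epoch = epoch)
          since_best <- 0L
        } else {
          since_best <- since_best + tconfig$eval_every
        }
      }
      history[nrow(history) + 1L, ] <<- list(epoch, epoch_loss, val_auc)
      if (verbose && epoch %% 100 == 0)
        message(sprintf("epoch %d: loss %.5f", epoch, epoch_loss))
      if (!is.null(val_pairs) && since_best >= tconfig$patience) break
    }
    if (!is.null(val_pairs) && is.finite(best$auc)) params <- best$params
    params
  }
  params <- withr::with_seed(tconfig$seed, run())
  fw <- .forward(params, graph, config)
  structure(
    list(params = params, e_r = fw$e_r, e_d = fw$e_d,
         assignment = fw$assignment, history = history,
         graph = graph, config = config, tconfig = tconfig, table = table),
    class = "sda_model")
}

#' @export
print.sda_model <- function(x, ...) {
  cat(sprintf(
    "sda_model: %d snoRNAs x %d diseases, L=%d, K=%d, N_s=%d, %d epoch(s)\n",
    x$graph$N, x$graph$M, x$config$L, x$config$K, x$config$n_subgraphs,
    nrow(x$history)))
  if (nrow(x$history) > 0)
    cat(sprintf("  final loss %.5f\n", tail(x$history$loss, 1)))
  invisible(x)
}

#' Write the per-epoch training log as TSV
#'
#' @param model an [train_model()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_history <- function(model, path) {
  write.table(model$history, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
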