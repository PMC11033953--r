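#' Ranking and classification metrics
#'
#' `auc_score` is the Mann-Whitney statistic (ties counted 1/2);
#' `aupr_score` is the area under the precision-recall curve with step
#' interpolation (average precision); `accuracy_score` thresholds the
#' sigmoid-transformed score at `threshold` (default 0.5, i.e. raw score 0).
#'
#' @param scores numeric score vector.
#' @param labels 0/1 (or logical) label vector.
#' @return Scalar in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop("auc_score needs at least one positive and one negative label")
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' @rdname auc_score
#' @export
aupr_score <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1)
  if (npos == 0 || sum(labels == 0) == 0)
    stop("aupr_score needs at least one positive and one negative label")
  ord <- order(scores, seq_along(scores), decreasing = TRUE)
  l <- labels[ord]
  prec <- cumsum(l) / seq_along(l)
  sum(prec * l) / npos
}

#' @rdname auc_score
#' @param threshold probability threshold applied to `plogis(score)`.
#' @export
accuracy_score <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  mean((plogis(scores) >= threshold) == (labels == 1))
}

# Cells of the N x M score matrix not covered by train or test edges.
.negative_cells <- function(graph, test_pairs, extra_exclude = NULL) {
  N <- graph$N; M <- graph$M
  used <- c((graph$edges$disease_idx - 1L) * N + graph$edges$snorna_idx,
            (test_pairs[, 2] - 1L) * N + test_pairs[, 1])
  if (!is.null(extra_exclude))
    used <- c(used, (extra_exclude[, 2] - 1L) * N + extra_exclude[, 1])
  setdiff(seq_len(N * M), used)
}

# AUC of held-out positives against all unobserved cells; used for early
# stopping during training.
.holdout_auc <- function(S, graph, test_pairs) {
  test_pairs <- as.matrix(test_pairs)[, 1:2, drop = FALSE]
  neg <- .negative_cells(graph, test_pairs)
  pos_scores <- S[cbind(test_pairs[, 1], test_pairs[, 2])]
  auc_score(c(pos_scores, S[neg]),
            c(rep(1L, length(pos_scores)), rep(0L, length(neg))))
}

#' Evaluate a trained model on held-out association pairs
#'
#' Positives are the test pairs; negatives are, by default, every (snoRNA,
#' disease) cell absent from both the training graph and the test set (the
#' standard link-prediction convention). Accuracy is always computed on a
#' balanced negative sample of the same size as the positives, with the
#' sigmoid of the raw inner product thresholded at 0.5, since raw scores are
#' unbounded. Scores come from embeddings propagated on the training graph
#' only, so test edges never leak into propagation.
#'
#' @param model an [train_model()] result (or a list with `e_r`, `e_d`).
#' @param test_pairs 2-column matrix/data frame of (snorna_idx, disease_idx).
#' @param neg_policy `"all_unobserved"` (default) or `"balanced"`.
#' @param seed seed for the balanced negative sample.
#' @param graph training graph; defaults to `model$graph`.
#' @return An object of class `eval_result`: `auc`, `aupr`, `accuracy`,
#'   `n_pos`, `n_neg`.
#' @export
evaluate_split <- function(model, test_pairs,
                           neg_policy = c("all_unobserved", "balanced"),
                           seed = 1L, graph = NULL) {
  neg_policy <- match.arg(neg_policy)
  graph <- graph %||% model$graph
  test_pairs <- as.matrix(test_pairs)[, 1:2, drop = FALSE]
  if (nrow(test_pairs) == 0) stop("empty test set")
  S <- score_all(model$e_r, model$e_d)
  pos_scores <- S[cbind(test_pairs[, 1], test_pairs[, 2])]
  neg_cells <- .negative_cells(graph, test_pairs)
  if (length(neg_cells) == 0) stop("no negative cells available")
  bal_cells <- withr::with_seed(seed,
    neg_cells[sample.int(length(neg_cells),
                         min(length(neg_cells), length(pos_scores)))])
  rank_neg <- if (neg_policy == "balanced") bal_cells else neg_cells
  neg_scores <- S[rank_neg]
  scores <- c(pos_scores, neg_scores)
  labels <- c(rep(1L, length(pos_scores)), rep(0L, length(neg_scores)))
  bal_scores <- c(pos_scores, S[bal_cells])
  bal_labels <- c(rep(1L, length(pos_scores)), rep(0L, length(bal_cells)))
  structure(
    list(auc = auc_score(scores, labels),
         aupr = aupr_score(scores, labels),
         accuracy = accuracy_score(bal_scores, bal_labels),
         n_pos = length(pos_scores), n_neg = length(neg_scores)),
    class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("AUC %.4f  AUPR %.4f  accuracy %.4f  (%d pos / %d neg)\n",
              x$auc, x$aupr, x$accuracy, x$n_pos, x$n_neg))
  invisible(x)
}

#' k-fold cross-validation of the full pipeline
#'
#' Pairs are partitioned into `k` near-equal folds; for each fold the model
#' is trained on the remaining pairs and evaluated on the fold. The summary
#' is the arithmetic mean of the per-fold metrics.
#'
#' @param table an [association_table()].
#' @param config a [model_config()].
#' @param tconfig a [train_config()].
#' @param k number of folds (default 5).
#' @param seed seed for the fold partition.
#' @param neg_policy negative policy passed to [evaluate_split()].
#' @param verbose print per-fold progress.
#' @return An object of class `cv_result`: data frame `folds` (fold, auc,
#'   aupr, accuracy) and list `mean`.
#' @export
cross_validate <- function(table, config = model_config(),
                           tconfig = train_config(), k = 5L, seed = 1L,
                           neg_policy = "all_unobserved", verbose = FALSE) {
  plan <- make_folds(table, k = k, seed = seed)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    test_idx <- plan$folds[[i]]
    train_idx <- sort(unlist(plan$folds[-i]))
    g_train <- build_graph(table, train_idx)
    tc <- tconfig
    tc$seed <- (tconfig$seed + i - 1L) %% .Machine$integer.max
    fit <- train_model(g_train, config, tc, table = table)
    test_pairs <- as.matrix(table$pairs[test_idx, c("snorna_idx", "disease_idx")])
    res <- evaluate_split(fit, test_pairs, neg_policy = neg_policy,
                          seed = seed, graph = g_train)
    rows[[i]] <- data.frame(fold = i, auc = res$auc, aupr = res$aupr,
                            accuracy = res$accuracy)
    if (verbose)
      message(sprintf("fold %d: AUC %.4f AUPR %.4f acc %.4f",
                      i, res$auc, res$aupr, res$accuracy))
  }
  folds <- do.call(rbind, rows)
  structure(
    list(folds = folds,
         mean = list(auc = mean(folds$auc), aupr = mean(folds$aupr),
                     accuracy = mean(folds$accuracy)),
         k = k, seed = seed),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV: mean AUC %.4f  AUPR %.4f  accuracy %.4f\n",
              x$k, x$mean$auc, x$mean$aupr, x$mean$accuracy))
  invisible(x)
}

#' Noise-sensitivity experiment
#'
#' Runs a clean baseline plus one perturbed run per (fraction, target)
#' combination: spurious positives equal to `fraction` of the full pair count
#' are injected into either the training or the test partition, the model is
#' retrained, and the usual metrics recomputed. For test-side noise the audit
#' column reports the fraction of injected (known-false) pairs whose sigmoid
#' score falls below 0.5 - the model's ability to keep noise below the
#' decision threshold.
#'
#' @param table an [association_table()].
#' @param config a [model_config()].
#' @param tconfig a [train_config()].
#' @param fractions noise fractions (default `c(0.01, 0.05)`).
#' @param targets partitions to perturb (default both).
#' @param ratio train fraction of the base split.
#' @param seed seed for the split and injections.
#' @param verbose print progress.
#' @return Data frame with one row per condition: `condition`, `fraction`,
#'   `target`, `auc`, `aupr`, `accuracy`, `audit` (NA unless test-target).
#' @export
noise_sensitivity <- function(table, config = model_config(),
                              tconfig = train_config(),
                              fractions = c(0.01, 0.05),
                              targets = c("train", "test"),
                              ratio = 0.8, seed = 1L, verbose = FALSE) {
  plan <- split_pairs(table, ratio = ratio, seed = seed)
  run_one <- function(tab, pl, label, fraction, target, injected) {
    g_train <- build_graph(tab, pl$train)
    fit <- train_model(g_train, config, tconfig, table = tab)
    test_pairs <- as.matrix(tab$pairs[pl$test, c("snorna_idx", "disease_idx")])
    res <- evaluate_split(fit, test_pairs, seed = seed, graph = g_train)
    audit <- NA_real_
    if (length(injected) > 0 && target == "test") {
      S <- score_all(fit$e_r, fit$e_d)
      inj <- as.matrix(tab$pairs[injected, c("snorna_idx", "disease_idx")])
      audit <- mean(plogis(S[cbind(inj[, 1], inj[, 2])]) < 0.5)
    }
    if (verbose)
      message(sprintf("%s: AUC %.4f AUPR %.4f acc %.4f",
                      label, res$auc, res$aupr, res$accuracy))
    data.frame(condition = label, fraction = fraction, target = target,
               auc = res$auc, aupr = res$aupr, accuracy = res$accuracy,
               audit = audit, stringsAsFactors = FALSE)
  }
  out <- list(run_one(table, plan, "baseline", 0, NA_character_, integer(0)))
  for (target in targets) for (fraction in fractions) {
    np <- inject_noise(table, fraction, target = target, plan = plan,
                       seed = seed + round(1000 * fraction) +
                         1000L * (target == "test"))
    out[[length(out) + 1L]] <- run_one(
      np$table, np$plan,
      sprintf("%s_%g", target, 100 * fraction),
      fraction, target, np$injected)
  }
  do.call(rbind, out)
}

#' Rank candidate snoRNAs for a disease
#'
#' All snoRNAs without a known training association to the query disease,
#' sorted by predicted score in decreasing order (ties broken by snoRNA
#' index; stable).
#'
#' @param model an [train_model()] result holding a `table`.
#' @param disease disease name.
#' @param top_n number of candidates to return (default 10; truncated to the
#'   number available).
#' @return Data frame of class `ranked_predictions`: `rank`, `snorna`,
#'   `disease`, `score`.
#' @export
rank_candidates <- function(model, disease, top_n = 10L) {
  table <- model$table
  if (is.null(table))
    stop("model carries no association_table; pass table= to train_model()")
  d <- match(disease, table$diseases)
  if (is.na(d)) {
    close <- agrep(disease, table$diseases, max.distance = 0.3, value = TRUE)
    stop(sprintf("unknown disease '%s'%s", disease,
                 if (length(close) > 0)
                   paste0("; did you mean: ",
                          paste(head(close, 5), collapse = ", "))
                 else ""))
  }
  known <- model$graph$nbrs_of_disease[[d]]
  cand <- setdiff(seq_len(table$N), known)
  if (length(cand) == 0) stop("no candidate snoRNAs for this disease")
  sc <- score_pairs(model$e_r, model$e_d, cand, rep(d, length(cand)))
  ord <- order(-sc, cand)
  keep <- head(ord, top_n)
  out <- data.frame(rank = seq_along(keep),
                    snorna = table$snornas[cand[keep]],
                    disease = table$diseases[d],
                    score = sc[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_predictions", "data.frame")
  out
}
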