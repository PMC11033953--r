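test_that("AUC matches the pairwise-comparison definition", {
  expect_equal(auc_score(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_equal(auc_score(rep(0.3, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_equal(auc_score(c(0.8, 0.2, 0.6, 0.4), c(1, 0, 0, 1)), 0.75)
  expect_error(auc_score(c(1, 2), c(1, 1)), "negative")

  for (seed in 1:20) {
    n <- withr::with_seed(seed, sample(5:50, 1))
    scores <- withr::with_seed(seed + 100, round(rnorm(n), 1)) # forces ties
    labels <- withr::with_seed(seed + 200, rbinom(n, 1, 0.4))
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(auc_score(scores, labels), auc_brute(scores, labels))
  }
})

test_that("AUC agrees with an independent library implementation", {
  for (seed in 1:5) {
    scores <- withr::with_seed(seed, rnorm(40))
    labels <- withr::with_seed(seed + 50, rbinom(40, 1, 0.5))
    if (sum(labels) %in% c(0, 40)) next
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_score(scores, labels), ref, tolerance = 1e-10)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  scores <- withr::with_seed(3, rnorm(30))
  labels <- withr::with_seed(4, rbinom(30, 1, 0.5))
  a <- auc_score(scores, labels)
  expect_equal(auc_score(exp(scores), labels), a)
  expect_equal(auc_score(3 * scores - 7, labels), a)
})

test_that("AUPR is 1 for perfect separation and at least the prevalence", {
  expect_equal(aupr_score(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  for (seed in 1:10) {
    scores <- withr::with_seed(seed, rnorm(40))
    labels <- withr::with_seed(seed + 30, rbinom(40, 1, 0.3))
    if (sum(labels) %in% c(0, 40)) next
    prevalence <- mean(labels)
    # AP of the best single retrieval is >= prevalence for any ranking that
    # puts one positive first; random rankings hover around the prevalence
    expect_gte(aupr_score(labels + scores * 1e-9, labels), prevalence)
  }
})

test_that("accuracy thresholds the sigmoid of the score", {
  expect_equal(accuracy_score(c(2, -3, 1, -1), c(1, 0, 0, 1)), 0.5)
  expect_equal(accuracy_score(c(5, -5), c(1, 0)), 1)
})

test_that("evaluation excludes train and test cells from the negatives", {
  tab <- random_table(8, 6, 0.3, seed = 12)
  plan <- split_pairs(tab, 0.7, seed = 1)
  g <- build_graph(tab, plan$train)
  emb <- init_embeddings(tab$N, tab$M, 4, seed = 1)
  tp <- as.matrix(tab$pairs[plan$test, c("snorna_idx", "disease_idx")])
  res <- evaluate_split(list(e_r = emb$snorna, e_d = emb$disease), tp,
                        graph = g)
  expect_equal(res$n_neg,
               tab$N * tab$M - length(plan$train) - length(plan$test))
  expect_equal(res$n_pos, length(plan$test))

  bal <- evaluate_split(list(e_r = emb$snorna, e_d = emb$disease), tp,
                        neg_policy = "balanced", seed = 5, graph = g)
  expect_equal(bal$n_neg, bal$n_pos)
  bal2 <- evaluate_split(list(e_r = emb$snorna, e_d = emb$disease), tp,
                         neg_policy = "balanced", seed = 5, graph = g)
  expect_identical(bal$auc, bal2$auc)
})

test_that("cross-validation averages per-fold metrics without leakage", {
  sim <- generate_planted(2, 5, 4, 0.8, 0.05, seed = 15)
  cv <- cross_validate(sim$table, model_config(L = 8, n_subgraphs = 2, seed = 1),
                       train_config(epochs = 30, seed = 1), k = 3, seed = 2)
  expect_equal(nrow(cv$folds), 3)
  expect_equal(cv$mean$auc, mean(cv$folds$auc))
  expect_equal(cv$mean$aupr, mean(cv$folds$aupr))
  plan <- make_folds(sim$table, k = 3, seed = 2)
  for (i in 1:3)
    expect_length(intersect(plan$folds[[i]],
                            unlist(plan$folds[-i])), 0)
})

test_that("candidate ranking excludes known edges and follows score order", {
  sim <- generate_planted(2, 6, 4, 0.9, 0.1, seed = 17)
  g <- build_graph(sim$table)
  fit <- train_model(g, model_config(L = 8, n_subgraphs = 2, seed = 1),
                     train_config(epochs = 30, seed = 1), table = sim$table)
  dname <- sim$table$diseases[1]
  d <- 1L
  ranked <- rank_candidates(fit, dname, top_n = 1000)
  known <- fit$graph$nbrs_of_disease[[d]]
  expect_length(intersect(match(ranked$snorna, sim$table$snornas), known), 0)
  expect_equal(nrow(ranked), sim$table$N - length(known))
  expect_true(all(diff(ranked$score) <= 0))
  S <- score_all(fit$e_r, fit$e_d)
  expect_equal(ranked$score[1],
               max(S[setdiff(seq_len(sim$table$N), known), d]))
  top3 <- rank_candidates(fit, dname, top_n = 3)
  expect_equal(top3, ranked[1:3, ], ignore_attr = TRUE)
  expect_error(rank_candidates(fit, "no-such-disease"), "unknown disease")
})
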