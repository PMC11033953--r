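test_that("triplet negatives avoid the sampled snoRNA's known diseases", {
  tab <- association_table(c("r0", "r1"), c("d0", "d1"))
  g <- build_graph(tab)
  trip <- sample_triplets(g, 1, seed = 1)
  expect_equal(trip$neg[trip$snorna == 1], 2L) # only free disease
  expect_equal(trip$neg[trip$snorna == 2], 1L)

  trip2 <- sample_triplets(g, 2, seed = 1)
  expect_equal(nrow(trip2), 2 * nrow(g$edges))

  for (seed in 1:5) {
    tabr <- random_table(10, 8, 0.3, seed = seed)
    gr <- build_graph(tabr)
    tr <- sample_triplets(gr, 1, seed = seed)
    expect_equal(nrow(tr), nrow(gr$edges))
    for (i in seq_len(nrow(tr)))
      expect_false(tr$neg[i] %in% gr$nbrs_of_snorna[[tr$snorna[i]]])
  }
})

test_that("negative sampling is uniform over the complement", {
  # r1 has one disease of six; negatives must be uniform over the other five
  tab <- association_table(c("r1", "r2", "r2", "r2", "r2", "r2"),
                           c("d1", "d2", "d3", "d4", "d5", "d6"))
  g <- build_graph(tab)
  draws <- withr::with_seed(7, {
    unlist(lapply(1:2000, function(i) {
      tr <- sample_triplets(g, 1)
      tr$neg[tr$snorna == 1]
    }))
  })
  tabled <- table(factor(draws, levels = 2:6))
  chi <- suppressWarnings(chisq.test(tabled))
  expect_gt(chi$p.value, 1e-4)
})

test_that("snoRNAs linked to every disease are skipped with a warning", {
  tab <- association_table(c("r0", "r0", "r1"), c("d0", "d1", "d0"))
  g <- build_graph(tab)
  expect_warning(trip <- sample_triplets(g, 1, seed = 1), "skipped")
  expect_false(1 %in% trip$snorna)
})

test_that("BPR loss matches its closed forms", {
  expect_equal(bpr_loss(c(1, 2, 3), c(1, 2, 3)), log(2))
  expect_equal(bpr_loss(1, 0), -log(plogis(1)), tolerance = 1e-12)
  expect_equal(bpr_loss(1, 0), 0.3132617, tolerance = 1e-6)
  # saturated ranking leaves only the regularization term
  expect_equal(bpr_loss(1e4, 0, reg_term = 2.5, lambda = 0.1), 0.25,
               tolerance = 1e-8)
  # invariant under adding a constant to both scores
  sp <- rnorm(20); sn <- rnorm(20)
  expect_equal(bpr_loss(sp, sn), bpr_loss(sp + 5, sn + 5))
})

test_that("training reduces the loss on planted structure", {
  sim <- generate_planted(2, 6, 5, 0.8, 0.05, seed = 3)
  g <- build_graph(sim$table)
  fit <- train_model(g, model_config(L = 16, n_subgraphs = 2, seed = 3),
                     train_config(epochs = 50, seed = 3), table = sim$table)
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
})

test_that("zero epochs returns the initial parameters", {
  sim <- generate_planted(2, 4, 3, 0.9, 0.05, seed = 4)
  g <- build_graph(sim$table)
  cfg <- model_config(L = 8, n_subgraphs = 2, seed = 5)
  fit <- train_model(g, cfg, train_config(epochs = 0, seed = 5))
  expect_identical(fit$params, init_model_params(g$N, g$M, cfg))
  expect_equal(nrow(fit$history), 0)
})

test_that("strong regularization shrinks embedding norms", {
  sim <- generate_planted(2, 5, 4, 0.8, 0.05, seed = 6)
  g <- build_graph(sim$table)
  cfg <- model_config(L = 8, n_subgraphs = 2, seed = 6)
  n_free <- sum(train_model(g, cfg, train_config(epochs = 100, lambda = 0,
                                                 seed = 6))$params$E_r^2)
  n_reg <- sum(train_model(g, cfg, train_config(epochs = 100, lambda = 1000,
                                                seed = 6))$params$E_r^2)
  expect_lt(n_reg, n_free)
})

test_that("training is bit-reproducible under fixed seeds", {
  sim <- generate_planted(2, 4, 4, 0.8, 0.05, seed = 8)
  g <- build_graph(sim$table)
  cfg <- model_config(L = 8, n_subgraphs = 2, seed = 2)
  tc <- train_config(epochs = 25, seed = 2)
  f1 <- train_model(g, cfg, tc)
  f2 <- train_model(g, cfg, tc)
  expect_identical(f1$e_r, f2$e_r)
  expect_identical(f1$history, f2$history)
})

test_that("mini-batch training runs and records finite losses", {
  sim <- generate_planted(2, 4, 4, 0.8, 0.05, seed = 9)
  g <- build_graph(sim$table)
  fit <- train_model(g, model_config(L = 8, n_subgraphs = 2, seed = 1),
                     train_config(epochs = 10, batch_size = 8, seed = 1))
  expect_true(all(is.finite(fit$history$loss)))
})

test_that("early stopping restores the best validation parameters", {
  sim <- generate_planted(2, 6, 5, 0.9, 0.02, seed = 10)
  tab <- sim$table
  plan <- split_pairs(tab, 0.8, seed = 10)
  g <- build_graph(tab, plan$train)
  vp <- as.matrix(tab$pairs[plan$test, c("snorna_idx", "disease_idx")])
  fit <- train_model(g, model_config(L = 8, n_subgraphs = 2, seed = 1),
                     train_config(epochs = 60, eval_every = 10, patience = 20,
                                  seed = 1),
                     val_pairs = vp)
  expect_true(any(is.finite(fit$history$val_auc)))
})
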