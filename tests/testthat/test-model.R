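test_that("embedding initialization has the right shape, seed and scale", {
  e <- init_embeddings(3, 2, 4, seed = 7)
  expect_equal(dim(e$snorna), c(3, 4))
  expect_equal(dim(e$disease), c(2, 4))
  expect_identical(e, init_embeddings(3, 2, 4, seed = 7))
  expect_false(identical(e, init_embeddings(3, 2, 4, seed = 8)))

  big <- init_embeddings(500, 500, 100, seed = 1)
  m <- mean(c(big$snorna, big$disease))
  expect_lt(abs(m), 3 * 0.1 / sqrt(2 * 500 * 100)) # 3 s.e. of the mean
})

test_that("first-order propagation aggregates normalized neighbor embeddings", {
  tab <- association_table("r0", "d0")
  g <- build_graph(tab)
  e <- init_embeddings(1, 1, 3, seed = 1)
  p1 <- propagate_first_order(e$snorna, e$disease, g)
  expect_equal(p1$snorna[1, ], e$disease[1, ])
  expect_equal(p1$disease[1, ], e$snorna[1, ])

  # r0 ~ {d0, d1}, deg(d0) = 1, deg(d1) = 2 via a second snoRNA
  tab2 <- association_table(c("r0", "r0", "r1"), c("d0", "d1", "d1"))
  g2 <- build_graph(tab2)
  e2 <- init_embeddings(2, 2, 3, seed = 2)
  p2 <- propagate_first_order(e2$snorna, e2$disease, g2)
  expect_equal(p2$snorna[1, ],
               e2$disease[1, ] / sqrt(2) + e2$disease[2, ] / 2)

  g0 <- build_graph(tab2, integer(0))
  p0 <- propagate_first_order(e2$snorna, e2$disease, g0)
  expect_true(all(p0$snorna == 0) && all(p0$disease == 0))
})

test_that("first-order propagation equals the dense normalized-adjacency product", {
  for (seed in 1:10) {
    tab <- random_table(9, 7, 0.25, seed = seed)
    g <- build_graph(tab)
    e <- init_embeddings(g$N, g$M, 5, seed = seed)
    p1 <- propagate_first_order(e$snorna, e$disease, g)
    A <- as.matrix(g$adj)
    Dr <- ifelse(g$deg_snorna > 0, 1 / sqrt(g$deg_snorna), 0)
    Dd <- ifelse(g$deg_disease > 0, 1 / sqrt(g$deg_disease), 0)
    Ahat <- diag(Dr, g$N) %*% A %*% diag(Dd, g$M)
    expect_equal(p1$snorna, Ahat %*% e$disease, tolerance = 1e-12)
    expect_equal(p1$disease, t(Ahat) %*% e$snorna, tolerance = 1e-12)
  }
})

test_that("feature fusion applies LeakyReLU to the fused linear map", {
  e0 <- matrix(c(1, 2, 3, 4), 2, 2)
  e1 <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
  I2 <- diag(2)
  expect_equal(fuse_features(e0, e1, I2, c(0, 0)), e0 + e1)

  # negative pre-activations scale by the slope
  eneg <- matrix(c(-1, -2, 3, 4), 2, 2)
  F <- fuse_features(eneg, 0 * eneg, I2, c(0, 0), leaky_slope = 0.1)
  expect_equal(F[, 1], c(-0.1, -0.2))
  expect_equal(F[, 2], c(3, 4))

  expect_equal(fuse_features(0 * e0, 0 * e1, I2, c(0, 0)), 0 * e0)
})

test_that("subgraph assignment takes the argmax with lowest-index ties", {
  # W2 = 0 makes H constant; choose W3, b3 so O is the bias row
  params <- list(W2 = matrix(0, 2, 3), b2 = c(0, 0),
                 W3 = matrix(0, 3, 2), b3 = c(0.1, 0.9, 0.3))
  F <- matrix(rnorm(12), 4, 3)
  a <- assign_subgraphs(F, params, mode = "hard")
  expect_equal(a$hard, rep(2L, 4))
  expect_null(a$soft)

  params$b3 <- c(0.5, 0.5, 0.2)
  a2 <- assign_subgraphs(F, params, mode = "straight_through")
  expect_equal(a2$hard, rep(1L, 4)) # tie broken toward the lowest index
  expect_equal(rowSums(a2$soft), rep(1, 4))

  params1 <- list(W2 = matrix(rnorm(6), 2, 3), b2 = rnorm(2),
                  W3 = matrix(rnorm(2), 1, 2), b3 = rnorm(1))
  expect_equal(assign_subgraphs(F, params1)$hard, rep(1L, 4))
})

test_that("layer combination is the arithmetic mean and is linear", {
  l0 <- matrix(c(1, 0), 1, 2)
  l1 <- matrix(c(0, 1), 1, 2)
  l2 <- matrix(c(1, 1), 1, 2)
  expect_equal(combine_layers(list(l0)), l0)
  expect_equal(combine_layers(list(l0, l1, l2)), matrix(c(2, 2) / 3, 1, 2))
  expect_equal(combine_layers(list(3 * l0, 3 * l1, 3 * l2)),
               3 * combine_layers(list(l0, l1, l2)))
})

test_that("scores are inner products and score_all matches score_pairs", {
  expect_equal(score_pairs(matrix(c(1, 2), 1), matrix(c(3, 4), 1), 1, 1), 11)
  expect_equal(score_pairs(matrix(c(1, 2), 1), matrix(0, 1, 2), 1, 1), 0)
  er <- matrix(rnorm(12), 4, 3)
  ed <- matrix(rnorm(15), 5, 3)
  S <- score_all(er, ed)
  idx <- expand.grid(r = 1:4, d = 1:5)
  expect_equal(S[cbind(idx$r, idx$d)], score_pairs(er, ed, idx$r, idx$d))
})

test_that("forward is deterministic and satisfies cross-subgraph consistency", {
  tab <- random_table(12, 9, 0.25, seed = 6)
  g <- build_graph(tab)
  cfg <- model_config(L = 6, K = 3, n_subgraphs = 3, seed = 4)
  p <- init_model_params(g$N, g$M, cfg)
  fw1 <- sda_forward(p, g, cfg)
  fw2 <- sda_forward(p, g, cfg)
  expect_identical(fw1$e_r, fw2$e_r)
  expect_identical(fw1$e_d, fw2$e_d)
  # every high-order disease layer is the sum of its subgraph-local pieces
  for (j in 2:(cfg$K + 1))
    expect_equal(fw1$Y[[j]], Reduce(`+`, fw1$Yds[[j]]), tolerance = 1e-12)
})

test_that("relabeling nodes permutes the output embeddings identically", {
  tab <- random_table(10, 8, 0.3, seed = 11)
  g <- build_graph(tab)
  cfg <- model_config(L = 5, K = 2, n_subgraphs = 3, seed = 2)
  p <- random_params(g$N, g$M, cfg, seed = 3)
  fw <- sda_forward(p, g, cfg)

  pr <- withr::with_seed(1, sample.int(g$N))
  pd <- withr::with_seed(2, sample.int(g$M))
  g2 <- g
  g2$adj <- g$adj[pr, pd]
  g2$deg_snorna <- g$deg_snorna[pr]
  g2$deg_disease <- g$deg_disease[pd]
  p2 <- p
  p2$E_r <- p$E_r[pr, ]
  p2$E_d <- p$E_d[pd, ]
  fw2 <- sda_forward(p2, g2, cfg)
  expect_equal(fw2$e_r, fw$e_r[pr, ], tolerance = 1e-12)
  expect_equal(fw2$e_d, fw$e_d[pd, ], tolerance = 1e-12)
  expect_equal(fw2$assignment$hard, fw$assignment$hard[pr])
})

test_that("exported propagation steps reproduce the forward layers", {
  tab <- random_table(9, 6, 0.3, seed = 8)
  g <- build_graph(tab)
  cfg <- model_config(L = 4, K = 3, n_subgraphs = 2, seed = 5)
  p <- init_model_params(g$N, g$M, cfg)
  fw <- sda_forward(p, g, cfg)
  asg <- fw$assignment

  p1 <- propagate_first_order(p$E_r, p$E_d, g)
  expect_equal(p1$snorna, fw$X[[2]], tolerance = 1e-12)
  yds1 <- split_first_order(p$E_r, g, asg)
  expect_equal(yds1, fw$Yds[[2]], tolerance = 1e-12)
  expect_equal(Reduce(`+`, yds1), fw$Y[[2]], tolerance = 1e-12)
  ho <- propagate_high_order(fw$X[[2]], yds1, g, asg)
  expect_equal(ho$snorna, fw$X[[3]], tolerance = 1e-12)
  expect_equal(ho$disease_sub, fw$Yds[[3]], tolerance = 1e-12)
  expect_equal(ho$disease, fw$Y[[3]], tolerance = 1e-12)
  expect_error(propagate_high_order(fw$X[[2]], yds1[1], g, asg),
               "do not match")
})
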