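test_that("degree matrix holds adjacency row sums on the diagonal", {
  ones <- matrix(1, 3, 3)
  expect_equal(degree_matrix(ones), diag(c(3, 3, 3)))
  expect_equal(degree_matrix(diag(3)), diag(3))
  W <- random_network(7, seed = 41)
  expect_equal(diag(degree_matrix(W)), rowSums(W), tolerance = 1e-12)
})

test_that("hard objective matches zero-cut identities and the matrix oracle", {
  # two disconnected all-ones blocks: each ratio is 1, total = K per view
  W <- block_network(c(4, 4), within = 1, between = 0)
  lab <- block_labels(c(4, 4))
  expect_identical(minmax_objective(W, lab, 2), 2)
  expect_identical(minmax_objective(rep(list(W), 5), lab, 2), 10)

  views <- list(random_network(8, seed = 43), random_network(8, seed = 44))
  set.seed(45)
  lab <- sample(1:2, 8, replace = TRUE)
  lab[1] <- 1; lab[2] <- 2                 # keep both clusters nonempty
  expect_equal(minmax_objective(views, lab, 2),
               objective_oracle(views, lab, 2), tolerance = 1e-10)

  expect_error(minmax_objective(W, rep(1, 8), 2), "label")
})

test_that("ratio bound holds: objective >= m*K, equality iff zero cut", {
  for (s in 1:5) {
    views <- list(random_network(9, seed = 100 + s),
                  random_network(9, seed = 200 + s))
    set.seed(s)
    lab <- c(1, 2, sample(1:2, 7, replace = TRUE))
    obj <- minmax_objective(views, lab, 2)
    expect_gt(obj, 2 * 2)                 # random cuts are never zero
  }
  W <- block_network(c(3, 5), within = 1, between = 0)
  expect_equal(minmax_objective(list(W, W), block_labels(c(3, 5)), 2), 4)
})

test_that("exhaustive solver enumerates all partitions and finds zero cuts", {
  W <- random_network(4, seed = 51)
  ex <- minmax_cut_exhaustive(list(W), 2)
  expect_identical(ex$n_evaluated, 7L)     # Stirling S(4,2)
  expect_gte(ex$objective, 2)

  Wb <- block_network(c(3, 3), within = 1, between = 0)
  exb <- minmax_cut_exhaustive(list(Wb, Wb), 2)
  expect_equal(exb$objective, 4)           # m*K lower bound attained
  expect_equal(adjusted_rand_index(exb$assignment, block_labels(c(3, 3))), 1)

  expect_error(minmax_cut_exhaustive(list(random_network(16, seed = 1)), 2),
               "limited")
  expect_error(minmax_cut_exhaustive(list(W), 4), "limited")
})

test_that("solver recovers planted blocks across five views", {
  W <- block_network(c(5, 5), within = 1, between = 0.05)
  views <- rep(list(W), 5)
  fit <- minmax_cut(views, 2, seed = 3)
  expect_equal(adjusted_rand_index(fit$assignment, block_labels(c(5, 5))), 1)
  ex <- minmax_cut_exhaustive(list(W), 2)
  expect_equal(adjusted_rand_index(fit$assignment, ex$assignment), 1)
  expect_true(all(tabulate(fit$assignment, 2) > 0))
})

test_that("a single view in the multigraph solver equals the single-graph fit", {
  W <- random_network(10, seed = 61)
  fit_m <- minmax_cut(list(W), 3, seed = 2)
  fit_s <- minmax_cut_single(W, 3, seed = 2)
  expect_identical(fit_m$assignment, fit_s$assignment)
  expect_identical(fit_m$hard_objective, fit_s$hard_objective)
})

test_that("descent trace is non-increasing and Q stays orthonormal", {
  views <- list(random_network(12, seed = 71), random_network(12, seed = 72))
  fit <- minmax_cut(views, 3, seed = 5)
  expect_true(all(diff(fit$relaxed_trace) <= 1e-12))
  gram <- crossprod(fit$Q)
  expect_lt(max(abs(gram - diag(3))), 1e-6)
  expect_true(all(fit$Q >= -1e-6))
  expect_gte(fit$hard_objective, 2 * 3)
})

test_that("fixed seed gives identical assignments across repeated runs", {
  views <- list(random_network(10, seed = 81), random_network(10, seed = 82))
  f1 <- minmax_cut(views, 2, seed = 9)
  f2 <- minmax_cut(views, 2, seed = 9)
  expect_identical(f1$assignment, f2$assignment)
  expect_identical(f1$relaxed_trace, f2$relaxed_trace)
})

test_that("permuting SNP order permutes the recovered partition", {
  W <- block_network(c(4, 6), within = 1, between = 0.1)
  fit <- minmax_cut(list(W), 2, seed = 4)
  set.seed(4)
  perm <- sample(nrow(W))
  Wp <- W[perm, perm]
  fitp <- minmax_cut(list(Wp), 2, seed = 4)
  # same partition of the same nodes, up to cluster relabeling
  expect_equal(adjusted_rand_index(fit$assignment[perm], fitp$assignment), 1)
})

test_that("solver stays within 5% of the exhaustive optimum on random instances", {
  ratios <- vapply(1:8, function(s) {
    views <- list(random_network(8, seed = 300 + s),
                  random_network(8, seed = 400 + s))
    fit <- minmax_cut(views, 2, seed = s)
    ex <- minmax_cut_exhaustive(views, 2)
    fit$hard_objective / ex$objective
  }, numeric(1))
  expect_true(all(ratios >= 1 - 1e-12))    # exhaustive is a true lower bound
  expect_true(all(ratios <= 1.05))
})

test_that("degenerate solver inputs are rejected", {
  W <- random_network(5, seed = 91)
  expect_error(minmax_cut(list(W), 6, seed = 1), "exceed")
  expect_error(minmax_cut(list(W), 1, seed = 1), "k must satisfy")
  expect_error(minmax_cut(list(W, random_network(6, seed = 92)), 2, seed = 1),
               "identical dimension")
})
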