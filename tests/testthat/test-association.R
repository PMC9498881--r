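test_that("noiseless fixture recovers the additive effect exactly", {
  fx <- tiny_regression_fixture(beta = 2, intercept = 5, noise_sd = 0)
  fit <- fit_snp_qt(fx$genotypes, fx$phenotypes, "snpA", "ROI_1", fx$cohort)
  expect_equal(fit$alpha, 2, tolerance = 1e-8)
  expect_identical(fit$n_used, nrow(fx$genotypes))
})

test_that("results are invariant to phenotype row order", {
  fx <- tiny_regression_fixture(noise_sd = 1, seed = 7)
  fit1 <- fit_snp_qt(fx$genotypes, fx$phenotypes, "snpA", "ROI_1", fx$cohort)
  perm <- fx$phenotypes[sample(nrow(fx$phenotypes)), ]
  attr(perm, "roi_ids") <- "ROI_1"
  fit2 <- fit_snp_qt(fx$genotypes, perm, "snpA", "ROI_1", fx$cohort)
  expect_equal(fit1, fit2, tolerance = 1e-12)
})

test_that("alpha and p-value match the closed-form OLS oracle", {
  set.seed(42)
  for (rep in 1:25) {
    n <- 200
    g <- stats::rbinom(n, 2, runif(1, 0.1, 0.5))
    if (stats::var(g) == 0) next
    age <- stats::rnorm(n, 75, 6); sex <- stats::rbinom(n, 1, 0.5)
    edu <- stats::rnorm(n, 16, 2)
    y <- 0.3 * g + 0.01 * age - 0.05 * sex + stats::rnorm(n)
    ids <- sprintf("s%03d", 1:n)
    G <- matrix(as.integer(g), ncol = 1, dimnames = list(ids, "snpA"))
    phen <- data.frame(subject_id = ids, diagnosis = "case", age = age,
                       sex = sex, education = edu, ROI_1 = y,
                       stringsAsFactors = FALSE)
    fit <- fit_snp_qt(G, phen, "snpA", "ROI_1",
                      cohort_spec("all", "case", "none"))
    oracle <- ols_oracle(y, cbind(1, g, age, sex, edu))
    expect_equal(fit$alpha, oracle$beta[2], tolerance = 1e-8)
    expect_equal(fit$p_value, oracle$p[2], tolerance = 1e-8)
  }
})

test_that("missing dosages are dropped pairwise per SNP", {
  fx <- tiny_regression_fixture(noise_sd = 1, seed = 3)
  G <- fx$genotypes
  G[1:5, "snpA"] <- NA
  fit <- fit_snp_qt(G, fx$phenotypes, "snpA", "ROI_1", fx$cohort)
  expect_identical(fit$n_used, nrow(G) - 5L)
  # equals fitting on the complete subset directly
  keep <- rownames(G)[-(1:5)]
  sub_phen <- fx$phenotypes[fx$phenotypes$subject_id %in% keep, ]
  attr(sub_phen, "roi_ids") <- "ROI_1"
  fit2 <- fit_snp_qt(fx$genotypes[keep, , drop = FALSE], sub_phen,
                     "snpA", "ROI_1", fx$cohort)
  expect_equal(fit$alpha, fit2$alpha, tolerance = 1e-12)
})

test_that("degenerate and zero-variance fits are flagged, not fatal maps", {
  fx <- tiny_regression_fixture(n = 30, noise_sd = 1, seed = 5)
  G0 <- fx$genotypes
  G0[, "snpA"] <- 1L                     # zero-variance dosage
  fit <- fit_snp_qt(G0, fx$phenotypes, "snpA", "ROI_1", fx$cohort)
  expect_identical(fit$flag, "zero_variance_dosage")
  expect_identical(fit$p_value, 1)
  expect_warning(
    amap <- association_map(G0, fx$phenotypes, fx$cohort),
    "zero_variance")
  expect_true(all(amap["snpA", ] == 0))  # p = 1 pair -> entry 0

  tiny <- tiny_regression_fixture(n = 4, noise_sd = 1, seed = 6)
  expect_error(fit_snp_qt(tiny$genotypes, tiny$phenotypes, "snpA", "ROI_1",
                          tiny$cohort),
               "degenerate")
})

test_that("association maps have the right shape and nonnegative entries", {
  cfg <- simulation_config(n_subjects = 80, n_snps = 2, n_rois = 3,
                           n_clusters = 2, seed = 13)
  coh <- simulate_cohort(cfg)
  phen <- coh$phenotypes
  attr(phen, "roi_ids") <- sprintf("ROI_%d", 1:3)
  amap <- association_map(coh$genotypes, phen,
                          cohort_spec("all", c("AD", "LMCI", "EMCI"), "HC"))
  expect_identical(dim(amap), c(2L, 3L))
  expect_true(all(amap >= 0))
})

test_that("null SNP-QT pairs give -log10 Uniform(0,1) distributed entries", {
  # Under the null the regression p-values are Uniform(0,1); compare the
  # back-transformed map entries with uniformity by a KS test at alpha 0.01.
  set.seed(21)
  n <- 150; n_roi <- 150
  ids <- sprintf("s%03d", 1:n)
  G <- matrix(as.integer(stats::rbinom(n, 2, 0.3)), ncol = 1,
              dimnames = list(ids, "snpA"))
  Y <- matrix(stats::rnorm(n * n_roi), n, n_roi,
              dimnames = list(NULL, sprintf("ROI_%d", 1:n_roi)))
  phen <- data.frame(subject_id = ids, diagnosis = "case",
                     age = stats::rnorm(n, 75, 6),
                     sex = stats::rbinom(n, 1, 0.5),
                     education = stats::rnorm(n, 16, 2), Y,
                     check.names = FALSE, stringsAsFactors = FALSE)
  attr(phen, "roi_ids") <- colnames(Y)
  amap <- association_map(G, phen, cohort_spec("all", "case", "none"))
  pvals <- 10^(-amap["snpA", ])
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("row normalization yields unit vectors and flags zero rows", {
  m <- rbind(a = c(3, 4, 0), b = c(0, 0, 0), c = c(1, 1, 1))
  colnames(m) <- paste0("ROI_", 1:3)
  amap <- snpmincut:::new_association_map(m)
  nm <- normalize_rows(amap)
  expect_equal(unname(nm["a", ]), c(0.6, 0.8, 0), tolerance = 1e-12)
  expect_equal(unname(nm["b", ]), c(0, 0, 0))
  expect_identical(attr(nm, "zero_rows"), "b")
  norms <- sqrt(rowSums(unclass(nm)[c("a", "c"), ]^2))
  expect_equal(unname(norms), c(1, 1), tolerance = 1e-12)
  expect_true(attr(nm, "normalized"))
})
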