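test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_snps = 6, n_rois = 10, n_clusters = 2,
                                 roi_signatures = list(1:3, 3:5)),
               "disjoint")
  expect_error(simulation_config(n_snps = 6, n_rois = 10,
                                 cluster_memberships = list(1:6, integer(0)),
                                 roi_signatures = list(1:2, 3:4)),
               "nonempty")
  expect_error(simulation_config(n_snps = 6, n_rois = 10,
                                 cluster_memberships = list(1:3, 3:6),
                                 roi_signatures = list(1:2, 3:4)),
               "partition")
  expect_error(simulation_config(group_proportions = c(a = 0.5, b = 0.6)),
               "sum to 1")
  expect_error(simulation_config(maf_range = c(0.4, 0.2)), "maf_range")
})

test_that("cohorts have the planted structure and valid genotypes", {
  cfg <- simulation_config(n_subjects = 40, n_snps = 6, n_rois = 10,
                           n_clusters = 2, seed = 11)
  coh <- simulate_cohort(cfg)
  expect_length(unique(coh$true_labels), 2)
  expect_true(all(coh$genotypes %in% c(0L, 1L, 2L)))
  expect_true(all(coh$phenotypes$diagnosis %in%
                    names(cfg$group_proportions)))
  expect_identical(dim(coh$genotypes), c(40L, 6L))
  expect_length(attr(coh$phenotypes, "roi_ids"), 0L)  # raw data frame
  expect_identical(ncol(coh$phenotypes), 5L + 10L)
})

test_that("fixed seed reproduces the cohort exactly", {
  cfg <- simulation_config(n_subjects = 30, n_snps = 8, n_rois = 12,
                           seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$true_labels, b$true_labels)
})

test_that("noiseless zero-covariate limit is an exact linear function of burden", {
  cfg <- simulation_config(n_subjects = 50, n_snps = 6, n_rois = 10,
                           n_clusters = 2, effect_size = 1.5, noise_sd = 0,
                           covariate_effects = c(age = 0, sex = 0,
                                                 education = 0),
                           seed = 2)
  coh <- simulate_cohort(cfg)
  for (c in seq_along(cfg$cluster_memberships)) {
    burden <- rowSums(coh$genotypes[, cfg$cluster_memberships[[c]],
                                    drop = FALSE])
    for (r in cfg$roi_signatures[[c]]) {
      expect_equal(coh$phenotypes[[paste0("ROI_", r)]],
                   unname(1.5 * burden), tolerance = 1e-12)
    }
  }
  # ROIs outside every signature are exactly zero in this limit
  outside <- setdiff(seq_len(10), unlist(cfg$roi_signatures))
  for (r in outside) {
    expect_true(all(coh$phenotypes[[paste0("ROI_", r)]] == 0))
  }
})

test_that("empirical allele frequencies match the binomial sampling model", {
  # Binomial oracle: freq_hat = mean(g)/2, sd ~ sqrt(p(1-p)/(2n)) = 0.0046
  # at p = 0.3, n = 5000, so the 0.02 band is > 4 sd per SNP.
  cfg <- simulation_config(n_subjects = 5000, n_snps = 20, n_rois = 4,
                           n_clusters = 2, maf_range = c(0.3, 0.3), seed = 9)
  coh <- simulate_cohort(cfg)
  freqs <- colMeans(coh$genotypes) / 2
  expect_true(all(abs(freqs - 0.3) < 0.02))
})

test_that("simulated association maps respect signal and noise settings", {
  memb <- list(1:3, 4:6)
  m0 <- simulate_association_map(6, 10, memb, signal = 0, noise_sd = 1,
                                 seed = 4)
  expect_true(all(m0 >= 0))
  expect_identical(dim(m0), c(6L, 10L))

  noiseless <- simulate_association_map(6, 10, memb, signal = 2,
                                        noise_sd = 0, seed = 4)
  expect_equal(noiseless[1, ], noiseless[2, ], tolerance = 0)
  expect_equal(noiseless[4, ], noiseless[6, ], tolerance = 0)
  expect_false(isTRUE(all.equal(noiseless[1, ], noiseless[4, ])))

  again <- simulate_association_map(6, 10, memb, signal = 2, noise_sd = 0,
                                    seed = 4)
  expect_identical(unclass(noiseless), unclass(again))

  noisy <- simulate_association_map(6, 10, memb, signal = 2, noise_sd = 0.5,
                                    seed = 8)
  noisy2 <- simulate_association_map(6, 10, memb, signal = 2, noise_sd = 0.5,
                                     seed = 8)
  expect_identical(unclass(noisy), unclass(noisy2))
})

test_that("cohort files round trip through the io layer", {
  cfg <- simulation_config(n_subjects = 25, n_snps = 5, n_rois = 6, seed = 3)
  coh <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  g_csv <- read_genotypes(paths[["genotypes_csv"]], "csv")
  g_raw <- read_genotypes(paths[["genotypes_raw"]], "plink_raw")
  expect_identical(g_csv, coh$genotypes)
  expect_identical(g_raw, coh$genotypes)
  phen <- read_phenotypes(paths[["phenotypes"]])
  expect_identical(attr(phen, "roi_ids"), sprintf("ROI_%d", 1:6))
  expect_equal(phen$age, coh$phenotypes$age, tolerance = 1e-12)
})
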