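#' Configuration for a synthetic imaging-genetics cohort
#'
#' Describes a cohort with planted SNP-cluster structure: SNPs are grouped
#' into clusters, each cluster is tied to a disjoint set of ROI columns
#' (its "signature"), and every signature ROI receives a genetic
#' contribution proportional to the summed allele count of the cluster's
#' SNPs. This emulates the shape of a candidate-variant imaging-genetics
#' study (additively coded genotypes, ROI-level quantitative traits,
#' age/sex/education covariates, diagnosis groups) without any linkage
#' structure or realistic brain covariance.
#'
#' @param n_subjects number of subjects.
#' @param n_snps number of SNPs (default 54, the candidate-panel size the
#'   pipeline is dimensioned for).
#' @param n_rois number of ROI quantitative traits (default 116, an
#'   AAL-atlas-sized panel).
#' @param n_clusters number of planted SNP clusters; ignored when
#'   `cluster_memberships` is given.
#' @param cluster_memberships optional list of integer vectors partitioning
#'   `1:n_snps` into nonempty clusters. Default: contiguous equal split.
#' @param roi_signatures optional list (one per cluster) of pairwise
#'   disjoint ROI index sets. Default: contiguous blocks of
#'   `floor(n_rois / (2 * n_clusters))` ROIs each, leaving the remaining
#'   ROIs signal-free.
#' @param effect_size QT units added per summed minor allele of the
#'   cluster, on that cluster's signature ROIs (default 1).
#' @param maf_range interval in (0, 0.5) from which each SNP's minor allele
#'   frequency is drawn uniformly. Default c(0.2, 0.45): common variants,
#'   as in real candidate panels of GWAS index SNPs. Under the burden
#'   model each SNP's marginal association strength is bounded by
#'   `n_subjects * var(g_j) / sum(var(g_j'))` over its cluster mates,
#'   whatever the effect size, so a cohort with genuinely strong per-SNP
#'   signal requires common alleles; rare variants (MAF near 0.05) are
#'   intrinsically weak marginally at realistic sample sizes.
#' @param noise_sd standard deviation of the Gaussian QT noise (default 1).
#' @param covariate_effects named numeric vector with elements `age`, `sex`,
#'   `education`: additive QT effect per covariate unit, applied to every
#'   ROI (default c(age = 0.02, sex = 0.1, education = -0.02)).
#' @param group_proportions named fractions over diagnosis labels, summing
#'   to 1. Default mirrors a typical case-control neuroimaging cohort:
#'   AD 0.208, LMCI 0.225, EMCI 0.305, HC 0.262.
#' @param seed integer seed; one seed drives all randomness in
#'   [simulate_cohort()].
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
simulation_config <- function(n_subjects = 500,
                              n_snps = 54,
                              n_rois = 116,
                              n_clusters = 2,
                              cluster_memberships = NULL,
                              roi_signatures = NULL,
                              effect_size = 1,
                              maf_range = c(0.2, 0.45),
                              noise_sd = 1,
                              covariate_effects = c(age = 0.02, sex = 0.1,
                                                    education = -0.02),
                              group_proportions = c(AD = 0.208, LMCI = 0.225,
                                                    EMCI = 0.305, HC = 0.262),
                              seed = 1L) {
  if (is.null(cluster_memberships)) {
    cluster_memberships <- split(seq_len(n_snps),
                                 cut(seq_len(n_snps), n_clusters, labels = FALSE))
    cluster_memberships <- lapply(cluster_memberships, as.integer)
  }
  n_clusters <- length(cluster_memberships)
  if (is.null(roi_signatures)) {
    block <- max(1L, n_rois %/% (2L * n_clusters))
    roi_signatures <- lapply(seq_len(n_clusters), function(c) {
      seq.int((c - 1L) * block + 1L, c * block)
    })
  }
  cfg <- structure(
    list(n_subjects = as.integer(n_subjects), n_snps = as.integer(n_snps),
         n_rois = as.integer(n_rois), n_clusters = n_clusters,
         cluster_memberships = cluster_memberships,
         roi_signatures = roi_signatures, effect_size = effect_size,
         maf_range = maf_range, noise_sd = noise_sd,
         covariate_effects = covariate_effects,
         group_proportions = group_proportions, seed = as.integer(seed)),
    class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  members <- sort(unlist(cfg$cluster_memberships, use.names = FALSE))
  if (any(lengths(cfg$cluster_memberships) == 0L)) {
    stop("configuration error: every planted cluster must be nonempty")
  }
  if (!identical(as.integer(members), seq_len(cfg$n_snps))) {
    stop("configuration error: cluster_memberships must partition 1:n_snps")
  }
  sig <- unlist(cfg$roi_signatures, use.names = FALSE)
  if (anyDuplicated(sig)) {
    stop("configuration error: roi_signatures must be pairwise disjoint")
  }
  if (length(cfg$roi_signatures) != cfg$n_clusters) {
    stop("configuration error: need one ROI signature per cluster")
  }
  if (any(sig < 1L) || any(sig > cfg$n_rois)) {
    stop("configuration error: roi_signatures outside 1:n_rois")
  }
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] > cfg$maf_range[2] ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5) {
    stop("configuration error: maf_range must lie within (0, 0.5]")
  }
  if (cfg$noise_sd < 0) stop("configuration error: noise_sd must be >= 0")
  if (abs(sum(cfg$group_proportions) - 1) > 1e-8) {
    stop("configuration error: group_proportions must sum to 1")
  }
  req <- c("age", "sex", "education")
  if (!all(req %in% names(cfg$covariate_effects))) {
    stop("configuration error: covariate_effects needs age, sex, education")
  }
  invisible(cfg)
}

#' Simulate a genotype/phenotype cohort with planted SNP clusters
#'
#' Genotypes are drawn per SNP as Binomial(2, MAF) allele counts with MAF
#' uniform in `maf_range`. Covariates follow fixed documented
#' distributions: age ~ Normal(75, 6), sex ~ Bernoulli(0.5),
#' education ~ Normal(16, 2). Each ROI in cluster c's signature receives
#' `effect_size * sum(genotypes of cluster c)` plus covariate effects plus
#' Normal(0, noise_sd) noise; ROIs outside every signature receive
#' covariates and noise only. Diagnosis labels are assigned independently
#' of genotype according to `group_proportions`. The whole draw is
#' reproducible from the single `seed` in the configuration.
#'
#' @param config a [simulation_config()] object.
#' @return A list of class `synthetic_cohort` with elements
#'   \item{genotypes}{subjects x SNPs integer matrix of dosages 0/1/2 with
#'     subject and SNP dimnames,}
#'   \item{phenotypes}{data frame with subject_id, diagnosis, age, sex,
#'     education, then one column per ROI (`ROI_1` ...),}
#'   \item{true_labels}{named integer vector, planted cluster per SNP,}
#'   \item{mafs}{the drawn minor allele frequencies.}
#' @examples
#' cfg <- simulation_config(n_subjects = 50, n_snps = 6, n_rois = 10,
#'                          n_clusters = 2, seed = 7)
#' coh <- simulate_cohort(cfg)
#' table(coh$true_labels)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  with_seed(config$seed, {
    n <- config$n_subjects
    snp_ids <- sprintf("snp%03d", seq_len(config$n_snps))
    subj_ids <- sprintf("subj%04d", seq_len(n))
    roi_ids <- sprintf("ROI_%d", seq_len(config$n_rois))

    mafs <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
    G <- vapply(mafs, function(p) stats::rbinom(n, 2L, p), integer(n))
    dimnames(G) <- list(subj_ids, snp_ids)

    age <- stats::rnorm(n, 75, 6)
    sex <- stats::rbinom(n, 1L, 0.5)
    education <- stats::rnorm(n, 16, 2)
    groups <- names(config$group_proportions)
    diagnosis <- sample(groups, n, replace = TRUE,
                        prob = config$group_proportions)

    ce <- config$covariate_effects
    base <- ce[["age"]] * age + ce[["sex"]] * sex + ce[["education"]] * education
    Y <- matrix(stats::rnorm(n * config$n_rois, 0, config$noise_sd),
                n, config$n_rois) + base
    for (c in seq_along(config$cluster_memberships)) {
      snps <- config$cluster_memberships[[c]]
      burden <- rowSums(G[, snps, drop = FALSE])
      Y[, config$roi_signatures[[c]]] <-
        Y[, config$roi_signatures[[c]], drop = FALSE] +
        config$effect_size * burden
    }
    colnames(Y) <- roi_ids

    labels <- integer(config$n_snps)
    for (c in seq_along(config$cluster_memberships)) {
      labels[config$cluster_memberships[[c]]] <- c
    }
    names(labels) <- snp_ids

    phen <- data.frame(subject_id = subj_ids, diagnosis = diagnosis,
                       age = age, sex = sex, education = education,
                       Y, check.names = FALSE, stringsAsFactors = FALSE)
    structure(list(genotypes = G, phenotypes = phen, true_labels = labels,
                   mafs = stats::setNames(mafs, snp_ids)),
              class = "synthetic_cohort")
  })
}

#' Simulate an association map with planted row clusters
#'
#' Direct fixture for the network-construction and clustering stages,
#' bypassing regression: rows in the same planted cluster share an
#' elevated-mean column pattern. ROI columns are split evenly among the
#' clusters; entries are `signal` (on the cluster's columns) plus
#' Normal(0, noise_sd) noise, floored at 0 so the result is a valid
#' nonnegative significance-map stand-in.
#'
#' @param n_snps,n_rois map dimensions.
#' @param cluster_memberships list of integer vectors partitioning
#'   `1:n_snps`.
#' @param signal elevated mean added on a cluster's own columns (>= 0).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return An unnormalized association map (see [association_map()] value).
#' @export
simulate_association_map <- function(n_snps, n_rois, cluster_memberships,
                                     signal, noise_sd, seed = 1L) {
  if (signal < 0) stop("signal must be >= 0")
  members <- sort(unlist(cluster_memberships, use.names = FALSE))
  if (!identical(as.integer(members), seq_len(n_snps))) {
    stop("cluster_memberships must partition 1:n_snps")
  }
  with_seed(seed, {
    K <- length(cluster_memberships)
    col_block <- split(seq_len(n_rois),
                      cut(seq_len(n_rois), K, labels = FALSE))
    M <- matrix(0, n_snps, n_rois)
    for (c in seq_len(K)) M[cluster_memberships[[c]], col_block[[c]]] <- signal
    X <- pmax(M + matrix(stats::rnorm(n_snps * n_rois, 0, noise_sd),
                         n_snps, n_rois), 0)
    dimnames(X) <- list(sprintf("snp%03d", seq_len(n_snps)),
                        sprintf("ROI_%d", seq_len(n_rois)))
    new_association_map(X, normalized = FALSE)
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes the genotype matrix as CSV and as a simplified PLINK-`.raw`-style
#' table (FID, IID, then one allele-count column per SNP), the phenotype
#' table as CSV, and the planted labels as a two-column TSV.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genotypes_csv = file.path(dir, "genotypes.csv"),
             genotypes_raw = file.path(dir, "genotypes.raw"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             labels = file.path(dir, "true_labels.tsv"))
  g <- data.frame(subject_id = rownames(cohort$genotypes),
                  cohort$genotypes, check.names = FALSE)
  utils::write.csv(g, paths[["genotypes_csv"]], row.names = FALSE, quote = FALSE)
  raw <- data.frame(FID = rownames(cohort$genotypes),
                    IID = rownames(cohort$genotypes),
                    cohort$genotypes, check.names = FALSE)
  utils::write.table(raw, paths[["genotypes_raw"]], sep = " ",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$phenotypes, paths[["phenotypes"]],
                   row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(snp_id = names(cohort$true_labels),
                                cluster = cohort$true_labels),
                     paths[["labels"]], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}
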