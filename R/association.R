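# Internal constructor: an association map is a nonnegative SNPs x ROIs
# matrix of -log10(p) values with a `normalized` flag.
new_association_map <- function(values, normalized = FALSE, zero_rows = NULL) {
  m <- as.matrix(values)
  if (any(m < 0)) stop("association map entries must be nonnegative")
  structure(m, normalized = normalized, zero_rows = zero_rows,
            class = c("association_map", class(m)))
}

#' @export
print.association_map <- function(x, ...) {
  cat(sprintf("Association map: %d SNPs x %d ROIs (-log10 p%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "normalized"))) ", rows unit-L2" else ""))
  invisible(x)
}

# Cohort subset of subjects with complete covariates present in both
# genotype and phenotype tables; alignment is by subject id, never order.
cohort_subjects <- function(genotypes, phenotypes, cohort) {
  keep <- phenotypes$diagnosis %in%
    c(cohort$case_labels, cohort$control_labels)
  ids <- intersect(phenotypes$subject_id[keep], rownames(genotypes))
  if (length(ids) == 0) stop("cohort '", cohort$name, "' matches no subjects")
  ids
}

# OLS of each ROI column in Y on [1, dosage, covariates] for one SNP,
# dropping subjects with missing dosage pairwise. Returns per-ROI alpha,
# se, p, n. The same code path backs fit_snp_qt and association_map so a
# single pair and the full map can never disagree.
fit_one_snp <- function(g, Z, Y) {
  ok <- !is.na(g)
  g <- g[ok]; Z <- Z[ok, , drop = FALSE]; Y <- Y[ok, , drop = FALSE]
  p <- 2L + ncol(Z)                      # intercept + dosage + covariates
  n <- length(g)
  out <- list(alpha = rep(NA_real_, ncol(Y)), se = rep(NA_real_, ncol(Y)),
              p_value = rep(1, ncol(Y)), n_used = n, flag = NULL)
  if (n < p + 1L) {
    out$flag <- "degenerate"
    return(out)
  }
  if (stats::var(g) == 0) {
    out$flag <- "zero_variance_dosage"
    return(out)
  }
  X <- cbind(`(Intercept)` = 1, dosage = g, Z)
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    out$flag <- "rank_deficient"
    return(out)
  }
  coefs <- qr.coef(qr_x, Y)
  res <- Y - X %*% coefs
  df <- n - p
  sigma2 <- colSums(res^2) / df
  xtx_inv_22 <- chol2inv(qr.R(qr_x))[2, 2]
  alpha <- coefs[2, ]
  se <- sqrt(sigma2 * xtx_inv_22)
  tt <- alpha / se
  pv <- 2 * stats::pt(-abs(tt), df)
  pv[se == 0] <- ifelse(alpha[se == 0] == 0, 1, 0)
  pv <- pmin(pmax(pv, 0), 1)
  out$alpha <- alpha; out$se <- se; out$p_value <- pv
  out
}

#' Covariate-adjusted association of one SNP with one imaging trait
#'
#' Ordinary least squares of the quantitative trait on
#' `[intercept, dosage, age, sex, education]` over the cohort's subjects
#' (cases and controls pooled). The reported p-value is the two-sided
#' t-test on the additive dosage coefficient. Subjects with missing dosage
#' for this SNP are dropped pairwise.
#'
#' @param genotypes matrix from [read_genotypes()] or a synthetic cohort.
#' @param phenotypes data frame from [read_phenotypes()].
#' @param snp_id,roi_id column names selecting the pair.
#' @param cohort a [cohort_spec()].
#' @param covariates covariate column names to adjust for.
#' @return List with `alpha` (additive effect), `alpha_se`, `p_value`,
#'   `n_used`, and `flag` (`NULL`, or e.g. `"zero_variance_dosage"`, in
#'   which case `p_value` is 1).
#' @export
fit_snp_qt <- function(genotypes, phenotypes, snp_id, roi_id, cohort,
                       covariates = c("age", "sex", "education")) {
  ids <- cohort_subjects(genotypes, phenotypes, cohort)
  ph <- phenotypes[match(ids, phenotypes$subject_id), , drop = FALSE]
  g <- genotypes[ids, snp_id]
  Z <- as.matrix(ph[, covariates, drop = FALSE])
  Y <- as.matrix(ph[, roi_id, drop = FALSE])
  fit <- fit_one_snp(g, Z, Y)
  if (identical(fit$flag, "degenerate")) {
    stop("degenerate fit: fewer usable subjects than model parameters for ",
         snp_id)
  }
  list(alpha = unname(fit$alpha[1]), alpha_se = unname(fit$se[1]),
       p_value = unname(fit$p_value[1]), n_used = fit$n_used,
       flag = fit$flag)
}

#' Build the SNP x ROI significance map for a cohort
#'
#' Runs the covariate-adjusted regression of [fit_snp_qt()] for every
#' (SNP, ROI) pair in the cohort and records `-log10(p)` per cell, capped
#' at 300 to guard against floating-point underflow of extreme p-values.
#' Per-pair failures (zero-variance dosage, rank deficiency) are recorded
#' as p = 1 (cell value 0) and surfaced as one aggregated warning rather
#' than a crash.
#'
#' @inheritParams fit_snp_qt
#' @param snps,rois optional subsets of SNP / ROI ids (default: all).
#' @param cap upper bound applied to `-log10(p)`.
#' @return An unnormalized `association_map` matrix (SNPs x ROIs).
#' @export
association_map <- function(genotypes, phenotypes, cohort,
                            snps = colnames(genotypes),
                            rois = attr(phenotypes, "roi_ids"),
                            covariates = c("age", "sex", "education"),
                            cap = 300) {
  if (is.null(rois)) {
    rois <- setdiff(colnames(phenotypes),
                    c("subject_id", "diagnosis", covariates))
  }
  ids <- cohort_subjects(genotypes, phenotypes, cohort)
  ph <- phenotypes[match(ids, phenotypes$subject_id), , drop = FALSE]
  Z <- as.matrix(ph[, covariates, drop = FALSE])
  Y <- as.matrix(ph[, rois, drop = FALSE])
  vals <- matrix(0, length(snps), length(rois),
                 dimnames = list(snps, rois))
  flagged <- character(0)
  for (s in snps) {
    fit <- fit_one_snp(genotypes[ids, s], Z, Y)
    if (!is.null(fit$flag)) {
      flagged <- c(flagged, sprintf("%s (%s)", s, fit$flag))
      next                               # row stays 0 (p = 1)
    }
    vals[s, ] <- pmin(-log10(fit$p_value), cap)
  }
  if (length(flagged) > 0) {
    warning("regression flagged for ", length(flagged), " SNP(s): ",
            paste(flagged, collapse = ", "))
  }
  new_association_map(vals, normalized = FALSE)
}

#' Normalize association-map rows to unit Euclidean norm
#'
#' Each SNP's 116-dimensional (in general, ROI-dimensional) significance
#' vector is rescaled to L2 norm 1, so each SNP is represented as a
#' directional unit vector before similarity scoring. All-zero rows are
#' left unchanged and recorded in `attr(, "zero_rows")`.
#'
#' @param map an `association_map`.
#' @return The normalized `association_map`.
#' @export
normalize_rows <- function(map) {
  m <- unclass(map)
  attributes(m) <- list(dim = dim(map), dimnames = dimnames(map))
  norms <- sqrt(rowSums(m^2))
  zero <- which(norms == 0)
  scale <- ifelse(norms == 0, 1, norms)
  m <- m / scale
  new_association_map(m, normalized = TRUE,
                      zero_rows = if (length(zero)) rownames(map)[zero])
}
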