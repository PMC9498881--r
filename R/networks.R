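#' @export
similarity_measures <- c("pearson", "spearman", "manhattan", "euclidean",
                         "cosine")

#' Raw similarity or distance score between two SNP profile vectors
#'
#' The five scoring functions applied to pairs of (row-normalized) SNP
#' association profiles: Pearson correlation, Spearman rank correlation
#' (average ranks on ties), Manhattan (L1) distance, Euclidean (L2)
#' distance, and cosine similarity. The bounded measures
#' (pearson/spearman/cosine) are clamped into [-1, 1] to absorb
#' floating-point overshoot. A zero-variance vector under
#' pearson/spearman, or a zero vector under cosine, yields the sentinel
#' `NA` ("undefined"); [similarity_network()] converts that to weight 0
#' with a warning.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @param measure one of `r paste(similarity_measures, collapse = ", ")`.
#' @return A single number: a correlation/cosine in [-1, 1] or a
#'   nonnegative distance.
#' @examples
#' similarity_score(c(1, 2, 3), c(0.001, 0.002, 0.003), "cosine")  # 1
#' @export
similarity_score <- function(x, y, measure = similarity_measures) {
  measure <- match.arg(measure)
  if (length(x) != length(y) || length(x) < 2) {
    stop("x and y must have equal length >= 2")
  }
  clamp1 <- function(v) min(max(v, -1), 1)
  switch(measure,
    pearson = if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
              else clamp1(stats::cor(x, y)),
    spearman = if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
               else clamp1(stats::cor(x, y, method = "spearman")),
    manhattan = sum(abs(x - y)),
    euclidean = sqrt(sum((x - y)^2)),
    cosine = {
      nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
      if (nx == 0 || ny == 0) NA_real_ else clamp1(sum(x * y) / (nx * ny))
    })
}

#' Gaussian RBF transform from distances to similarities
#'
#' Maps a pairwise distance matrix into (0, 1] with a Gaussian radial
#' basis function centered at distance 0 with standard deviation
#' `(max - min) / 3`: `s = exp(-0.5 * ((d - dmin) / sigma)^2)`. The
#' minimum and maximum are taken over all entries including the zero
#' diagonal, so `dmin = 0` and the kernel is genuinely centered at zero
#' distance; the largest observed distance maps to `exp(-4.5)`. If all
#' distances are equal the similarity is defined as 1 everywhere.
#'
#' @param d symmetric nonnegative distance matrix with zero diagonal.
#' @return Similarity matrix of the same shape, diagonal 1.
#' @export
rbf_similarity <- function(d) {
  d <- as.matrix(d)
  if (any(d < 0)) stop("distances must be nonnegative")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
  dmin <- min(d); dmax <- max(d)
  if (dmax == dmin) {
    s <- matrix(1, nrow(d), ncol(d), dimnames = dimnames(d))
    return(s)
  }
  sigma <- (dmax - dmin) / 3
  exp(-0.5 * ((d - dmin) / sigma)^2)
}

#' Build one SNP-SNP similarity network from an association map
#'
#' Scores all SNP pairs with one measure and normalizes into [0, 1]:
#' correlations and cosine by absolute value, Manhattan/Euclidean
#' distances through [rbf_similarity()]. The diagonal is forced to
#' exactly 1 and the matrix is symmetric by construction. Undefined raw
#' scores (zero-variance profiles) become weight 0 with one aggregated
#' warning.
#'
#' @param map an `association_map`; the pipeline always normalizes rows
#'   first (see [normalize_rows()]).
#' @param measure one of the five scoring functions.
#' @return SNPs x SNPs numeric matrix with `attr(, "measure")` set.
#' @export
similarity_network <- function(map, measure = similarity_measures) {
  measure <- match.arg(measure)
  m <- unclass(map)
  attributes(m) <- list(dim = dim(map), dimnames = dimnames(map))
  S <- nrow(m)
  undefined <- FALSE
  if (measure %in% c("pearson", "spearman")) {
    sds <- apply(m, 1, stats::sd)
    mm <- if (measure == "spearman") t(apply(m, 1, rank)) else m
    W <- suppressWarnings(stats::cor(t(mm)))
    bad <- sds == 0
    if (any(bad)) { undefined <- TRUE; W[bad, ] <- 0; W[, bad] <- 0 }
    W <- abs(pmin(pmax(W, -1), 1))
  } else if (measure == "cosine") {
    norms <- sqrt(rowSums(m^2))
    scale <- ifelse(norms == 0, 1, norms)
    U <- m / scale
    W <- U %*% t(U)
    bad <- norms == 0
    if (any(bad)) { undefined <- TRUE; W[bad, ] <- 0; W[, bad] <- 0 }
    W <- abs(pmin(pmax(W, -1), 1))
  } else {
    d <- as.matrix(stats::dist(m, method = measure))
    W <- rbf_similarity(d)
  }
  W <- (W + t(W)) / 2
  diag(W) <- 1
  dimnames(W) <- list(rownames(m), rownames(m))
  if (undefined) {
    warning("undefined ", measure,
            " score for zero-variance SNP profile(s); weight set to 0")
  }
  attr(W, "measure") <- measure
  W
}

#' Build all five similarity networks
#'
#' @param map an `association_map` (row-normalized in the pipeline).
#' @param measures scoring functions to use (default: all five).
#' @return Named list of networks, one per measure, with identical SNP
#'   ordering.
#' @export
similarity_networks <- function(map, measures = similarity_measures) {
  stats::setNames(lapply(measures, function(ms) similarity_network(map, ms)),
                  measures)
}
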