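# Shared fixtures: all built in code, no stored data.

# Block-structured similarity network: within-block weight `within`,
# between-block weight `between`, diagonal 1.
block_network <- function(sizes, within = 1, between = 0) {
  S <- sum(sizes)
  labels <- rep(seq_along(sizes), sizes)
  W <- matrix(between, S, S)
  for (k in seq_along(sizes)) W[labels == k, labels == k] <- within
  diag(W) <- 1
  rownames(W) <- colnames(W) <- sprintf("snp%02d", seq_len(S))
  W
}

# Random symmetric similarity matrix with entries in [0, 1], diagonal 1.
random_network <- function(S, seed) {
  set.seed(seed)
  M <- matrix(stats::runif(S * S), S, S)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  rownames(M) <- colnames(M) <- sprintf("snp%02d", seq_len(S))
  M
}

block_labels <- function(sizes) rep(seq_along(sizes), sizes)

# Tiny cohort for regression tests: known dosages and covariates.
tiny_regression_fixture <- function(n = 60, seed = 1, beta = 2,
                                    intercept = 5, noise_sd = 0) {
  set.seed(seed)
  g <- stats::rbinom(n, 2, 0.4)
  age <- stats::rnorm(n, 75, 6)
  sex <- stats::rbinom(n, 1, 0.5)
  education <- stats::rnorm(n, 16, 2)
  y <- intercept + beta * g + stats::rnorm(n, 0, noise_sd)
  ids <- sprintf("s%03d", seq_len(n))
  G <- matrix(as.integer(g), ncol = 1, dimnames = list(ids, "snpA"))
  phen <- data.frame(subject_id = ids,
                     diagnosis = rep(c("case", "ctrl"), length.out = n),
                     age = age, sex = sex, education = education,
                     ROI_1 = y, stringsAsFactors = FALSE)
  attr(phen, "roi_ids") <- "ROI_1"
  list(genotypes = G, phenotypes = phen,
       cohort = cohort_spec("all", "case", "ctrl"))
}

# Closed-form OLS oracle: normal equations + t CDF, independent of the
# package's qr-based fitting path.
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tt <- beta / se
  list(beta = unname(drop(beta)), se = unname(se),
       p = unname(drop(2 * stats::pt(-abs(tt), df))))
}

# Direct Table-style silhouette oracle: brute-force loops over the
# 1 - similarity distance matrix.
silhouette_oracle <- function(W, assignment) {
  d <- 1 - W
  n <- nrow(d)
  vapply(seq_len(n), function(i) {
    ci <- assignment[i]
    same <- setdiff(which(assignment == ci), i)
    if (length(same) == 0) return(0)
    a <- mean(d[i, same])
    b <- min(vapply(setdiff(unique(assignment), ci), function(k) {
      mean(d[i, assignment == k])
    }, numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

# Direct quadratic-form objective oracle using explicit matrix products.
objective_oracle <- function(views, assignment, K) {
  if (is.matrix(views)) views <- list(views)
  total <- 0
  for (A in views) {
    D <- diag(rowSums(A), nrow(A))
    for (k in seq_len(K)) {
      q <- as.numeric(assignment == k)
      total <- total + drop(t(q) %*% D %*% q) / drop(t(q) %*% A %*% q)
    }
  }
  total
}
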