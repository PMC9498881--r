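#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so package calls never perturb user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Relabel cluster ids 1..K in order of first occurrence, so that the same
# partition always yields the same label vector regardless of how the solver
# numbered the clusters.
canonicalize_labels <- function(assignment) {
  first <- unique(assignment)
  out <- match(assignment, first)
  names(out) <- names(assignment)
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items,
#' used to compare a recovered SNP partition with a planted one. Returns 1
#' for identical partitions (up to relabeling) and has expectation 0 for
#' independent random partitions.
#'
#' @param a,b integer or factor label vectors of equal length.
#' @return A single number in [-1, 1].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: same partition
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# assignment as named integer vector (names = snp ids, values 1..K);
# validate it covers all K labels with no gaps.
check_assignment <- function(assignment, K = max(assignment)) {
  if (anyNA(assignment)) stop("assignment contains NA labels")
  labs <- sort(unique(as.integer(assignment)))
  if (!identical(labs, seq_len(K))) {
    stop(sprintf("assignment must use every label 1..%d; found {%s}",
                 K, paste(labs, collapse = ",")))
  }
  invisible(TRUE)
}
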