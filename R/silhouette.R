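#' Per-SNP silhouette values on a similarity network
#'
#' Similarities are converted to distances by `d = 1 - w`. For each SNP i
#' with cluster C: `a(i)` is the mean distance to the other members of C
#' (excluding itself), `b(i)` is the smallest mean distance to any other
#' cluster, and `s(i) = (b - a) / max(a, b)`. Members of singleton
#' clusters score 0 by convention.
#'
#' @param network symmetric similarity matrix with entries in [0, 1].
#' @param assignment integer cluster labels 1..K covering every SNP;
#'   at least two clusters.
#' @return Numeric vector of silhouette values in [-1, 1], one per SNP.
#' @export
silhouette_scores <- function(network, assignment) {
  K <- max(assignment)
  if (K < 2) stop("silhouette requires at least 2 clusters")
  check_assignment(assignment, K)
  d <- 1 - network
  n <- nrow(d)
  sizes <- tabulate(assignment, K)
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- assignment[i]
    if (sizes[ci] == 1) { s[i] <- 0; next }
    a <- sum(d[i, assignment == ci]) / (sizes[ci] - 1)  # d[i,i] = 0
    b <- Inf
    for (k in seq_len(K)) {
      if (k == ci) next
      b <- min(b, mean(d[i, assignment == k]))
    }
    denom <- max(a, b)
    s[i] <- if (denom == 0) 0 else (b - a) / denom
  }
  names(s) <- rownames(network)
  s
}

# Small-K preference: the smallest K whose averaged score is within
# `tolerance` of the maximum (exact argmax, lowest K on ties, at 0).
choose_k <- function(averaged_score, tolerance) {
  best <- max(averaged_score)
  eligible <- as.integer(names(averaged_score)[averaged_score >=
                                                 best - tolerance])
  min(eligible)
}

# A network grid is a named list of cohorts, each a named list of
# measure -> similarity matrix. A bare list of matrices is promoted to a
# single-cohort grid.
as_network_grid <- function(networks) {
  if (length(networks) > 0 && all(vapply(networks, is.matrix, logical(1)))) {
    networks <- list(cohort = networks)
  }
  if (length(networks) == 0) stop("empty network grid")
  networks
}

#' Average silhouette score over a (measure x cohort) grid
#'
#' The grid holds one similarity network per (measure, cohort) cell; each
#' cohort contributes one clustering (in the multigraph case the same
#' assignment is scored against all of that cohort's measure networks).
#' Every cell's score is the mean per-SNP silhouette, and the returned
#' value is the arithmetic mean over all cells — for the full design of 5
#' measures and 5 comparison groups this is the 25-score average used to
#' compare cluster numbers.
#'
#' @param assignments named list: cohort -> label vector.
#' @param networks named list: cohort -> named list of measure networks.
#' @return Single number in [-1, 1].
#' @export
averaged_silhouette <- function(assignments, networks) {
  networks <- as_network_grid(networks)
  missing_cells <- setdiff(names(networks), names(assignments))
  if (length(missing_cells) > 0) {
    stop("no assignment for cohort(s): ", paste(missing_cells, collapse = ", "))
  }
  cells <- unlist(lapply(names(networks), function(coh) {
    vapply(networks[[coh]], function(net) {
      mean(silhouette_scores(net, assignments[[coh]]))
    }, numeric(1))
  }))
  mean(cells)
}

#' Sweep the number of clusters and select K by averaged silhouette
#'
#' For every K in `k_range`, clusters each cohort's networks (jointly
#' across measures with [minmax_cut()] in `"multigraph"` mode, or one
#' clustering per measure network in `"singlegraph"` mode), scores every
#' (measure, cohort) cell by mean silhouette on that measure's distance
#' matrix, and averages the cells. The selected K is the smallest K whose
#' averaged score is within `tolerance` of the maximum — when scores are
#' similar, fewer clusters are preferred because the aim is a high-level
#' summary.
#'
#' @param networks a network grid (cohort -> measure -> matrix), or a
#'   bare list of measure networks for a single cohort.
#' @param k_range candidate cluster numbers (default 2:9).
#' @param tolerance score slack for the small-K preference (default
#'   0.01); 0 selects the exact argmax (lowest K on ties).
#' @param seed solver seed.
#' @param mode `"multigraph"` (one joint clustering per cohort) or
#'   `"singlegraph"` (one clustering per measure network).
#' @param ... passed to [minmax_cut()].
#' @return Object of class `silhouette_report`: `per_cell_scores` (data
#'   frame with measure, cohort, k, score), `averaged_score` (named by
#'   K), `selected_k`, `tolerance`, `mode`, and `assignments[[as
#'   character(K)]][[cohort]]` (multigraph mode) holding the fitted
#'   labels.
#' @export
select_k <- function(networks, k_range = 2:9, tolerance = 0.01, seed = 1L,
                     mode = c("multigraph", "singlegraph"), ...) {
  mode <- match.arg(mode)
  networks <- as_network_grid(networks)
  S <- nrow(networks[[1]][[1]])
  if (min(k_range) < 2 || max(k_range) > S - 1) {
    stop("k_range must lie within [2, S - 1]")
  }
  cells <- list()
  averaged <- stats::setNames(numeric(length(k_range)), k_range)
  assignments <- list()
  for (k in k_range) {
    kk <- as.character(k)
    assignments[[kk]] <- list()
    for (coh in names(networks)) {
      nets <- networks[[coh]]
      if (mode == "multigraph") {
        fit <- minmax_cut(nets, k, seed = seed, ...)
        assignments[[kk]][[coh]] <- fit$assignment
        sc <- vapply(nets, function(net) {
          mean(silhouette_scores(net, fit$assignment))
        }, numeric(1))
      } else {
        sc <- vapply(nets, function(net) {
          fit <- minmax_cut(list(net), k, seed = seed, ...)
          mean(silhouette_scores(net, fit$assignment))
        }, numeric(1))
      }
      cells[[length(cells) + 1L]] <-
        data.frame(measure = names(nets), cohort = coh, k = k, score = sc,
                   row.names = NULL)
    }
    per_k <- do.call(rbind, cells[vapply(cells, function(d) d$k[1] == k,
                                         logical(1))])
    averaged[kk] <- mean(per_k$score)
  }
  selected <- choose_k(averaged, tolerance)
  structure(list(per_cell_scores = do.call(rbind, cells),
                 averaged_score = averaged, selected_k = selected,
                 tolerance = tolerance, mode = mode,
                 assignments = assignments),
            class = "silhouette_report")
}

#' @export
print.silhouette_report <- function(x, ...) {
  cat(sprintf("Silhouette sweep (%s mode), tolerance %.3g\n",
              x$mode, x$tolerance))
  for (k in names(x$averaged_score)) {
    cat(sprintf("  K = %s: averaged silhouette %.4f%s\n", k,
                x$averaged_score[[k]],
                if (as.integer(k) == x$selected_k) "  <- selected" else ""))
  }
  invisible(x)
}

#' @export
plot.silhouette_report <- function(x, ...) {
  ks <- as.integer(names(x$averaged_score))
  graphics::plot(ks, x$averaged_score, type = "b", xlab = "number of clusters",
                 ylab = "averaged silhouette score",
                 main = sprintf("Silhouette sweep (%s)", x$mode), ...)
  graphics::abline(v = x$selected_k, lty = 2)
  invisible(x)
}
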