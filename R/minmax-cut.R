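#' Degree matrix of a similarity network
#'
#' Diagonal matrix of row sums of the adjacency (similarity) matrix, the
#' standard degree matrix used by min-max graph cut.
#'
#' @param network symmetric SNPs x SNPs similarity matrix.
#' @return Diagonal matrix of the same dimension.
#' @export
degree_matrix <- function(network) {
  D <- diag(rowSums(network), nrow(network))
  dimnames(D) <- dimnames(network)
  D
}

# Coerce solver input to a list of conformable symmetric views.
as_views <- function(views) {
  if (is.matrix(views)) views <- list(views)
  if (!is.list(views) || length(views) == 0) {
    stop("views must be a similarity matrix or a nonempty list of them")
  }
  S <- nrow(views[[1]])
  for (v in views) {
    if (!is.matrix(v) || nrow(v) != S || ncol(v) != S) {
      stop("all views must be square matrices of identical dimension")
    }
  }
  views
}

# Per-view cluster statistics for a hard assignment: within-cluster weight
# q'Aq and degree mass q'Dq per cluster, as submatrix / degree sums.
cluster_sums <- function(A, deg, assignment, K) {
  W <- numeric(K); Dm <- numeric(K)
  for (k in seq_len(K)) {
    idx <- which(assignment == k)
    W[k] <- sum(A[idx, idx])
    Dm[k] <- sum(deg[idx])
  }
  list(W = W, Dm = Dm)
}

#' Min-max cut objective of a hard assignment
#'
#' Evaluates `sum_v sum_k (q_k' D_v q_k) / (q_k' A_v q_k)` with `q_k` the
#' 0/1 indicator of cluster k, `A_v` the v-th similarity view and `D_v`
#' its degree matrix. The ratio is scale-invariant in `q_k`, so
#' unnormalized indicators are valid. Each term is >= 1 (the degree mass
#' of a cluster counts its within weight plus its cut), so the objective
#' is bounded below by `m * K`, with equality exactly when every
#' between-cluster weight is zero.
#'
#' @param views similarity matrix or list of views.
#' @param assignment integer labels 1..K per node.
#' @param K number of clusters (default: `max(assignment)`).
#' @return A single number >= `length(views) * K`.
#' @export
minmax_objective <- function(views, assignment, K = max(assignment)) {
  views <- as_views(views)
  check_assignment(assignment, K)
  total <- 0
  for (A in views) {
    cs <- cluster_sums(A, rowSums(A), assignment, K)
    if (any(cs$W <= 0)) stop("cluster with nonpositive within-weight")
    total <- total + sum(cs$Dm / cs$W)
  }
  total
}

# Relaxed objective and gradient for nonnegative Q with orthonormal
# columns: J(Q) = sum_v sum_k (q_k' D_v q_k) / (q_k' A_v q_k + eps).
relaxed_objective <- function(Q, views, degs, eps) {
  J <- 0
  for (v in seq_along(views)) {
    DQ <- Q * degs[[v]]
    AQ <- views[[v]] %*% Q
    J <- J + sum(colSums(Q * DQ) / (colSums(Q * AQ) + eps))
  }
  J
}

relaxed_gradient <- function(Q, views, degs, eps) {
  G <- matrix(0, nrow(Q), ncol(Q))
  for (v in seq_along(views)) {
    DQ <- Q * degs[[v]]
    AQ <- views[[v]] %*% Q
    num <- colSums(Q * DQ)
    den <- colSums(Q * AQ) + eps
    G <- G + 2 * (sweep(DQ, 2, den, "/") - sweep(AQ, 2, num / den^2, "*"))
  }
  G
}

# Project onto the set of nonnegative matrices with orthonormal columns.
# A nonnegative Q with Q'Q = I must have disjoint row supports, so the
# projection keeps each row's largest entry (floored at a tiny positive
# value to preserve support), reassigns a row to any emptied column, and
# rescales columns to unit norm. Both constraints then hold exactly.
project_Q <- function(Q) {
  n <- nrow(Q); K <- ncol(Q)
  k_star <- max.col(Q, ties.method = "first")
  vals <- pmax(Q[cbind(seq_len(n), k_star)], 1e-8)
  counts <- tabulate(k_star, K)
  for (k in which(counts == 0)) {
    for (i in order(Q[, k], decreasing = TRUE)) {
      if (counts[k_star[i]] >= 2) {
        counts[k_star[i]] <- counts[k_star[i]] - 1L
        k_star[i] <- k
        counts[k] <- 1L
        vals[i] <- max(Q[i, k], 1e-8)
        break
      }
    }
  }
  P <- matrix(0, n, K)
  P[cbind(seq_len(n), k_star)] <- vals
  sweep(P, 2, sqrt(colSums(P^2)), "/")
}

# Spectral embedding of the view-averaged symmetric-normalized adjacency
# followed by seeded k-means; returns hard labels for initialization.
spectral_init <- function(views, K, seed) {
  Abar <- Reduce(`+`, views) / length(views)
  d <- rowSums(Abar)
  d[d <= 0] <- 1
  s <- 1 / sqrt(d)
  L <- Abar * tcrossprod(s)
  ev <- eigen(L, symmetric = TRUE)
  U <- ev$vectors[, seq_len(K), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  U <- U / ifelse(rn == 0, 1, rn)
  with_seed(seed, stats::kmeans(U, centers = K, nstart = 10,
                                iter.max = 100)$cluster)
}

# Move nodes one at a time into empty clusters, choosing at each step the
# transfer that least increases the hard objective evaluated over the
# clusters that are nonempty after the move; donors must keep >= 1 node.
repair_empty_clusters <- function(assignment, views, K) {
  repeat {
    sizes <- tabulate(assignment, K)
    empty <- which(sizes == 0)
    if (length(empty) == 0) return(assignment)
    k <- empty[1]
    best <- NULL; best_obj <- Inf
    for (i in seq_along(assignment)) {
      if (sizes[assignment[i]] < 2) next
      cand <- assignment; cand[i] <- k
      nonempty <- which(tabulate(cand, K) > 0)
      relab <- match(cand, nonempty)      # objective over nonempty clusters
      obj <- minmax_objective(views, relab, length(nonempty))
      if (obj < best_obj) { best_obj <- obj; best <- cand }
    }
    if (is.null(best)) stop("cannot repair empty cluster: too few nodes")
    assignment <- best
  }
}

# Greedy single-node local refinement: repeatedly apply the move that
# most decreases the hard objective until no improving move exists.
# Deterministic; never increases the objective.
refine_assignment <- function(assignment, views, K, max_passes = 50) {
  degs <- lapply(views, rowSums)
  stats_v <- lapply(seq_along(views), function(v) {
    cluster_sums(views[[v]], degs[[v]], assignment, K)
  })
  obj_from <- function(stats_v) {
    sum(vapply(stats_v, function(cs) sum(cs$Dm / cs$W), numeric(1)))
  }
  cur <- obj_from(stats_v)
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (i in seq_along(assignment)) {
      from <- assignment[i]
      if (sum(assignment == from) < 2) next
      for (to in seq_len(K)) {
        if (to == from) next
        cand_stats <- stats_v
        ok <- TRUE
        for (v in seq_along(views)) {
          A <- views[[v]]; deg <- degs[[v]]
          link_from <- sum(A[i, assignment == from]) # includes A[i,i]
          link_to <- sum(A[i, assignment == to])
          cs <- cand_stats[[v]]
          cs$W[from] <- cs$W[from] - 2 * link_from + A[i, i]
          cs$W[to] <- cs$W[to] + 2 * link_to + A[i, i]
          cs$Dm[from] <- cs$Dm[from] - deg[i]
          cs$Dm[to] <- cs$Dm[to] + deg[i]
          if (cs$W[from] <= 0 || cs$W[to] <= 0) { ok <- FALSE; break }
          cand_stats[[v]] <- cs
        }
        if (!ok) next
        cand_obj <- obj_from(cand_stats)
        if (cand_obj < cur - 1e-12) {
          assignment[i] <- to
          stats_v <- cand_stats
          cur <- cand_obj
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  assignment
}

#' Multigraph min-max cut clustering of SNP similarity networks
#'
#' Fits a joint K-way partition of the SNPs across one or more similarity
#' views by minimizing the multigraph min-max cut objective
#' `sum_v sum_k (q_k' D_v q_k) / (q_k' A_v q_k)`, which rewards strong
#' within-cluster similarity relative to each cluster's total degree mass
#' simultaneously in every view. With a single view this is the classic
#' single-graph min-max cut.
#'
#' The solver (i) initializes a relaxed nonnegative indicator `Q` from a
#' spectral embedding of the view-averaged symmetric-normalized adjacency
#' followed by seeded k-means, (ii) minimizes the relaxed objective by
#' projected gradient descent with backtracking line search (only
#' non-increasing steps are accepted; after each step `Q` is projected
#' onto nonnegativity and column orthonormality), (iii) stops when the
#' relative objective change falls below `tol` or at `max_iter`,
#' (iv) discretizes by row argmax (ties toward the lowest cluster index),
#' (v) repairs any empty cluster by greedy minimal-damage transfers so
#' every cluster is nonempty, and (vi) optionally polishes the hard
#' assignment with deterministic greedy single-node moves
#' (`refine = TRUE`). The run is deterministic for a fixed seed.
#'
#' @param views one similarity matrix or a list of views sharing SNP ids.
#' @param k number of clusters, `2 <= k <= S - 1`.
#' @param seed integer seed for the k-means initialization.
#' @param max_iter iteration cap for the gradient descent.
#' @param tol relative objective-change convergence threshold.
#' @param refine logical: apply the greedy hard-objective polish.
#' @param eps denominator guard for relaxed columns with near-zero
#'   support.
#' @return Object of class `minmax_cut`: list with `assignment` (named,
#'   labels 1..k, canonicalized by first occurrence), `k`, `Q` (relaxed
#'   indicator), `hard_objective`, `relaxed_trace` (accepted objective
#'   values, non-increasing), `n_iterations`, `n_views`, `seed`.
#' @examples
#' A <- matrix(0.05, 6, 6); A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; diag(A) <- 1
#' fit <- minmax_cut(A, k = 2, seed = 1)
#' fit$assignment
#' @export
minmax_cut <- function(views, k, seed = 1L, max_iter = 1000, tol = 1e-6,
                       refine = TRUE, eps = 1e-12) {
  views <- as_views(views)
  S <- nrow(views[[1]])
  if (k > S) stop("k must not exceed the number of SNPs")
  if (k < 2 || k > S - 1) stop("k must satisfy 2 <= k <= S - 1")
  snp_ids <- rownames(views[[1]])
  degs <- lapply(views, rowSums)

  init <- spectral_init(views, k, seed)
  H <- matrix(0, S, k)
  H[cbind(seq_len(S), init)] <- 1
  Q <- project_Q(H + 0.2)                # smoothed nonnegative indicator

  J <- relaxed_objective(Q, views, degs, eps)
  trace <- J
  step <- 1
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    G <- relaxed_gradient(Q, views, degs, eps)
    accepted <- FALSE
    s <- step
    for (bt in seq_len(30)) {
      Q_new <- project_Q(Q - s * G)
      J_new <- relaxed_objective(Q_new, views, degs, eps)
      if (J_new <= J) { accepted <- TRUE; break }
      s <- s / 2
    }
    if (!accepted) break                  # no non-increasing step: converged
    rel_change <- (J - J_new) / max(abs(J), 1e-300)
    Q <- Q_new; J <- J_new
    trace <- c(trace, J)
    step <- min(s * 2, 1e3)
    if (rel_change < tol) break
  }

  assignment <- max.col(Q, ties.method = "first")
  assignment <- repair_empty_clusters(assignment, views, k)
  if (refine) assignment <- refine_assignment(assignment, views, k)
  assignment <- canonicalize_labels(assignment)
  names(assignment) <- snp_ids

  structure(list(assignment = assignment, k = k, Q = Q,
                 hard_objective = minmax_objective(views, assignment, k),
                 relaxed_trace = trace, n_iterations = iter,
                 n_views = length(views), seed = as.integer(seed)),
            class = "minmax_cut")
}

#' @rdname minmax_cut
#' @param view a single similarity matrix.
#' @param ... passed on to [minmax_cut()].
#' @export
minmax_cut_single <- function(view, k, ...) {
  if (is.list(view)) stop("minmax_cut_single expects one similarity matrix")
  minmax_cut(list(view), k, ...)
}

#' Exhaustive min-max cut solver (testing oracle)
#'
#' Enumerates every partition of the S nodes into exactly K nonempty
#' blocks (restricted-growth-string enumeration, canonical label order)
#' and returns the global minimum of [minmax_objective()]. Only feasible
#' at toy sizes; refuses instances beyond S = 15 or K = 3.
#'
#' @inheritParams minmax_objective
#' @return List with `assignment`, `objective`, and `n_evaluated` (the
#'   Stirling number S(S, K) of partitions scored).
#' @export
minmax_cut_exhaustive <- function(views, K) {
  views <- as_views(views)
  S <- nrow(views[[1]])
  if (S > 15 || K > 3) {
    stop("exhaustive solver limited to S <= 15 nodes and K <= 3 clusters")
  }
  best <- NULL; best_obj <- Inf; count <- 0L
  a <- integer(S)
  recurse <- function(i, maxlab) {
    if (i > S) {
      if (maxlab == K) {
        count <<- count + 1L
        obj <- minmax_objective(views, a, K)
        if (obj < best_obj) { best_obj <<- obj; best <<- a }
      }
      return(invisible())
    }
    upper <- min(maxlab + 1L, K)
    for (lab in seq_len(upper)) {
      a[i] <<- lab
      recurse(i + 1L, max(maxlab, lab))
    }
  }
  a[1] <- 1L
  recurse(2L, 1L)
  assignment <- best
  names(assignment) <- rownames(views[[1]])
  list(assignment = assignment, objective = best_obj, n_evaluated = count)
}

#' @export
print.minmax_cut <- function(x, ...) {
  cat(sprintf(
    "Multigraph min-max cut: %d clusters over %d views (%d SNPs)\n",
    x$k, x$n_views, length(x$assignment)))
  cat(sprintf("  hard objective: %.6f (lower bound %d)\n",
              x$hard_objective, x$n_views * x$k))
  cat("  cluster sizes:", paste(tabulate(x$assignment, x$k), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.minmax_cut <- function(object, ...) {
  sizes <- tabulate(object$assignment, object$k)
  out <- list(k = object$k, n_views = object$n_views, sizes = sizes,
              hard_objective = object$hard_objective,
              n_iterations = object$n_iterations,
              relaxed_final = utils::tail(object$relaxed_trace, 1),
              members = split(names(object$assignment), object$assignment))
  class(out) <- "summary.minmax_cut"
  out
}

#' @export
print.summary.minmax_cut <- function(x, ...) {
  cat(sprintf("Min-max cut with K = %d over %d view(s)\n", x$k, x$n_views))
  cat(sprintf("  hard objective %.6f after %d gradient iterations\n",
              x$hard_objective, x$n_iterations))
  for (k in seq_len(x$k)) {
    mem <- x$members[[as.character(k)]]
    cat(sprintf("  cluster %d (%d SNPs): %s%s\n", k, x$sizes[k],
                paste(utils::head(mem, 8), collapse = ", "),
                if (length(mem) > 8) ", ..." else ""))
  }
  invisible(x)
}

#' @export
plot.minmax_cut <- function(x, network = NULL, ...) {
  if (is.null(network)) {
    graphics::plot(x$relaxed_trace, type = "b", xlab = "accepted iteration",
                   ylab = "relaxed objective",
                   main = "Min-max cut descent trace", ...)
  } else {
    ord <- order(x$assignment)
    graphics::image(t(network[ord, rev(ord)]), axes = FALSE,
                    main = sprintf("Similarity network reordered by %d clusters",
                                   x$k), ...)
  }
  invisible(x)
}
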