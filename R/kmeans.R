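#' K-means clustering of the trait matrix
#'
#' Lloyd's algorithm with k-means++ seeding and multiple restarts, keeping the
#' run with the lowest inertia (total within-cluster sum of squared Euclidean
#' distances to centroids). Fully deterministic given `seed`. If a cluster
#' empties during iteration it is repaired by re-seeding it with the point
#' farthest from its current centroid. Within each run the inertia is
#' non-increasing across iterations (checked).
#'
#' Cluster labels are renumbered 1..k by order of each cluster's first species
#' (row order), so labels are stable and comparable across runs.
#'
#' @param m a `trait_matrix` or numeric matrix (species rows).
#' @param k number of clusters (2 <= k <= number of species).
#' @param n_init number of restarts (default 100).
#' @param max_iter maximum Lloyd iterations per restart (default 300).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return Object of class `trait_kmeans`: `partition` (a [partition] with
#'   `method = "kmeans"`), `centroids` (k x trait), `inertia`, `iterations`,
#'   `n_init`, `seed`.
#' @export
trait_kmeans <- function(m, k, n_init = 100L, max_iter = 300L, seed = NULL) {
  x <- unclass(m)
  n <- nrow(x)
  if (k > n) stop2("k (", k, ") exceeds the number of species (", n, ")")
  if (k < 2L) stop2("k must be at least 2")
  with_seed(seed, {
    best <- NULL
    for (run in seq_len(n_init)) {
      fit <- kmeans_single(x, k, max_iter)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
    best
  }) -> best
  # relabel clusters by first occurrence in row order
  first <- vapply(seq_len(k), function(c) match(c, best$assign), 0L)
  relab <- integer(k); relab[order(first)] <- seq_len(k)
  assign <- relab[best$assign]
  centroids <- best$centroids[order(first), , drop = FALSE]
  rownames(centroids) <- paste0("cluster", seq_len(k))
  species <- rownames(x) %||% as.character(seq_len(n))
  structure(list(
    partition = partition(stats::setNames(as.character(assign), species),
                          method = "kmeans"),
    centroids = centroids, inertia = best$inertia,
    iterations = best$iterations, n_init = n_init, seed = seed),
    class = "trait_kmeans")
}

# squared Euclidean distances from every row of x to every row of centers
cross_dist2 <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  pmax(d2, 0)
}

kmeans_pp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- cross_dist2(x, x[idx[1], , drop = FALSE])[, 1]
  for (j in seq_len(k - 1L)) {
    if (sum(d2) <= 0) idx[j + 1L] <- sample.int(n, 1L)
    else idx[j + 1L] <- sample.int(n, 1L, prob = d2)
    d2 <- pmin(d2, cross_dist2(x, x[idx[j + 1L], , drop = FALSE])[, 1])
  }
  x[idx, , drop = FALSE]
}

kmeans_single <- function(x, k, max_iter) {
  centers <- kmeans_pp_init(x, k)
  assign <- integer(nrow(x))
  prev_inertia <- Inf
  for (iter in seq_len(max_iter)) {
    d2 <- cross_dist2(x, centers)
    new_assign <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: seed with the point farthest from its centroid
    for (c in which(tabulate(new_assign, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(nrow(x)), new_assign)])
      new_assign[far] <- c
      d2[far, ] <- Inf; d2[far, c] <- 0
    }
    inertia <- sum(d2[cbind(seq_len(nrow(x)), new_assign)])
    if (inertia > prev_inertia + 1e-8 * max(1, prev_inertia))
      stop2("internal error: k-means inertia increased")
    converged <- identical(new_assign, assign)
    assign <- new_assign
    centers <- rowsum(x, assign, reorder = TRUE) /
      tabulate(assign, k)
    if (converged) break
    prev_inertia <- inertia
  }
  d2 <- cross_dist2(x, centers)
  inertia <- sum(d2[cbind(seq_len(nrow(x)), assign)])
  list(assign = assign, centroids = centers, inertia = inertia,
       iterations = iter)
}

#' @export
print.trait_kmeans <- function(x, ...) {
  cat("k-means clustering: k = ", nrow(x$centroids), ", inertia = ",
      format(x$inertia, digits = 6), " (best of ", x$n_init, " starts)\n",
      sep = "")
  print(table(cluster = x$partition$labels))
  invisible(x)
}
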