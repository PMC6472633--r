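#' Ward agglomerative clustering of the trait matrix
#'
#' Bottom-up hierarchical clustering under Ward's minimum-variance criterion:
#' at each step the pair of clusters whose merger least increases the total
#' within-cluster sum of squares (dSS) is combined. Implemented with the
#' Lance-Williams update over the dSS merge-cost matrix, initialized at half
#' the squared Euclidean distances (the classical "Ward.D2-equivalent"
#' objective). Ties are broken deterministically by the lexicographically
#' smallest pair of smallest original member indices, so the tree is fully
#' reproducible.
#'
#' Merge costs are non-decreasing along the sequence, and their sum equals
#' the total sum of squares of the centered matrix.
#'
#' @param m a `trait_matrix` or numeric matrix (>= 2 species rows).
#' @return Object of class `ward_tree`: `merges` (data frame with `step`,
#'   `members_a`, `members_b` as "+"-joined species names, `delta_ss`),
#'   `merge` (hclust-style signed merge matrix), `delta_ss`, `labels`.
#' @export
ward_linkage <- function(m) {
  x <- unclass(m)
  n <- nrow(x)
  if (n < 2L) stop2("need at least 2 species")
  species <- rownames(x) %||% as.character(seq_len(n))
  M <- as.matrix(stats::dist(x))^2 / 2     # dSS for singleton pairs
  sizes <- rep(1L, n)
  members <- as.list(seq_len(n))           # original row indices per cluster
  cluster_id <- -seq_len(n)                # hclust convention: leaves < 0
  active <- rep(TRUE, n)
  merge_mat <- matrix(0L, n - 1L, 2L)
  delta_ss <- numeric(n - 1L)
  merges <- vector("list", n - 1L)
  tol <- 1e-9

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    Msub <- M[act, act, drop = FALSE]
    Msub[lower.tri(Msub, diag = TRUE)] <- Inf
    best <- min(Msub)
    cand <- which(Msub <= best + tol * max(1, abs(best)), arr.ind = TRUE)
    # tie-break: smallest (min member of first cluster, min member of second)
    key <- cbind(
      pmin(vapply(members[act[cand[, 1]]], min, 0L),
           vapply(members[act[cand[, 2]]], min, 0L)),
      pmax(vapply(members[act[cand[, 1]]], min, 0L),
           vapply(members[act[cand[, 2]]], min, 0L)))
    pick <- order(key[, 1], key[, 2])[1]
    i <- act[min(cand[pick, ])]
    j <- act[max(cand[pick, ])]
    dss <- M[i, j]

    merges[[step]] <- data.frame(
      step = step,
      members_a = paste(species[sort(members[[i]])], collapse = "+"),
      members_b = paste(species[sort(members[[j]])], collapse = "+"),
      delta_ss = dss, stringsAsFactors = FALSE)
    merge_mat[step, ] <- sort(c(cluster_id[i], cluster_id[j]))
    delta_ss[step] <- dss

    ni <- sizes[i]; nj <- sizes[j]
    for (kk in act) {
      if (kk == i || kk == j) next
      nk <- sizes[kk]
      M[i, kk] <- M[kk, i] <-
        ((ni + nk) * M[i, kk] + (nj + nk) * M[j, kk] - nk * dss) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    members[[i]] <- c(members[[i]], members[[j]])
    cluster_id[i] <- step
    active[j] <- FALSE
  }

  structure(list(merges = do.call(rbind, merges), merge = merge_mat,
                 delta_ss = delta_ss, labels = species, n = n),
            class = "ward_tree")
}

#' Cut a Ward tree into k clusters
#'
#' Returns the partition formed by the clusters existing after `n - k`
#' merges. Cluster labels are 1..k in order of each cluster's smallest
#' original species index. If all merges up to the cut have zero cost the
#' data are degenerate (identical points) and a warning is issued.
#'
#' @param tree a `ward_tree`.
#' @param k number of clusters, 1 <= k <= n.
#' @return A [partition] with `method = "hca"`.
#' @export
cut_tree <- function(tree, k) {
  n <- tree$n
  if (k < 1L || k > n) stop2("k must be between 1 and ", n)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  n_merge <- n - k
  for (step in seq_len(n_merge)) {
    pair <- tree$merge[step, ]
    # resolve: negative entries are leaves, positive are earlier merge steps
    resolve <- function(e) if (e < 0) -e else resolve(tree$merge[e, 1])
    a <- find(resolve(pair[1])); b <- find(resolve(pair[2]))
    parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, 0L)
  if (n_merge > 0 && all(tree$delta_ss[seq_len(n_merge)] <= 1e-12))
    warning("degenerate tree: all merge costs up to the cut are zero",
            call. = FALSE)
  lab <- match(roots, sort(unique(roots)))   # 1..k by smallest member index
  partition(stats::setNames(as.character(lab), tree$labels), method = "hca")
}

#' @export
print.ward_tree <- function(x, ...) {
  cat("Ward linkage tree: ", x$n, " species, ", x$n - 1L, " merges\n",
      sep = "")
  cat("Merge costs (dSS): first = ", format(x$delta_ss[1], digits = 4),
      ", last = ", format(x$delta_ss[x$n - 1L], digits = 4),
      ", total = ", format(sum(x$delta_ss), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Convert a Ward tree to an hclust object
#'
#' Heights are on the `ward.D2` scale, `sqrt(2 * dSS)`, so the result is
#' directly comparable with `hclust(dist(x), method = "ward.D2")`.
#'
#' @param x a `ward_tree`.
#' @param ... unused.
#' @return An object of class `hclust`.
#' @export
as.hclust.ward_tree <- function(x, ...) {
  n <- x$n
  # leaf order: depth-first traversal of the merge matrix
  order_of <- function(step) {
    unlist(lapply(x$merge[step, ], function(e)
      if (e < 0) -e else order_of(e)))
  }
  structure(list(merge = x$merge, height = sqrt(2 * x$delta_ss),
                 order = order_of(n - 1L), labels = x$labels,
                 method = "ward", dist.method = "euclidean",
                 call = match.call()),
            class = "hclust")
}
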