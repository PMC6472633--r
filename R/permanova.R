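#' Euclidean distances between species trait profiles
#'
#' @param m a `trait_matrix` (or plain numeric matrix) with species rows.
#' @return A `dist` object of pairwise Euclidean distances.
#' @export
trait_distances <- function(m) {
  if (nrow(m) < 2L) stop2("need at least 2 species")
  stats::dist(unclass(m), method = "euclidean")
}

# Within-group sum of squares from a squared-distance matrix:
# SS_W = sum over groups g of (1/n_g) * sum_{i<j in g} d(i,j)^2.
ssw_from_d2 <- function(D2, lab_int, a) {
  G <- rowsum(D2, lab_int)           # a x n partial sums
  H <- rowsum(t(G), lab_int)         # a x a block sums (row/col order 1..a)
  ng <- tabulate(lab_int, nbins = a)
  sum(diag(H) / (2 * ng))
}

# All distinct assignments of a label multiset to n positions, as an integer
# matrix (one assignment per row). Used for exact permutation enumeration.
multiset_permutations <- function(counts) {
  n <- sum(counts)
  a <- length(counts)
  res <- list()
  assign_next <- function(prefix, counts) {
    if (length(prefix) == n) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(a)) {
      if (counts[lab] > 0L) {
        counts[lab] <- counts[lab] - 1L
        assign_next(c(prefix, lab), counts)
        counts[lab] <- counts[lab] + 1L
      }
    }
  }
  assign_next(integer(0), as.integer(counts))
  do.call(rbind, res)
}

#' One-way PERMANOVA (distance-based variance partitioning)
#'
#' Partitions the total sum of squared inter-point distances into between- and
#' within-group components for a single grouping factor, and tests the
#' pseudo-F statistic by permutation of group labels over points (the distance
#' matrix is held fixed). With Euclidean distances on a single variable this
#' reproduces classical one-way ANOVA exactly.
#'
#' Definitions, for \eqn{n} points in \eqn{a} groups:
#' \deqn{SS_T = \frac{1}{n}\sum_{i<j} d_{ij}^2, \quad
#'       SS_W = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2, \quad
#'       SS_A = SS_T - SS_W}
#' \deqn{F = \frac{SS_A/(a-1)}{SS_W/(n-a)}, \quad R^2 = SS_A/SS_T}
#'
#' The permutation p-value uses the estimator
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + B)}, which includes the observed
#' statistic so that \eqn{p > 0} always. When the number of distinct label
#' assignments is at most `enumerate_threshold`, all of them are evaluated
#' instead and `p` is the exact proportion (the observed arrangement is one of
#' them).
#'
#' Degenerate cases: if all points are identical (`SS_T = 0`), `r_squared` is
#' 0 and `pseudo_f`/`p_value` are `NA` with `degenerate = TRUE`; if groups are
#' internally identical but distinct (`SS_W = 0`, `SS_T > 0`), `pseudo_f` is
#' `Inf` and `r_squared` is 1.
#'
#' @param d a `dist`, a symmetric distance matrix, or a `trait_matrix` (in
#'   which case Euclidean distances are computed).
#' @param grouping a [partition], or a (named) label vector/factor covering
#'   every point in `d`.
#' @param n_permutations number of random label permutations (default 999); 0
#'   skips the test and reports only sums of squares, F and R-squared.
#' @param seed integer seed making the permutations reproducible; `NULL`
#'   draws from the current RNG state.
#' @param enumerate_threshold enumerate all distinct assignments when their
#'   count is at most this (default 10000).
#' @param keep_permutations keep the permuted F and R-squared values in the
#'   result (`$permuted`).
#' @return Object of class `trait_permanova` with elements `ss_total`,
#'   `ss_within`, `ss_between`, `df_between`, `df_within`, `pseudo_f`,
#'   `r_squared`, `p_value`, `n_permutations`, `method` (`"sampled"`,
#'   `"enumerated"` or `"none"`), `seed`, `degenerate`.
#' @export
trait_permanova <- function(d, grouping, n_permutations = 999, seed = NULL,
                            enumerate_threshold = 10000,
                            keep_permutations = FALSE) {
  if (inherits(d, "trait_matrix") || (is.matrix(d) && !isSymmetric(unname(unclass(d)))))
    d <- trait_distances(d)
  D <- as.matrix(d)
  n <- nrow(D)
  pts <- rownames(D)
  lab <- if (!is.null(pts)) partition_labels_for(grouping, pts)
         else partition_labels_for(grouping, seq_len(n))
  f <- factor(lab)
  a <- nlevels(f)
  if (a < 2L) stop2("need at least 2 groups")
  lab_int <- as.integer(f)
  D2 <- D^2

  sst <- sum(D2) / (2 * n)
  ssw <- ssw_from_d2(D2, lab_int, a)
  ssa <- sst - ssw
  dfb <- a - 1L
  dfw <- n - a
  if (dfw < 1L) stop2("no residual degrees of freedom (n <= number of groups)")

  degenerate <- FALSE
  if (sst <= .Machine$double.eps * n) {
    r2 <- 0; fstat <- NA_real_; degenerate <- TRUE
  } else {
    r2 <- ssa / sst
    fstat <- if (ssw <= .Machine$double.eps * sst) Inf
             else (ssa / dfb) / (ssw / dfw)
  }

  pval <- NA_real_
  method <- "none"
  permuted <- NULL
  if (n_permutations > 0 && !degenerate) {
    counts <- tabulate(lab_int, a)
    n_distinct <- exp(lfactorial(n) - sum(lfactorial(counts)))
    perm_stats <- function(perm_labels) {
      ssw_p <- ssw_from_d2(D2, perm_labels, a)
      ssa_p <- sst - ssw_p
      f_p <- if (ssw_p <= .Machine$double.eps * sst) Inf
             else (ssa_p / dfb) / (ssw_p / dfw)
      c(f = f_p, r2 = ssa_p / sst)
    }
    if (n_distinct <= enumerate_threshold) {
      method <- "enumerated"
      all_assign <- multiset_permutations(counts)
      stats_mat <- apply(all_assign, 1L, perm_stats)
      pval <- mean(stats_mat["f", ] >= fstat)
      n_permutations <- nrow(all_assign)
      permuted <- list(pseudo_f = unname(stats_mat["f", ]),
                       r_squared = unname(stats_mat["r2", ]))
    } else {
      method <- "sampled"
      stats_mat <- with_seed(seed, vapply(seq_len(n_permutations), function(b)
        perm_stats(sample(lab_int)), c(f = 0, r2 = 0)))
      pval <- (1 + sum(stats_mat["f", ] >= fstat)) / (1 + n_permutations)
      permuted <- list(pseudo_f = unname(stats_mat["f", ]),
                       r_squared = unname(stats_mat["r2", ]))
    }
  }

  structure(list(
    ss_total = sst, ss_within = ssw, ss_between = ssa,
    df_between = dfb, df_within = dfw,
    pseudo_f = fstat, r_squared = r2, p_value = pval,
    n_permutations = if (method == "none") 0L else n_permutations,
    method = method, seed = seed, degenerate = degenerate,
    n = n, n_groups = a,
    permuted = if (keep_permutations) permuted else NULL),
    class = "trait_permanova")
}

#' @export
print.trait_permanova <- function(x, digits = 4, ...) {
  cat("One-way PERMANOVA (", x$n, " points, ", x$n_groups, " groups)\n",
      sep = "")
  tab <- data.frame(
    Df = c(x$df_between, x$df_within, x$df_between + x$df_within),
    SumOfSqs = c(x$ss_between, x$ss_within, x$ss_total),
    R2 = c(x$r_squared, 1 - x$r_squared, 1),
    F = c(x$pseudo_f, NA, NA),
    `Pr(>F)` = c(x$p_value, NA, NA),
    row.names = c("groups", "residual", "total"), check.names = FALSE)
  print(format(tab, digits = digits), ...)
  if (x$method != "none")
    cat("p-value from ", x$n_permutations, " ", x$method, " permutations\n",
        sep = "")
  if (x$degenerate) cat("degenerate: all points identical (SS_T = 0)\n")
  invisible(x)
}

#' @export
summary.trait_permanova <- function(object, ...) object
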