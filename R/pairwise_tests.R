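#' Two-sided rank-sum test with midrank ties
#'
#' Wilcoxon-Mann-Whitney rank-sum test of two independent samples. Ties
#' receive midranks. When both samples have at most `exact_max` observations
#' the null distribution of the rank-sum is enumerated exactly over all
#' \eqn{\binom{n}{n_1}} label assignments and the two-sided p-value is the
#' proportion of assignments whose rank-sum is at least as far from its null
#' mean as the observed one (this handles ties exactly, where the classical
#' exact Wilcoxon distribution does not apply). Larger samples use the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_max exact enumeration when both sample sizes are at most this
#'   (default 10).
#' @return List with `statistic` (rank-sum of `x`), `p_value` and `method`.
#' @export
ranksum_test <- function(x, y, exact_max = 10L) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))               # midranks
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    sel <- utils::combn(n, n1)
    wall <- colSums(matrix(r[sel], nrow = n1))
    p <- mean(abs(wall - mu) >= abs(w - mu) - 1e-9)
    list(statistic = w, p_value = p, method = "exact")
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    list(statistic = w, p_value = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal")
  }
}

#' Pairwise rank-sum tests of one trait across functional groups
#'
#' For every unordered pair of groups, tests whether species-level values of a
#' trait differ between the groups, via [ranksum_test]. Groups with fewer than
#' 2 values are skipped with a warning. Optional Holm adjustment across the
#' pairs actually tested.
#'
#' @param values named numeric vector of species-level trait values.
#' @param grouping a [partition] or label vector covering the species.
#' @param adjust `"holm"` (default) or `"none"`.
#' @param exact_max passed to [ranksum_test].
#' @param trait_name optional label carried into the result.
#' @return Data frame of class `pairwise_trait_tests` with one row per tested
#'   pair: `group1`, `group2`, `statistic`, `p_value`, `adjusted_p`, `method`.
#' @export
pairwise_trait_tests <- function(values, grouping, adjust = c("holm", "none"),
                                 exact_max = 10L, trait_name = NULL) {
  adjust <- match.arg(adjust)
  lab <- partition_labels_for(grouping,
                              names(values) %||% seq_along(values))
  groups <- sort(unique(lab))
  sizes <- table(lab)
  small <- names(sizes)[sizes < 2]
  if (length(small))
    warning("group(s) with < 2 values skipped: ",
            paste(small, collapse = ", "), call. = FALSE)
  usable <- setdiff(groups, small)
  rows <- list()
  if (length(usable) >= 2L) {
    pairs <- utils::combn(usable, 2)
    for (i in seq_len(ncol(pairs))) {
      g1 <- pairs[1, i]; g2 <- pairs[2, i]
      res <- ranksum_test(values[lab == g1], values[lab == g2],
                          exact_max = exact_max)
      rows[[i]] <- data.frame(group1 = g1, group2 = g2,
                              statistic = res$statistic,
                              p_value = res$p_value, method = res$method,
                              stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group1 = character(), group2 = character(),
               statistic = numeric(), p_value = numeric(),
               method = character(), stringsAsFactors = FALSE)
  out$adjusted_p <- if (adjust == "holm" && nrow(out))
    stats::p.adjust(out$p_value, method = "holm") else out$p_value
  if (!is.null(trait_name) && nrow(out))
    out <- cbind(trait_name = trait_name, out)
  class(out) <- c("pairwise_trait_tests", "data.frame")
  out
}
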