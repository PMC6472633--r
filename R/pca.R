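#' Principal components analysis of trait space
#'
#' PCA of the (already column-scaled) trait matrix after centering, i.e. an
#' eigendecomposition of the covariance matrix, computed via [stats::prcomp].
#' Columns are *not* re-standardized to correlation since traits are already
#' on a common scale after matrix construction; set `scale.` to override.
#' Component signs are fixed deterministically: each loading column's
#' largest-magnitude entry is made positive.
#'
#' @param m a `trait_matrix` (at least 3 species and 2 traits).
#' @param scale. passed to [stats::prcomp]; default `FALSE` (covariance PCA).
#' @return Object of class `trait_pca` with `scores` (species x component),
#'   `loadings` (trait x component), `sdev` and `variance_fraction`
#'   (non-increasing, summing to 1).
#' @export
trait_pca <- function(m, scale. = FALSE) {
  x <- unclass(m)
  if (nrow(x) < 3L || ncol(x) < 2L) stop2("need >= 3 species and >= 2 traits")
  p <- stats::prcomp(x, center = TRUE, scale. = scale.)
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  vf <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, loadings = p$rotation, sdev = p$sdev,
                 center = p$center, variance_fraction = vf),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, digits = 3, ...) {
  cat("Trait-space PCA: ", nrow(x$scores), " species, ",
      ncol(x$loadings), " components\n", sep = "")
  cat("Variance fractions:\n")
  print(round(x$variance_fraction, digits))
  cat("Loadings:\n")
  print(round(x$loadings, digits))
  invisible(x)
}

#' @export
plot.trait_pca <- function(x, components = c(1, 2), ...) {
  s <- x$scores[, components, drop = FALSE]
  lab <- paste0("PC", components, " (",
                round(100 * x$variance_fraction[components], 1), "%)")
  graphics::plot(s, xlab = lab[1], ylab = lab[2], ...)
  invisible(x)
}
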