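#' Build a standardized species-by-trait matrix
#'
#' Converts cleaned long-format records into the matrix used by all
#' multivariate analyses. The pipeline order is fixed: log-transform each
#' record value, aggregate per species and trait (mean or a quantile of the
#' log values), then scale each trait column across species. Only species with
#' data for *all* requested traits are retained (complete case); at least
#' three complete-case species are required.
#'
#' Scaling modes:
#' * `"zscore01"` (default): z-score each trait (variance scaling) then
#'   min-max rescale the z-scores to \[0, 1\];
#' * `"minmax"`: plain min-max to \[0, 1\];
#' * `"none"`: keep aggregated log values (used e.g. to compare traits on
#'   equal known scales in simulations).
#'
#' The two \[0, 1\] modes differ only by a per-trait affine map, but Euclidean
#' distances differ between them, so the mode is recorded in the scaling
#' metadata and is switchable. Per-trait metadata (log base, centre, scale,
#' min, max) makes the aggregated log values exactly recoverable via
#' [recover_log_values()]. A constant trait column cannot be min-max scaled
#' and is set to 0.5 (flagged in metadata).
#'
#' @param ds a `trait_dataset`.
#' @param traits character vector of trait names to include.
#' @param statistic species-level aggregation: `"mean"` or `"quantile"`.
#' @param q quantile in (0, 1) when `statistic = "quantile"`; linear
#'   interpolation between order statistics at index `(n - 1) * q`.
#' @param scaling `"zscore01"`, `"minmax"` or `"none"`.
#' @param log_base base of the log transform (default 10).
#' @return A `trait_matrix`: numeric matrix (species rows, trait columns) with
#'   attributes `scaling` (per-trait metadata) and `aggregation`.
#' @export
build_trait_matrix <- function(ds, traits = trait_vocabulary()[1:6],
                               statistic = c("mean", "quantile"), q = NULL,
                               scaling = c("zscore01", "minmax", "none"),
                               log_base = 10) {
  statistic <- match.arg(statistic)
  scaling <- match.arg(scaling)
  if (statistic == "quantile") {
    if (is.null(q) || q <= 0 || q >= 1) stop2("quantile statistic needs q in (0, 1)")
  } else if (!is.null(q)) stop2("q is only meaningful with statistic = 'quantile'")
  if (!length(traits)) stop2("traits must be nonempty")
  rec <- ds$records[ds$records$trait_name %in% traits, , drop = FALSE]
  if (any(rec$value <= 0)) stop2("non-positive trait values; clean the dataset first")
  rec$logv <- log(rec$value, base = log_base)

  agg_fun <- if (statistic == "mean") mean else
    function(x) unname(stats::quantile(x, probs = q, type = 7))
  agg <- stats::aggregate(logv ~ species_name + trait_name, data = rec,
                          FUN = agg_fun)
  wide <- stats::reshape(agg, idvar = "species_name", timevar = "trait_name",
                         direction = "wide")
  names(wide) <- sub("^logv\\.", "", names(wide))
  miss_tr <- setdiff(traits, names(wide))
  if (length(miss_tr))
    stop2("no data for trait(s): ", paste(miss_tr, collapse = ", "))
  complete <- stats::complete.cases(wide[traits])
  wide <- wide[complete, , drop = FALSE]
  if (nrow(wide) < 3L)
    stop2("fewer than 3 complete-case species (got ", nrow(wide),
          "); multivariate statistics are undefined")
  m <- as.matrix(wide[traits])
  rownames(m) <- wide$species_name
  m <- m[order(rownames(m)), , drop = FALSE]
  scale_trait_matrix(m, scaling, log_base,
                     aggregation = list(statistic = statistic, q = q))
}

scale_trait_matrix <- function(m, scaling, log_base, aggregation) {
  meta <- vector("list", ncol(m))
  names(meta) <- colnames(m)
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    info <- list(mode = scaling, log_base = log_base,
                 center = 0, scale = 1, min = 0, max = 1, constant = FALSE)
    if (scaling == "none") {
      out[, j] <- x
      info$min <- NA_real_; info$max <- NA_real_
    } else {
      z <- x
      if (scaling == "zscore01") {
        info$center <- mean(x)
        info$scale <- stats::sd(x)
        if (info$scale == 0) info$scale <- 1
        z <- (x - info$center) / info$scale
      }
      lo <- min(z); hi <- max(z)
      if (hi > lo) {
        out[, j] <- (z - lo) / (hi - lo)
        info$min <- lo; info$max <- hi
      } else {
        out[, j] <- rep(0.5, length(z))
        info$min <- lo; info$max <- hi; info$constant <- TRUE
      }
    }
    meta[[j]] <- info
  }
  structure(out, scaling = meta, aggregation = aggregation,
            class = c("trait_matrix", "matrix", "array"))
}

#' Recover aggregated log values from a trait matrix
#'
#' Inverts the recorded per-trait scaling, returning the species-level
#' aggregated log-scale values (exact to numerical precision; constant columns
#' recover their common value).
#'
#' @param m a `trait_matrix`.
#' @return Numeric matrix of aggregated log values.
#' @export
recover_log_values <- function(m) {
  meta <- attr(m, "scaling")
  out <- unclass(m)
  attr(out, "scaling") <- NULL
  attr(out, "aggregation") <- NULL
  for (j in seq_len(ncol(out))) {
    info <- meta[[colnames(out)[j]]]
    if (info$mode == "none") next
    z <- if (info$constant) rep(info$min, nrow(out)) else
      out[, j] * (info$max - info$min) + info$min
    out[, j] <- z * info$scale + info$center
  }
  out
}

#' Restrict a trait matrix to a subset of traits
#'
#' Keeps the selected columns; per-trait scaling is *not* recomputed, so
#' subset analyses see the same per-trait coordinates as the full matrix.
#' Species are unchanged (the matrix is complete-case by construction).
#'
#' @param m a `trait_matrix`.
#' @param traits nonempty subset of `colnames(m)`.
#' @return The restricted `trait_matrix`.
#' @export
matrix_subset <- function(m, traits) {
  if (!length(traits)) stop2("trait subset must be nonempty")
  unknown <- setdiff(traits, colnames(m))
  if (length(unknown))
    stop2("unknown trait(s): ", paste(unknown, collapse = ", "))
  out <- m[, traits, drop = FALSE]
  structure(out, scaling = attr(m, "scaling")[traits],
            aggregation = attr(m, "aggregation"),
            class = c("trait_matrix", "matrix", "array"))
}

#' @export
print.trait_matrix <- function(x, ...) {
  agg <- attr(x, "aggregation")
  mode <- attr(x, "scaling")[[1]]$mode
  cat("Trait matrix: ", nrow(x), " species x ", ncol(x), " traits (",
      paste(colnames(x), collapse = ", "), ")\n", sep = "")
  cat("  aggregation: ", agg$statistic,
      if (identical(agg$statistic, "quantile")) paste0(" (q = ", agg$q, ")"),
      "; scaling: ", mode, "\n", sep = "")
  print(utils::head(unclass(x)[, , drop = FALSE], 5))
  if (nrow(x) > 5) cat("  ... ", nrow(x) - 5, " more species\n", sep = "")
  invisible(x)
}
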