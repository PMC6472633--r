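#' Species partitions
#'
#' A partition assigns every species to exactly one labelled group. Partitions
#' arise from a priori functional group schemes (read from a classification
#' table) or from post hoc clustering of the trait matrix.
#'
#' @param labels named character vector: names are species, values are group
#'   labels; or a factor with species names.
#' @param method one of `"a_priori"`, `"kmeans"`, `"hca"`.
#' @param scheme_name optional scheme identifier (e.g. `"traditional_4"`).
#' @return An object of class `partition`: a list with `labels` (named
#'   character), `k` (number of distinct labels) and `method`.
#' @export
partition <- function(labels, method = c("a_priori", "kmeans", "hca"),
                      scheme_name = NULL) {
  method <- match.arg(method)
  labels <- stats::setNames(as.character(labels), names(labels))
  if (is.null(names(labels)) || anyNA(names(labels)) || any(names(labels) == ""))
    stop2("every species in a partition must be named")
  if (anyDuplicated(names(labels)))
    stop2("duplicated species in partition: ",
          paste(unique(names(labels)[duplicated(names(labels))]), collapse = ", "))
  if (anyNA(labels)) stop2("NA group labels are not allowed")
  structure(
    list(labels = labels, k = length(unique(labels)), method = method,
         scheme_name = scheme_name),
    class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("Species partition (", x$method,
      if (!is.null(x$scheme_name)) paste0(", scheme '", x$scheme_name, "'"),
      ")\n", sep = "")
  cat("  ", length(x$labels), " species in ", x$k, " groups\n", sep = "")
  print(table(group = x$labels))
  invisible(x)
}

# Coerce labels aligned to a species vector; errors on missing species.
partition_labels_for <- function(part, species) {
  if (inherits(part, "partition")) part <- part$labels
  if (is.factor(part)) part <- stats::setNames(as.character(part), names(part))
  if (is.null(names(part))) {
    if (length(part) != length(species))
      stop2("unnamed grouping must have one label per species")
    return(as.character(part))
  }
  miss <- setdiff(species, names(part))
  if (length(miss))
    stop2("species without a group label: ", paste(utils::head(miss, 5), collapse = ", "),
          if (length(miss) > 5) " ...")
  as.character(part[species])
}
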