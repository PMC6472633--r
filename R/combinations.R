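#' Enumerate trait subsets
#'
#' All subsets of the trait list with at least `min_size` members, in
#' deterministic (size, then lexicographic) order.
#'
#' @param traits character vector.
#' @param min_size minimum subset size (default 1).
#' @return List of character vectors.
#' @export
enumerate_trait_subsets <- function(traits, min_size = 1L) {
  if (!length(traits)) stop2("traits must be nonempty")
  traits <- sort(unique(traits))
  out <- list()
  for (s in seq(min_size, length(traits))) {
    cc <- utils::combn(traits, s, simplify = FALSE)
    out <- c(out, cc)
  }
  out
}

# classical one-way sums-of-squares R^2, identical to the Euclidean
# PERMANOVA R^2 by the identity sum_{i<j} d_ij^2 = n * sum_i |x_i - xbar|^2
group_r2_fast <- function(x, lab_int, a) {
  n <- nrow(x)
  sst <- sum(sweep(x, 2, colMeans(x))^2)
  if (sst <= .Machine$double.eps * n) return(0)
  ng <- tabulate(lab_int, a)
  gm <- rowsum(x, lab_int) / ng
  ssw <- sum(x^2) - sum(gm^2 * ng)
  (sst - ssw) / sst
}

#' Variance explained by a scheme for one trait subset, with resampling
#'
#' Builds the complete-case trait matrix for a subset of traits (species
#' standardization over the full complete-case pool), then repeatedly draws a
#' fixed number of species without replacement and records the PERMANOVA
#' R-squared of the grouping scheme on each draw. Equalizing the species
#' count across trait subsets makes R-squared comparable between subsets with
#' different data availability. R-squared per draw is computed directly from
#' group sums of squares (no permutations — the mean R-squared surface needs
#' no p-values).
#'
#' @param ds a `trait_dataset`.
#' @param traits trait subset.
#' @param scheme a [partition] assigning species to groups.
#' @param n_species species drawn per replication; if the pool is smaller the
#'   whole pool is used every time and the result is flagged degenerate.
#' @param n_reps number of replications (default 999).
#' @param seed integer seed.
#' @param statistic,q,scaling passed to [build_trait_matrix()].
#' @param restandardize re-run column scaling within each draw instead of
#'   inheriting the pool's scaling (default `FALSE`).
#' @param economic,size trait names defining the subset class.
#' @return Object of class `combo_result`: `trait_subset`, `n_pool`,
#'   `n_species_drawn`, `n_replications`, `r2_mean`, `r2_sd`, `r2_values`,
#'   `subset_class`, `degenerate`.
#' @export
resampled_group_r2 <- function(ds, traits, scheme, n_species = 295L,
                               n_reps = 999L, seed = NULL,
                               statistic = "mean", q = NULL,
                               scaling = "zscore01", restandardize = FALSE,
                               economic = trait_axes()$economic,
                               size = trait_axes()$size) {
  m <- build_trait_matrix(ds, traits = traits, statistic = statistic, q = q,
                          scaling = scaling)
  keep <- intersect(rownames(m), names(scheme$labels))
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 3L) stop2("complete-case pool below 3 species")
  lab <- factor(scheme$labels[rownames(m)])
  if (nlevels(lab) < 2L) stop2("complete-case pool spans a single group")
  x <- unclass(m)
  pool <- nrow(x)
  degenerate <- pool <= n_species
  draw_n <- min(n_species, pool)
  lab_int <- as.integer(lab)
  a <- nlevels(lab)
  r2 <- with_seed(seed, vapply(seq_len(n_reps), function(b) {
    idx <- if (degenerate) seq_len(pool)
           else sample.int(pool, draw_n)
    xs <- x[idx, , drop = FALSE]
    if (restandardize)
      xs <- unclass(scale_trait_matrix(xs, scaling, 10,
                                       attr(m, "aggregation")))
    li <- lab_int[idx]
    grp <- sort(unique(li))
    group_r2_fast(xs, match(li, grp), length(grp))
  }, 0))
  structure(list(
    trait_subset = sort(traits), n_pool = pool, n_species_drawn = draw_n,
    n_replications = n_reps, r2_mean = mean(r2), r2_sd = stats::sd(r2),
    r2_values = r2,
    subset_class = subset_class(traits, economic, size),
    degenerate = degenerate, seed = seed),
    class = "combo_result")
}

subset_class <- function(traits, economic, size) {
  if (all(traits %in% economic)) "economic_only"
  else if (all(traits %in% size)) "size_only"
  else "mixed"
}

#' @export
print.combo_result <- function(x, ...) {
  cat("Trait subset {", paste(x$trait_subset, collapse = ", "), "} [",
      x$subset_class, "]\n", sep = "")
  cat("  R2 = ", format(x$r2_mean, digits = 4), " (SD ",
      format(x$r2_sd, digits = 3), ") over ", x$n_replications,
      " draws of ", x$n_species_drawn, "/", x$n_pool, " species",
      if (x$degenerate) " [pool exhausted: degenerate resampling]", "\n",
      sep = "")
  invisible(x)
}

#' Run the resampling analysis over every trait subset
#'
#' Convenience wrapper: [enumerate_trait_subsets()] then
#' [resampled_group_r2()] per subset, with an independent seed per subset
#' derived from `seed` by offset (species draws are redrawn independently
#' per subset).
#'
#' @inheritParams resampled_group_r2
#' @param min_size minimum subset size.
#' @return List of `combo_result`.
#' @export
all_trait_combos <- function(ds, traits, scheme, n_species = 295L,
                             n_reps = 999L, seed = NULL, min_size = 1L, ...) {
  subsets <- enumerate_trait_subsets(traits, min_size)
  lapply(seq_along(subsets), function(i)
    resampled_group_r2(ds, subsets[[i]], scheme, n_species = n_species,
                       n_reps = n_reps,
                       seed = if (is.null(seed)) NULL else seed + i, ...))
}

#' Summarize trait-combination results
#'
#' Emits the full per-subset table plus class means: by subset class
#' (economic-only / size-only / mixed), by whether the subset contains LDMC,
#' and by whether it contains plant height or seed mass.
#'
#' @param results list of `combo_result` from [all_trait_combos()] or
#'   [resampled_group_r2()].
#' @param ldmc_trait,height_trait,seed_trait trait names driving the
#'   contains-classifications.
#' @return List of class `combo_summary`: `table` (one row per subset),
#'   `by_class`, `by_contains_ldmc`, `by_contains_height_or_seed`.
#' @export
combo_summary <- function(results, ldmc_trait = "LDMC",
                          height_trait = "plant_height",
                          seed_trait = "seed_mass") {
  if (!length(results)) stop2("no results to summarize")
  tab <- do.call(rbind, lapply(results, function(r) data.frame(
    traits = paste(r$trait_subset, collapse = "+"),
    n_traits = length(r$trait_subset),
    n_species = r$n_species_drawn, n_reps = r$n_replications,
    r2_mean = r$r2_mean, r2_sd = r$r2_sd, class = r$subset_class,
    contains_ldmc = ldmc_trait %in% r$trait_subset,
    contains_height_or_seed = any(c(height_trait, seed_trait) %in%
                                    r$trait_subset),
    stringsAsFactors = FALSE)))
  mean_by <- function(flag) {
    v <- tapply(tab$r2_mean, flag, mean)
    data.frame(group = names(v), mean_r2 = as.numeric(v),
               n_subsets = as.integer(table(flag)[names(v)]),
               stringsAsFactors = FALSE)
  }
  structure(list(table = tab, by_class = mean_by(tab$class),
                 by_contains_ldmc = mean_by(tab$contains_ldmc),
                 by_contains_height_or_seed =
                   mean_by(tab$contains_height_or_seed)),
            class = "combo_summary")
}

#' @export
print.combo_summary <- function(x, ...) {
  cat("Trait-combination analysis: ", nrow(x$table), " subsets\n\n", sep = "")
  cat("Mean R2 by subset class:\n"); print(x$by_class)
  cat("\nMean R2 by contains-LDMC:\n"); print(x$by_contains_ldmc)
  cat("\nMean R2 by contains plant height or seed mass:\n")
  print(x$by_contains_height_or_seed)
  invisible(x)
}
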