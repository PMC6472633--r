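#' Confusion matrix between two partitions
#'
#' Cross-tabulates co-assignment of the species common to both partitions.
#'
#' @param a,b [partition] objects (or named label vectors). Rows of the
#'   result follow `a`, columns follow `b`.
#' @return Integer matrix with row/column dimnames; the grand total equals
#'   the number of shared species.
#' @export
confusion <- function(a, b) {
  la <- if (inherits(a, "partition")) a$labels else a
  lb <- if (inherits(b, "partition")) b$labels else b
  common <- intersect(names(la), names(lb))
  if (!length(common)) stop2("partitions share no species")
  unclass(table(la[common], lb[common]))
}

#' Optimal one-to-one matching of cluster labels to reference groups
#'
#' Finds the injective assignment of column labels to row labels that
#' maximizes the number of co-classified species (the sum of the matched
#' confusion-matrix cells) — an assignment problem. With at most
#' `exhaustive_max` labels on the smaller side all permutations are searched
#' in lexicographic order (first optimum kept); otherwise the Hungarian
#' algorithm (Jonker-Volgenant shortest augmenting path) is used. Both routes
#' attain the same optimum.
#'
#' When one partition has more labels than the other, unmatched labels
#' contribute no consistent species.
#'
#' @param cm confusion matrix from [confusion()] (rows = reference).
#' @param method `"auto"` (default), `"exhaustive"` or `"hungarian"`.
#' @param exhaustive_max size threshold for the exhaustive route.
#' @return List with `matching` (named character: column label -> matched row
#'   label, only for matched pairs) and `n_consistent`.
#' @export
optimal_matching <- function(cm, method = c("auto", "exhaustive", "hungarian"),
                             exhaustive_max = 8L) {
  method <- match.arg(method)
  cm <- as.matrix(cm)
  s <- max(nrow(cm), ncol(cm))
  pad <- matrix(0, s, s)
  pad[seq_len(nrow(cm)), seq_len(ncol(cm))] <- cm
  use_exh <- method == "exhaustive" ||
    (method == "auto" && min(nrow(cm), ncol(cm)) <= exhaustive_max)
  assign_rows <- if (use_exh) exhaustive_assignment(pad)
                 else hungarian_max(pad)
  # assign_rows[j] = row matched to column j of the padded matrix
  matched <- integer(0)
  match_names <- character(0)
  total <- 0
  for (j in seq_len(ncol(cm))) {
    i <- assign_rows[j]
    if (i <= nrow(cm)) {
      total <- total + cm[i, j]
      matched <- c(matched, i)
      match_names <- c(match_names, colnames(cm)[j] %||% as.character(j))
    }
  }
  rown <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  list(matching = stats::setNames(rown[matched], match_names),
       n_consistent = unname(total))
}

# exhaustive search over column->row permutations, lexicographic order,
# strict improvement keeps the first-found optimum
exhaustive_assignment <- function(pad) {
  s <- nrow(pad)
  perms <- all_permutations(s)
  best <- -Inf; best_p <- NULL
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    val <- sum(pad[cbind(p, seq_len(s))])
    if (val > best) { best <- val; best_p <- p }
  }
  best_p
}

all_permutations <- function(s) {
  if (s == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(s - 1L)
  out <- matrix(0L, s * nrow(sub), s)
  row <- 1L
  for (first in seq_len(s)) {
    rest <- setdiff(seq_len(s), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# Hungarian algorithm (shortest augmenting path), maximizing sum over a
# square matrix; returns row index assigned to each column.
hungarian_max <- function(w) {
  s <- nrow(w)
  cost <- max(w) - w   # minimize
  INF <- .Machine$double.xmax / 4
  u <- numeric(s + 1L); v <- numeric(s + 1L)
  p <- integer(s + 1L)  # p[j]: row assigned to column j (0 = none); p[1] is virtual
  for (i in seq_len(s)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(INF, s + 1L)
    used <- rep(FALSE, s + 1L)
    way <- integer(s + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2L:(s + 1L)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 0L] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(s + 1L)) {
        if (used[j]) { if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign_rows <- integer(s)
  for (j in 2L:(s + 1L)) assign_rows[j - 1L] <- p[j]
  assign_rows
}

#' Consistency of post hoc classifications with a reference scheme
#'
#' For each comparison partition (e.g. the k-means and Ward clusterings), its
#' labels are matched one-to-one to the reference functional groups via
#' [optimal_matching()]; a species is *consistent* under a comparison when its
#' matched cluster label equals its reference group. The all-methods
#' consistent set contains the species consistent under *every* comparison.
#' Overall and per-reference-group proportions are reported, plus
#' abundance-weighted proportions when a cover table is supplied (see
#' [abundance_weighting()]).
#'
#' @param reference a [partition] (the a priori scheme).
#' @param comparisons named list of comparison [partition]s.
#' @param cover optional `cover_table` for abundance weighting.
#' @param weight_mode passed to [abundance_weighting()].
#' @return Object of class `consistency_result`: per-comparison entries (each
#'   with `matching`, `n_consistent`, `proportion_overall`,
#'   `proportion_per_group`, `consistent_species`,
#'   `abundance_weighted_proportion`) plus `all_methods` with the same fields.
#' @export
consistency <- function(reference, comparisons, cover = NULL,
                        weight_mode = c("per_site", "pooled")) {
  weight_mode <- match.arg(weight_mode)
  if (inherits(comparisons, "partition")) comparisons <- list(comparisons)
  if (!length(comparisons)) stop2("need at least one comparison partition")
  if (is.null(names(comparisons)))
    names(comparisons) <- paste0("comparison", seq_along(comparisons))
  ref_lab <- reference$labels
  common <- names(ref_lab)
  for (p in comparisons) common <- intersect(common, names(p$labels))
  if (!length(common)) stop2("no species shared by all partitions")
  ref <- ref_lab[common]

  score_one <- function(comp) {
    cm <- confusion(reference, comp)
    om <- optimal_matching(cm)
    comp_lab <- comp$labels[common]
    mapped <- unname(om$matching[comp_lab])       # NA for unmatched clusters
    cons <- !is.na(mapped) & mapped == ref
    per_group <- tapply(cons, ref, mean)
    res <- list(matching = om$matching, n_consistent = sum(cons),
                proportion_overall = mean(cons),
                proportion_per_group = c(per_group),
                consistent_species = common[cons])
    if (!is.null(cover))
      res$abundance_weighted_proportion <- abundance_weighting(
        common[cons], cover, species_with_traits = common,
        mode = weight_mode)
    res
  }

  per_comp <- lapply(comparisons, score_one)
  all_set <- Reduce(intersect, lapply(per_comp, `[[`, "consistent_species"))
  all_cons <- common %in% all_set
  all_res <- list(
    n_consistent = sum(all_cons),
    proportion_overall = mean(all_cons),
    proportion_per_group = c(tapply(all_cons, ref, mean)),
    consistent_species = common[all_cons])
  if (!is.null(cover))
    all_res$abundance_weighted_proportion <- abundance_weighting(
      common[all_cons], cover, species_with_traits = common,
      mode = weight_mode)

  structure(list(comparisons = per_comp, all_methods = all_res,
                 reference = reference$scheme_name %||% "reference",
                 n_species = length(common)),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, digits = 0, ...) {
  cat("Classification consistency vs '", x$reference, "' (",
      x$n_species, " species)\n\n", sep = "")
  print(round(100 * as.data.frame(x), digits))
  invisible(x)
}

#' @export
as.data.frame.consistency_result <- function(x, ...) {
  groups <- names(x$all_methods$proportion_per_group)
  cols <- c(lapply(x$comparisons, function(r)
    c(r$proportion_per_group[groups], all_groups = r$proportion_overall)),
    list(all_methods = c(x$all_methods$proportion_per_group[groups],
                         all_groups = x$all_methods$proportion_overall)))
  out <- as.data.frame(cols)
  aw <- c(lapply(x$comparisons, `[[`, "abundance_weighted_proportion"),
          list(x$all_methods$abundance_weighted_proportion))
  if (!any(vapply(aw, is.null, TRUE))) {
    out <- rbind(out, abundance_weighted = unlist(aw))
  }
  out
}

#' Abundance-weighted proportion of a species set
#'
#' Weights a set of (consistently classified) species by their vegetation
#' cover: per plot only the most recent survey year is kept, cover is summed
#' to the site level by species, species without trait data are dropped, and
#' each site contributes the ratio (cover of the set) / (cover of all
#' retained species). The default returns the unweighted mean of the per-site
#' ratios; `mode = "pooled"` pools cover across sites before taking the
#' ratio. Sites with zero retained cover are excluded with a warning.
#'
#' @param species_set character vector (e.g. consistent species).
#' @param cover a `cover_table`.
#' @param species_with_traits species universe for the denominator.
#' @param mode `"per_site"` (default) or `"pooled"`.
#' @return A proportion in \[0, 1\].
#' @export
abundance_weighting <- function(species_set, cover, species_with_traits,
                                mode = c("per_site", "pooled")) {
  mode <- match.arg(mode)
  if (!nrow(cover)) stop2("cover table is empty")
  latest <- stats::ave(cover$year, interaction(cover$site, cover$plot),
                       FUN = max)
  cov <- cover[cover$year == latest, , drop = FALSE]
  all_sites <- unique(cov$site)
  cov <- cov[cov$species_name %in% species_with_traits, , drop = FALSE]
  site_sp <- stats::aggregate(cover ~ site + species_name, data = cov,
                              FUN = sum)
  tot <- tapply(site_sp$cover, site_sp$site, sum)
  consum <- tapply(site_sp$cover * (site_sp$species_name %in% species_set),
                   site_sp$site, sum)
  zero <- tot <= 0 | is.na(tot)
  dropped <- c(names(tot)[zero], setdiff(all_sites, names(tot)))
  if (length(dropped)) {
    warning("site(s) with no retained cover excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    tot <- tot[!zero]; consum <- consum[!zero]
  }
  if (!length(tot)) stop2("no site retains cover for species with traits")
  if (mode == "per_site") mean(consum / tot) else sum(consum) / sum(tot)
}
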