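#' Configuration for the synthetic trait database generator
#'
#' Describes a planted-group world: species are nested in functional groups;
#' each species' true trait values sit on the log10 scale at the group
#' archetype plus a species-level offset; individual measurement records add
#' within-species noise; species-by-trait cells go missing at a configurable
#' rate; and plot cover is allocated by a skewed Dirichlet draw per site.
#'
#' Defaults emulate a small tundra-like study: 4 groups (evergreen shrubs,
#' deciduous shrubs, graminoids, forbs) x 25 species, the six focal traits
#' with archetypes ordered like real functional groups (evergreen shrubs
#' lowest in SLA and leaf N, highest in LDMC; shrubs larger-leaved and
#' heavier-seeded than forbs), between-species SD 0.25 and within-species SD
#' 0.15 log10 units, 5 records per species-trait, 10% missing cells, 3 sites
#' x 5 plots x 3 years, Dirichlet concentration 0.5 (strongly skewed
#' abundances).
#'
#' @param n_groups number of planted groups.
#' @param species_per_group species per group.
#' @param traits trait names.
#' @param group_means `n_groups` x `length(traits)` matrix of log10
#'   archetypes; defaults to the built-in tundra-like archetypes when the
#'   default traits are used, otherwise equally spaced offsets.
#' @param trait_sd_between_species per-trait SD of species offsets (recycled).
#' @param within_species_sd per-trait SD of record noise (recycled).
#' @param records_per_species integer, or length-2 range sampled uniformly.
#' @param missing_fraction per-trait probability that a species-by-trait cell
#'   is entirely missing (recycled).
#' @param n_sites,plots_per_site,years cover-table dimensions.
#' @param abundance_shape Dirichlet concentration; small values give skewed
#'   species abundances.
#' @param seed default seed used by [generate_dataset()].
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_groups = 4L, species_per_group = 25L,
                             traits = trait_vocabulary()[1:6],
                             group_means = NULL,
                             trait_sd_between_species = 0.25,
                             within_species_sd = 0.15,
                             records_per_species = 5L,
                             missing_fraction = 0.1,
                             n_sites = 3L, plots_per_site = 5L, years = 3L,
                             abundance_shape = 0.5, seed = 1L) {
  p <- length(traits)
  if (is.null(group_means)) group_means <- default_archetypes(n_groups, traits)
  group_means <- matrix(as.numeric(group_means), n_groups, p)
  rownames(group_means) <- default_group_names(n_groups)
  colnames(group_means) <- traits
  cfg <- list(
    n_groups = as.integer(n_groups),
    species_per_group = as.integer(species_per_group),
    traits = traits, group_means = group_means,
    trait_sd_between_species = rep_len(trait_sd_between_species, p),
    within_species_sd = rep_len(within_species_sd, p),
    records_per_species = as.integer(records_per_species),
    missing_fraction = rep_len(missing_fraction, p),
    n_sites = as.integer(n_sites),
    plots_per_site = as.integer(plots_per_site),
    years = as.integer(years),
    abundance_shape = abundance_shape, seed = as.integer(seed))
  if (any(cfg$trait_sd_between_species < 0) || any(cfg$within_species_sd < 0))
    stop2("standard deviations must be non-negative")
  if (any(cfg$missing_fraction < 0) || any(cfg$missing_fraction >= 1))
    stop2("missing_fraction must be in [0, 1)")
  if (cfg$abundance_shape <= 0) stop2("abundance_shape must be positive")
  class(cfg) <- "synthetic_config"
  cfg
}

default_group_names <- function(n_groups) {
  base <- c("evergreen_shrub", "deciduous_shrub", "graminoid", "forb",
            "grass", "sedge", "rush")
  if (n_groups <= length(base)) base[seq_len(n_groups)]
  else paste0("group", seq_len(n_groups))
}

# log10 archetypes, ordered like real tundra functional groups for the
# default six traits; other shapes fall back to evenly spaced offsets
default_archetypes <- function(n_groups, traits) {
  tundra <- rbind(
    evergreen_shrub = c(plant_height = -0.9, seed_mass = 0.0,
                        leaf_area = 1.5, SLA = 0.8, LDMC = -0.35,
                        leaf_N = 0.10),
    deciduous_shrub = c(-0.6, 0.3, 2.3, 1.2, -0.55, 0.35),
    graminoid       = c(-0.7, -0.3, 2.0, 1.1, -0.45, 0.25),
    forb            = c(-0.9, -0.5, 2.2, 1.3, -0.65, 0.40))
  if (n_groups == 4L && identical(traits, trait_vocabulary()[1:6]))
    return(tundra)
  outer(seq(0, by = 0.4, length.out = n_groups),
        rep(1, length(traits)))
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Generate a synthetic trait database with planted structure
#'
#' Draws a full study-shaped bundle from a [synthetic_config()]: long-format
#' trait records (log10-normal values: group archetype + species offset +
#' record noise, exponentiated to the raw scale), the planted group scheme, a
#' plot-level cover table (per-site Dirichlet abundance profile, jittered per
#' plot and year), and the ground truth (planted partition and species true
#' log means). Fully reproducible from `seed`.
#'
#' @param cfg a `synthetic_config`.
#' @param seed integer seed; defaults to `cfg$seed`.
#' @return List with `dataset` (`trait_dataset`), `scheme` ([partition]),
#'   `cover` (`cover_table`), `truth` (list with `partition`,
#'   `species_log_means`, `config`).
#' @export
generate_dataset <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(seed, {
    S <- cfg$n_groups * cfg$species_per_group
    p <- length(cfg$traits)
    group_of <- rep(seq_len(cfg$n_groups), each = cfg$species_per_group)
    species <- sprintf("species_%03d", seq_len(S))
    group_names <- rownames(cfg$group_means)

    offsets <- matrix(stats::rnorm(S * p), S, p) *
      matrix(cfg$trait_sd_between_species, S, p, byrow = TRUE)
    mu <- cfg$group_means[group_of, , drop = FALSE] + offsets
    dimnames(mu) <- list(species, cfg$traits)

    present <- matrix(stats::runif(S * p), S, p) >=
      matrix(cfg$missing_fraction, S, p, byrow = TRUE)

    m <- cfg$records_per_species
    rows <- list()
    for (j in seq_len(p)) {
      sp_idx <- which(present[, j])
      if (!length(sp_idx)) next
      reps <- rep(sp_idx, each = m)
      logv <- mu[reps, j] + stats::rnorm(length(reps), 0,
                                         cfg$within_species_sd[j])
      rows[[j]] <- data.frame(
        species_name = species[reps], trait_name = cfg$traits[j],
        value = 10^logv, unit = "synthetic",
        latitude = 65 + stats::runif(length(reps), 0, 10),
        longitude = stats::runif(length(reps), -150, 30),
        site = sample(paste0("site_", seq_len(cfg$n_sites)),
                      length(reps), replace = TRUE),
        year = sample(2010:2015, length(reps), replace = TRUE),
        source_id = "synthetic_generator", stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, rows)
    ds <- trait_dataset(records)
    ds$provenance$synthetic <- TRUE

    scheme <- partition(stats::setNames(group_names[group_of], species),
                        method = "a_priori", scheme_name = "planted")

    cov_rows <- list()
    for (s in seq_len(cfg$n_sites)) {
      w_site <- rdirichlet1(rep(cfg$abundance_shape, S))
      for (pl in seq_len(cfg$plots_per_site)) {
        for (yr in seq_len(cfg$years)) {
          w <- w_site * stats::rlnorm(S, 0, 0.2)
          cov_rows[[length(cov_rows) + 1L]] <- data.frame(
            site = paste0("site_", s), plot = paste0("plot_", pl),
            year = 2013L + yr, species_name = species,
            cover = 100 * w / sum(w), stringsAsFactors = FALSE)
        }
      }
    }
    cover <- as_cover_table(do.call(rbind, cov_rows))

    list(dataset = ds, scheme = scheme, cover = cover,
         truth = list(partition = scheme, species_log_means = mu,
                      config = cfg))
  })
}

#' Large-sample variance explained implied by a synthetic config
#'
#' The R-squared a PERMANOVA on the *unscaled* log-trait matrix converges to
#' as the number of species grows: summed over traits, the variance of the
#' group archetypes divided by the total of archetype variance,
#' between-species variance, and within-species variance shrunk by the
#' record count (species values are record means). Under \[0, 1\] rescaling
#' this is approximate, since rescaling reweights traits.
#'
#' @param cfg a `synthetic_config`.
#' @return Expected R-squared in \[0, 1\].
#' @export
expected_separation_r2 <- function(cfg) {
  gm <- cfg$group_means
  vb <- apply(gm, 2, function(v) mean((v - mean(v))^2))
  vs <- cfg$trait_sd_between_species^2
  vw <- cfg$within_species_sd^2 / cfg$records_per_species
  tot <- sum(vb + vs + vw)
  if (tot == 0) return(0)
  sum(vb) / tot
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic trait-database config: ", x$n_groups, " groups x ",
      x$species_per_group, " species, ", length(x$traits), " traits\n",
      sep = "")
  cat("  between-species SD ", paste(unique(x$trait_sd_between_species),
                                     collapse = "/"),
      ", within-species SD ", paste(unique(x$within_species_sd),
                                    collapse = "/"),
      ", ", x$records_per_species, " records/cell, missing ",
      paste(unique(x$missing_fraction), collapse = "/"), "\n", sep = "")
  cat("  expected separation R2 (log scale): ",
      round(expected_separation_r2(x), 3), "\n", sep = "")
  invisible(x)
}
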