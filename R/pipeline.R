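#' Read an analysis configuration file
#'
#' YAML (or JSON) configuration for [run_full_analysis()]. Either an `input`
#' block (paths to trait/cover/group/synonym CSVs) or a `synthetic` block
#' (arguments to [synthetic_config()]) must be present. Remaining keys have
#' defaults: `traits`, `aggregation` (`statistic`, `q`), `scaling`,
#' `schemes` (named list: scheme name -> k), `clustering` (`n_init`),
#' `n_permutations`, `combos` (`enabled`, `n_species`, `n_reps`, `min_size`),
#' `variants` (list of robustness reruns: `q25`, `q75`, `min_latitude`),
#' `seed`, `output_dir`.
#'
#' @param path config file path.
#' @return List of class `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_analysis_config(cfg)
}

#' @rdname read_analysis_config
#' @param cfg a named list with the configuration keys.
#' @export
as_analysis_config <- function(cfg) {
  if (is.null(cfg$input) && is.null(cfg$synthetic))
    stop2("config needs an 'input' or 'synthetic' block")
  cfg$traits <- cfg$traits %||% trait_vocabulary()[1:6]
  cfg$aggregation <- utils::modifyList(list(statistic = "mean", q = NULL),
                                       cfg$aggregation %||% list())
  cfg$scaling <- cfg$scaling %||% "zscore01"
  cfg$schemes <- cfg$schemes %||% list(planted = 4L)
  ks <- unlist(cfg$schemes)
  if (any(ks < 2)) stop2("every scheme k must be >= 2")
  cfg$clustering <- utils::modifyList(list(n_init = 100L), cfg$clustering %||% list())
  cfg$n_permutations <- cfg$n_permutations %||% 999L
  cfg$combos <- utils::modifyList(
    list(enabled = FALSE, n_species = 295L, n_reps = 999L, min_size = 1L),
    cfg$combos %||% list())
  cfg$variants <- cfg$variants %||% list()
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "traitgroups_output"
  class(cfg) <- "analysis_config"
  cfg
}

# fixed per-stage seed offsets so stages are reproducible in isolation
stage_seed <- function(cfg, stage) {
  cfg$seed + c(simulate = 0L, permanova = 1L, kmeans = 2L, combos = 3L)[[stage]]
}

#' Run the full functional-group analysis workflow
#'
#' Executes the complete study pipeline on real or synthetic inputs:
#' clean -> trait matrix -> per-trait pairwise rank tests, PCA, PERMANOVA per
#' scheme and per trait-axis subset (economic-only, size-only) -> k-means and
#' Ward clustering at each scheme's k -> consistency with abundance
#' weighting -> optional trait-combination resampling -> robustness variants
#' (25th/75th-percentile aggregation, minimum-latitude subsets). All result
#' tables are written as CSV plus one JSON summary and a run log under
#' `output_dir`. Output is a pure function of inputs, config and seed. A
#' stage failure aborts with a stage-tagged message; tables already written
#' are retained.
#'
#' @param cfg an `analysis_config` (see [read_analysis_config()]), or a path
#'   to a config file.
#' @param output_dir overrides `cfg$output_dir`.
#' @return Invisibly, a list with every computed object (`dataset`, `matrix`,
#'   `permanova`, `pca`, `pairwise`, `clusterings`, `consistency`, `combos`,
#'   `variants`) plus `files` (paths written).
#' @export
run_full_analysis <- function(cfg, output_dir = NULL) {
  if (is.character(cfg)) cfg <- read_analysis_config(cfg)
  stopifnot(inherits(cfg, "analysis_config"))
  out_dir <- output_dir %||% cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    if (is.data.frame(obj) || is.matrix(obj))
      utils::write.csv(as.data.frame(obj), path, row.names = TRUE)
    else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10,
                              pretty = TRUE, force = TRUE)
    files <<- c(files, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop2("[stage ", name, "] ", conditionMessage(e)))
  }
  log_lines <- c(paste("traitgroups", as.character(utils::packageVersion("traitgroups"))),
                 paste("seed:", cfg$seed), paste("run at:", "deterministic"))

  # --- data ---------------------------------------------------------------
  bundle <- stage("data", {
    if (!is.null(cfg$synthetic)) {
      scfg <- do.call(synthetic_config, cfg$synthetic)
      generate_dataset(scfg, seed = stage_seed(cfg, "simulate"))
    } else {
      inp <- cfg$input
      ds <- read_trait_records(inp$traits, column_map = inp$column_map)
      if (!is.null(inp$synonyms))
        ds <- apply_synonyms(ds, read_synonym_table(inp$synonyms))
      schemes <- lapply(names(cfg$schemes), function(nm)
        read_group_scheme(inp$groups, nm))
      names(schemes) <- names(cfg$schemes)
      list(dataset = ds, scheme = schemes[[1]], schemes = schemes,
           cover = if (!is.null(inp$cover)) read_cover_table(inp$cover))
    }
  })
  ds <- stage("clean", clean_dataset(bundle$dataset))
  emit(ds$provenance[setdiff(names(ds$provenance),
                             c("removed_records", "seed_mass_flagged"))],
       "cleaning_report.json")

  agg <- cfg$aggregation
  build <- function(d, statistic = agg$statistic, q = agg$q)
    build_trait_matrix(d, traits = cfg$traits, statistic = statistic, q = q,
                       scaling = cfg$scaling)
  m <- stage("matrix", build(ds))

  # --- per-scheme permanova + trait-axis subsets --------------------------
  schemes <- bundle$schemes %||%
    stats::setNames(list(bundle$scheme), names(cfg$schemes)[1])
  axes <- trait_axes()
  perm_rows <- list()
  run_perm <- function(mm, part, label) {
    pr <- trait_permanova(mm, part, n_permutations = cfg$n_permutations,
                          seed = stage_seed(cfg, "permanova"))
    perm_rows[[length(perm_rows) + 1L]] <<- data.frame(
      analysis = label, n = pr$n, groups = pr$n_groups,
      r_squared = pr$r_squared, pseudo_f = pr$pseudo_f,
      p_value = pr$p_value, n_permutations = pr$n_permutations,
      stringsAsFactors = FALSE)
    pr
  }
  permanova_fits <- stage("permanova", {
    fits <- list()
    for (nm in names(schemes)) {
      fits[[nm]] <- run_perm(m, schemes[[nm]], paste0(nm, "/all_traits"))
      for (axis in names(axes)) {
        tr <- intersect(axes[[axis]], colnames(m))
        if (length(tr) >= 1)
          run_perm(matrix_subset(m, tr), schemes[[nm]],
                   paste0(nm, "/", axis, "_only"))
      }
    }
    fits
  })

  # --- pca + pairwise -----------------------------------------------------
  pca_fit <- stage("pca", trait_pca(m))
  emit(pca_fit$scores, "pca_scores.csv")
  emit(pca_fit$loadings, "pca_loadings.csv")
  ref <- schemes[[1]]
  pairwise <- stage("pairwise", {
    logm <- recover_log_values(m)
    do.call(rbind, lapply(colnames(logm), function(tr)
      pairwise_trait_tests(stats::setNames(logm[, tr], rownames(logm)),
                           ref, trait_name = tr)))
  })
  emit(pairwise, "pairwise_tests.csv")

  # --- clustering + consistency -------------------------------------------
  clusterings <- stage("cluster", {
    out <- list()
    for (nm in names(schemes)) {
      k <- cfg$schemes[[nm]]
      km <- trait_kmeans(m, k, n_init = cfg$clustering$n_init,
                         seed = stage_seed(cfg, "kmeans"))
      tree <- ward_linkage(m)
      out[[nm]] <- list(kmeans = km, hca = cut_tree(tree, k), tree = tree)
      run_perm(m, km$partition, paste0(nm, "/kmeans_k", k))
      run_perm(m, out[[nm]]$hca, paste0(nm, "/hca_k", k))
    }
    out
  })
  part_tab <- do.call(rbind, lapply(names(clusterings), function(nm) {
    cl <- clusterings[[nm]]
    data.frame(scheme = nm, species_name = names(cl$kmeans$partition$labels),
               a_priori = schemes[[nm]]$labels[names(cl$kmeans$partition$labels)],
               kmeans = cl$kmeans$partition$labels,
               hca = cl$hca$labels[names(cl$kmeans$partition$labels)],
               stringsAsFactors = FALSE)
  }))
  emit(part_tab, "partitions.csv")
  consist <- stage("compare", {
    lapply(names(schemes), function(nm) consistency(
      schemes[[nm]],
      list(kmeans = clusterings[[nm]]$kmeans$partition,
           hca = clusterings[[nm]]$hca),
      cover = bundle$cover)) -> cs
    names(cs) <- names(schemes)
    cs
  })
  cons_tab <- do.call(rbind, lapply(names(consist), function(nm) {
    df <- as.data.frame(consist[[nm]])
    cbind(scheme = nm, group = rownames(df), df, row.names = NULL)
  }))
  emit(cons_tab, "consistency.csv")

  # --- trait combinations -------------------------------------------------
  combos <- NULL
  if (isTRUE(cfg$combos$enabled)) {
    combos <- stage("combos", combo_summary(all_trait_combos(
      ds, cfg$traits, ref, n_species = cfg$combos$n_species,
      n_reps = cfg$combos$n_reps, min_size = cfg$combos$min_size,
      seed = stage_seed(cfg, "combos"), statistic = agg$statistic,
      q = agg$q, scaling = cfg$scaling)))
    emit(combos$table, "combos.csv")
  }

  # --- robustness variants ------------------------------------------------
  variants <- list()
  for (v in cfg$variants) {
    label <- v$name %||% paste0("variant", length(variants) + 1L)
    variants[[label]] <- stage(paste0("variant:", label), {
      dv <- ds
      if (!is.null(v$min_latitude))
        dv <- subset_dataset(dv, min_latitude = v$min_latitude)
      mv <- build(dv, statistic = v$statistic %||% agg$statistic,
                  q = v$q %||% agg$q)
      sp <- intersect(rownames(mv), names(ref$labels))
      run_perm(mv[sp, , drop = FALSE], ref, paste0("variant/", label))
    })
  }

  perm_tab <- do.call(rbind, perm_rows)
  emit(perm_tab, "permanova_results.csv")
  summary_obj <- list(
    seed = cfg$seed,
    n_species = nrow(m), traits = colnames(m),
    permanova = perm_tab,
    consistency_overall = lapply(consist, function(cs) list(
      kmeans = cs$comparisons$kmeans$proportion_overall,
      hca = cs$comparisons$hca$proportion_overall,
      all_methods = cs$all_methods$proportion_overall,
      abundance_weighted = cs$all_methods$abundance_weighted_proportion)),
    combos_by_class = if (!is.null(combos)) combos$by_class)
  emit(summary_obj, "summary.json")
  writeLines(c(log_lines, paste("wrote:", files)),
             file.path(out_dir, "run_log.txt"))

  invisible(list(dataset = ds, matrix = m, permanova = permanova_fits,
                 permanova_table = perm_tab, pca = pca_fit,
                 pairwise = pairwise, clusterings = clusterings,
                 consistency = consist, combos = combos,
                 variants = variants, files = files))
}
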