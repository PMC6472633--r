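test_that("trait CSVs parse, skip unparsable rows, and honour column maps", {
  df <- data.frame(species_name = c("a", "b", "c"),
                   trait_name = "SLA", value = c(10, 20, 30))
  ds <- read_trait_records(write_temp_csv(df))
  expect_s3_class(ds, "trait_dataset")
  expect_equal(nrow(ds$records), 3L)

  df2 <- df; df2$value <- c("10", "abc", "30")
  ds2 <- read_trait_records(write_temp_csv(df2))
  expect_equal(nrow(ds2$records), 2L)
  expect_equal(ds2$provenance$n_skipped_unparsable_value, 1L)

  df3 <- df; names(df3)[1] <- "SpeciesName"
  ds3 <- read_trait_records(write_temp_csv(df3),
                            column_map = c(species_name = "SpeciesName"))
  expect_equal(ds3$records$species_name, ds$records$species_name)
  expect_error(read_trait_records(write_temp_csv(df3)), "species_name")

  expect_warning(
    empty <- read_trait_records(write_temp_csv(df[0, ])), "empty")
  expect_equal(nrow(empty$records), 0L)
})

test_that("traits outside the vocabulary and bad latitudes are handled", {
  df <- data.frame(species_name = c("a", "a", "b"),
                   trait_name = c("SLA", "not_a_trait", "SLA"),
                   value = c(1, 2, 3), latitude = c(68, 50, 95))
  ds <- read_trait_records(write_temp_csv(df))
  expect_equal(nrow(ds$records), 2L)
  expect_equal(ds$provenance$n_skipped_unknown_trait, 1L)
  expect_true(is.na(ds$records$latitude[2]))
  expect_equal(ds$provenance$n_invalid_latitude, 1L)
})

test_that("synonym resolution renames, passes unknowns, rejects chains", {
  ds <- trait_dataset(data.frame(
    species_name = c("Salix arctica var. x", "Salix arctica var. x",
                     "Salix arctica"),
    trait_name = "SLA", value = c(1, 2, 3)))
  out <- apply_synonyms(ds, c("Salix arctica var. x" = "Salix arctica"))
  expect_true(all(out$records$species_name == "Salix arctica"))
  expect_equal(out$provenance$n_synonyms_applied, 2L)

  same <- apply_synonyms(ds, character(0))
  expect_equal(same$records, ds$records)

  expect_error(apply_synonyms(ds, c(a = "b", b = "c")), "chain")
})

test_that("cleaning removes duplicates, non-positives and >4 SD log outliers", {
  base <- data.frame(species_name = "sp", trait_name = "SLA",
                     value = c(rep(10, 30), 10^1.5),
                     unit = "u", source_id = paste0("s", 1:31))
  ds <- clean_dataset(trait_dataset(base))
  # oracle: z-score of the odd point over all 31 log10 values
  logs <- log10(base$value)
  z <- abs(logs[31] - mean(logs)) / sd(logs)
  expect_gt(z, 4)
  expect_equal(nrow(ds$records), 30L)
  expect_equal(ds$provenance$n_sd_outliers_removed, 1L)

  dup <- trait_dataset(data.frame(
    species_name = c("a", "a", "b"), trait_name = "SLA",
    value = c(5, 5, -1), unit = "u", source_id = "x"))
  cl <- clean_dataset(dup)
  expect_equal(cl$provenance$n_duplicates_removed, 1L)
  expect_equal(cl$provenance$n_nonpositive_removed, 1L)
  expect_equal(nrow(cl$records), 1L)
  # conservation: records in + none lost unaccounted
  expect_equal(nrow(dup$records),
               nrow(cl$records) + nrow(cl$provenance$removed_records))
})

test_that("seed-mass 3-SD records are flagged for review, not removed", {
  df <- data.frame(species_name = "sp", trait_name = "seed_mass",
                   value = 10^c(rep(0.9, 15), rep(1.1, 15), 1.55),
                   unit = "mg", source_id = paste0("s", 1:31))
  logs <- log10(df$value)
  z <- abs(logs[31] - mean(logs)) / sd(logs)   # oracle: in the (3, 4] flag band
  expect_true(z > 3 && z <= 4)
  cl <- clean_dataset(trait_dataset(df))
  expect_equal(nrow(cl$records), 31L)
  expect_equal(nrow(cl$provenance$seed_mass_flagged), 1L)
  expect_equal(cl$provenance$seed_mass_flagged$source_id, "s31")
  # same deviation on a non-seed-mass trait is not flagged
  df$trait_name <- "SLA"
  expect_null(clean_dataset(trait_dataset(df))$provenance$seed_mass_flagged)
})

test_that("cleaning is idempotent and skips unstable small cells", {
  set.seed(42)
  df <- data.frame(species_name = rep(c("a", "b"), each = 15),
                   trait_name = "SLA",
                   value = 10^rnorm(30, 1, 0.3), unit = "u",
                   source_id = paste0("s", 1:30))
  once <- clean_dataset(trait_dataset(df))
  twice <- clean_dataset(once)
  expect_equal(twice$records, once$records)
  expect_equal(twice$provenance$n_sd_outliers_removed, 0L)

  tiny <- trait_dataset(data.frame(species_name = "a", trait_name = "SLA",
                                   value = c(1, 1e6), source_id = c("p", "q")))
  expect_equal(nrow(clean_dataset(tiny)$records), 2L)  # n < 3: no SD filter
})

test_that("subsetting filters by latitude, site and species, and commutes", {
  ds <- trait_dataset(data.frame(
    species_name = c("a", "b", "c", "d"), trait_name = "SLA",
    value = 1:4, latitude = c(68, 47, NA, 62),
    site = c("Abisko", "Davos", "Abisko", "QHI")))
  north <- subset_dataset(ds, min_latitude = 60)
  expect_setequal(north$records$species_name, c("a", "d"))
  expect_equal(subset_dataset(ds, species = c("a", "b"))$records$species_name,
               c("a", "b"))
  expect_equal(subset_dataset(ds, sites = "Abisko")$records$species_name,
               c("a", "c"))
  ab <- subset_dataset(subset_dataset(ds, min_latitude = 60), sites = "Abisko")
  ba <- subset_dataset(subset_dataset(ds, sites = "Abisko"), min_latitude = 60)
  expect_equal(ab$records, ba$records)
  expect_warning(subset_dataset(ds, sites = "nowhere"), "no records")
})

test_that("cover tables and group schemes validate their invariants", {
  cov <- data.frame(site = "s1", plot = "p1", year = 2020,
                    species_name = c("a", "b"), cover = c(10, 20))
  expect_s3_class(read_cover_table(write_temp_csv(cov)), "cover_table")
  bad <- cov; bad$cover[1] <- -1
  expect_error(read_cover_table(write_temp_csv(bad)), "non-negative")
  dup <- rbind(cov, cov[1, ])
  expect_error(read_cover_table(write_temp_csv(dup)), "duplicated")

  grp <- data.frame(species_name = c("a", "b", "c", "d"),
                    traditional_4 = c("ES", "DS", "G", "F"))
  sch <- read_group_scheme(write_temp_csv(grp), "traditional_4")
  expect_s3_class(sch, "partition")
  expect_equal(sch$k, 4L)
  conflict <- rbind(grp, data.frame(species_name = "a", traditional_4 = "G"))
  expect_error(read_group_scheme(write_temp_csv(conflict), "traditional_4"),
               "conflicting")
})
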