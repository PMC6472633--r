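test_that("generation is reproducible and emits the pipeline's CSV dialects", {
  cfg <- synthetic_config(species_per_group = 5, seed = 71)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$dataset$records, b$dataset$records)
  expect_identical(a$cover, b$cover)
  expect_s3_class(a$dataset, "trait_dataset")
  expect_s3_class(a$scheme, "partition")
  expect_s3_class(a$cover, "cover_table")
  expect_equal(a$scheme$k, 4L)
  expect_equal(length(a$scheme$labels), 20L)
  # round-trips through the readers
  tf <- write_temp_csv(a$dataset$records)
  expect_equal(nrow(read_trait_records(tf)$records), nrow(a$dataset$records))
  expect_s3_class(read_cover_table(write_temp_csv(a$cover)), "cover_table")
})

test_that("the zero-noise limit gives R2 = 1 and perfect recovery", {
  cfg <- synthetic_config(trait_sd_between_species = 0, within_species_sd = 0,
                          missing_fraction = 0, species_per_group = 6,
                          records_per_species = 1, seed = 72)
  b <- generate_dataset(cfg)
  # all species in a group share the trait vector
  mu <- b$truth$species_log_means
  expect_equal(unname(mu[1:6, ]), unname(mu[rep(1, 6), ]))
  m <- build_trait_matrix(b$dataset)
  expect_equal(trait_permanova(m, b$scheme, n_permutations = 0)$r_squared, 1)
})

test_that("null worlds give mean R2 near (a-1)/(n-1) over regenerations", {
  gm <- matrix(1, 4, 2)
  r2 <- vapply(1:100, function(i) {
    cfg <- synthetic_config(n_groups = 4, species_per_group = 20,
                            traits = c("SLA", "LDMC"), group_means = gm,
                            missing_fraction = 0, records_per_species = 1,
                            seed = 7000 + i)
    b <- generate_dataset(cfg)
    m <- build_trait_matrix(b$dataset, traits = c("SLA", "LDMC"),
                            scaling = "none")
    trait_permanova(m, b$scheme, n_permutations = 0)$r_squared
  }, 0)
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - 3 / 79), 3 * se)
})

test_that("species-by-trait missingness thins the complete-case pool binomially", {
  cfg <- synthetic_config(species_per_group = 50,
                          missing_fraction = c(0.5, 0, 0, 0, 0, 0),
                          records_per_species = 1, seed = 73)
  b <- generate_dataset(cfg)
  m <- build_trait_matrix(clean_dataset(b$dataset))
  # 200 species, first trait retained with p = 0.5: binomial(200, 0.5)
  expect_gt(nrow(m), 100 - 3 * sqrt(200 * 0.25))
  expect_lt(nrow(m), 100 + 3 * sqrt(200 * 0.25))
})

test_that("expected_separation_r2 matches its defining ratio", {
  gm <- matrix(1, 4, 2)
  null_cfg <- synthetic_config(group_means = gm, traits = c("SLA", "LDMC"))
  expect_equal(expected_separation_r2(null_cfg), 0)

  # single trait, archetype variance equal to total noise variance -> 0.5
  gm1 <- matrix(c(0, 1, 0, 1), 4, 1)          # population variance 0.25
  cfg1 <- synthetic_config(n_groups = 4, traits = "SLA", group_means = gm1,
                           trait_sd_between_species = sqrt(0.20),
                           within_species_sd = sqrt(0.25),
                           records_per_species = 5)
  expect_equal(expected_separation_r2(cfg1), 0.5)
})

test_that("empirical R2 approaches the expected separation at large n", {
  cfg <- synthetic_config(species_per_group = 150, missing_fraction = 0,
                          records_per_species = 2, seed = 74)
  b <- generate_dataset(cfg)
  m <- build_trait_matrix(b$dataset, scaling = "none")
  emp <- trait_permanova(m, b$scheme, n_permutations = 0)$r_squared
  expect_lt(abs(emp - expected_separation_r2(cfg)), 0.05)
})

test_that("log values are normal at the configured moments", {
  cfg <- synthetic_config(n_groups = 1, species_per_group = 1,
                          traits = "SLA", group_means = matrix(1, 1, 1),
                          trait_sd_between_species = 0,
                          within_species_sd = 0.3, missing_fraction = 0,
                          records_per_species = 10000, seed = 75)
  b <- generate_dataset(cfg)
  lv <- log10(b$dataset$records$value)
  expect_equal(mean(lv), 1, tolerance = 0.02)
  expect_equal(sd(lv), 0.3, tolerance = 0.02)
  # moment-based normality: skewness ~ 0, excess kurtosis ~ 0
  zc <- (lv - mean(lv)) / sd(lv)
  expect_lt(abs(mean(zc^3)), 0.1)
  expect_lt(abs(mean(zc^4) - 3), 0.2)
})

test_that("clustering recovery improves with between-group separation", {
  seps <- c(0.3, 1, 3)
  mean_ari <- vapply(seps, function(s) {
    base <- synthetic_config()$group_means
    ctr <- colMeans(base)
    gm <- sweep(sweep(base, 2, ctr) * s, 2, ctr, "+")
    mean(vapply(1:8, function(rep) {
      cfg <- synthetic_config(group_means = gm, species_per_group = 10,
                              missing_fraction = 0, records_per_species = 1,
                              seed = 760 + rep)
      b <- generate_dataset(cfg)
      m <- build_trait_matrix(b$dataset)
      km <- trait_kmeans(m, 4, n_init = 10, seed = rep)
      ari(km$partition, b$truth$partition)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_ari) >= -0.02))
  expect_gt(mean_ari[3], mean_ari[1])
})

test_that("configs validate their invariants", {
  expect_error(synthetic_config(within_species_sd = -1), "non-negative")
  expect_error(synthetic_config(missing_fraction = 1), "missing_fraction")
  expect_error(synthetic_config(abundance_shape = 0), "positive")
})
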