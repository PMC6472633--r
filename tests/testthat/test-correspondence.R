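test_that("confusion matrices count co-assignment over shared species", {
  sp <- sprintf("s%02d", 1:20)
  a <- partition(named_labels(rep(1:4, each = 5), sp))
  expect_equal(unname(diag(confusion(a, a))), rep(5L, 4))
  b_lab <- a$labels
  b_lab[c("s01", "s06")] <- c("2", "1")   # swap two species across groups
  b <- partition(b_lab)
  cm <- confusion(a, b)
  expect_equal(cm["1", "2"], 1L)
  expect_equal(cm["2", "1"], 1L)
  expect_equal(sum(cm), 20L)

  c6 <- partition(named_labels(rep(1:6, length.out = 20), sp))
  expect_equal(dim(confusion(a, c6)), c(4L, 6L))
  d <- partition(named_labels(1:2, c("x1", "x2")))
  expect_error(confusion(a, d), "share no species")
})

test_that("optimal matching beats greedy and matches hand-computed optima", {
  cm <- matrix(c(5, 4, 0,
                 4, 0, 0,
                 0, 0, 1), 3, byrow = TRUE,
               dimnames = list(paste0("r", 1:3), paste0("c", 1:3)))
  om <- optimal_matching(cm)
  expect_equal(om$n_consistent, 9)          # greedy row-max stops at 6
  expect_equal(om$matching, c(c1 = "r2", c2 = "r1", c3 = "r3"))

  cm2 <- matrix(c(3, 1, 2, 4), 2, byrow = TRUE,
                dimnames = list(c("r1", "r2"), c("c1", "c2")))
  om2 <- optimal_matching(cm2)
  expect_equal(om2$n_consistent, 7)
  expect_equal(om2$matching, c(c1 = "r1", c2 = "r2"))

  diag20 <- diag(5L, 4)
  expect_equal(optimal_matching(diag20)$n_consistent, 20)
})

test_that("exhaustive and Hungarian routes equal the brute-force oracle", {
  set.seed(51)
  for (i in 1:100) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    cm <- matrix(rpois(nr * nc, 3), nr, nc)
    oracle <- matching_oracle(cm)
    expect_equal(optimal_matching(cm, method = "exhaustive")$n_consistent,
                 oracle)
    expect_equal(optimal_matching(cm, method = "hungarian")$n_consistent,
                 oracle)
  }
})

test_that("n_consistent is invariant to relabeling and symmetric in k", {
  set.seed(52)
  sp <- sprintf("s%02d", 1:30)
  a <- partition(named_labels(sample(1:3, 30, TRUE), sp))
  b <- partition(named_labels(sample(1:3, 30, TRUE), sp))
  base <- optimal_matching(confusion(a, b))$n_consistent
  relab <- partition(named_labels(c("9", "7", "5")[as.integer(b$labels)], sp))
  expect_equal(optimal_matching(confusion(a, relab))$n_consistent, base)
  expect_equal(optimal_matching(confusion(b, a))$n_consistent, base)
})

test_that("consistency against itself is perfect; merged clusters reproduce hand counts", {
  sp <- sprintf("s%02d", 1:12)
  ref <- partition(named_labels(rep(c("X", "Y"), each = 6), sp))
  self <- consistency(ref, list(same = ref))
  expect_equal(self$comparisons$same$proportion_overall, 1)
  expect_equal(self$all_methods$consistent_species, sp)

  # comparison merges X and Y into cluster 1 and puts 2 X-species in cluster 2:
  # confusion [[4,2],[6,0]]; optimum matches c1->Y (6) + c2->X (2) = 8
  comp <- partition(named_labels(c("2", "2", rep("1", 10)), sp))
  cs <- consistency(ref, list(m = comp))
  expect_equal(cs$comparisons$m$n_consistent, 8L)
  expect_equal(unname(cs$comparisons$m$proportion_per_group["X"]), 2 / 6)
  expect_equal(unname(cs$comparisons$m$proportion_per_group["Y"]), 6 / 6)
})

test_that("the all-methods set is the intersection of pairwise consistent sets", {
  set.seed(53)
  sp <- sprintf("s%02d", 1:40)
  ref <- partition(named_labels(rep(1:4, each = 10), sp))
  mk <- function() partition(named_labels(sample(1:4, 40, TRUE), sp))
  cs <- consistency(ref, list(a = mk(), b = mk()))
  inter <- intersect(cs$comparisons$a$consistent_species,
                     cs$comparisons$b$consistent_species)
  expect_setequal(cs$all_methods$consistent_species, inter)
  expect_lte(cs$all_methods$proportion_overall,
             min(cs$comparisons$a$proportion_overall,
                 cs$comparisons$b$proportion_overall))
})

test_that("extra cluster labels beyond the reference contribute nothing", {
  sp <- sprintf("s%02d", 1:12)
  ref <- partition(named_labels(rep(c("X", "Y"), each = 6), sp))
  comp <- partition(named_labels(rep(c("1", "2", "3"), each = 4), sp))
  cs <- consistency(ref, list(fine = comp))
  expect_equal(length(cs$comparisons$fine$matching), 2L)  # only 2 matched
  expect_equal(cs$comparisons$fine$n_consistent, 8L)      # 4 + 4
})

test_that("abundance weighting follows most-recent-year, site-mean rules", {
  cov1 <- as_cover_table(data.frame(
    site = "s1", plot = "p1", year = 2020,
    species_name = c("a", "b"), cover = c(30, 10)))
  expect_equal(abundance_weighting("a", cov1, c("a", "b")), 0.75)

  cov2 <- as_cover_table(data.frame(
    site = rep(c("s1", "s2"), each = 2), plot = "p1", year = 2020,
    species_name = rep(c("a", "b"), 2), cover = c(10, 10, 20, 0)))
  expect_equal(abundance_weighting("a", cov2, c("a", "b")), mean(c(0.5, 1)))
  expect_equal(abundance_weighting("a", cov2, c("a", "b"), mode = "pooled"),
               30 / 40)

  # only each plot's most recent year counts
  cov3 <- as_cover_table(data.frame(
    site = "s1", plot = "p1", year = c(2019, 2019, 2020, 2020),
    species_name = c("a", "b", "a", "b"), cover = c(100, 0, 10, 30)))
  expect_equal(abundance_weighting("a", cov3, c("a", "b")), 0.25)

  # equal cover everywhere reduces to the species proportion
  sp <- paste0("s", 1:8)
  cov4 <- as_cover_table(data.frame(
    site = "s1", plot = "p1", year = 2020, species_name = sp, cover = 5))
  expect_equal(abundance_weighting(sp[1:2], cov4, sp), 0.25)

  # sites with no retained species are excluded with a warning
  cov5 <- as_cover_table(data.frame(
    site = c("s1", "s2"), plot = "p1", year = 2020,
    species_name = c("a", "z"), cover = c(10, 10)))
  expect_warning(r <- abundance_weighting("a", cov5, c("a", "b")), "excluded")
  expect_equal(r, 1)
})
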