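# Independent oracles and fixture builders used across the suite.

# adjusted Rand index between two labelings (mclust's implementation serves
# as the independent reference statistic)
ari <- function(a, b) {
  if (inherits(a, "partition")) a <- a$labels
  if (inherits(b, "partition")) b <- b$labels
  common <- intersect(names(a), names(b))
  mclust::adjustedRandIndex(a[common], b[common])
}

# classical one-way ANOVA R^2 and F via stats::aov — the oracle for the
# Euclidean-distance PERMANOVA identity
anova_oracle <- function(values, groups) {
  fit <- stats::anova(stats::aov(values ~ factor(groups)))
  ssb <- fit$`Sum Sq`[1]; ssw <- fit$`Sum Sq`[2]
  list(r2 = ssb / (ssb + ssw), f = fit$`F value`[1])
}

# brute-force optimal assignment over all label permutations of the larger
# side of a padded square matrix
matching_oracle <- function(cm) {
  s <- max(dim(cm))
  pad <- matrix(0, s, s)
  pad[seq_len(nrow(cm)), seq_len(ncol(cm))] <- cm
  perms <- gtools_permutations(s)
  best <- -Inf
  for (r in seq_len(nrow(perms))) {
    val <- sum(pad[cbind(perms[r, ], seq_len(s))])
    if (val > best) best <- val
  }
  best
}

gtools_permutations <- function(s) {
  if (s == 1L) return(matrix(1L))
  sub <- gtools_permutations(s - 1L)
  do.call(rbind, lapply(seq_len(s), function(first)
    cbind(first, matrix(setdiff(seq_len(s), first)[sub], nrow(sub)))))
}

# long-format records from a species-by-trait value matrix (one record per
# cell unless reps > 1)
records_from_matrix <- function(values, reps = 1L) {
  sp <- rownames(values); tr <- colnames(values)
  rows <- expand.grid(species_name = sp, trait_name = tr,
                      stringsAsFactors = FALSE)
  rows$value <- as.vector(values)
  rows <- rows[rep(seq_len(nrow(rows)), each = reps), ]
  rows$source_id <- paste0("src", seq_len(nrow(rows)))
  trait_dataset(rows)
}

# minimal named trait matrix without going through the builder
raw_matrix <- function(values, traits = NULL) {
  m <- as.matrix(values)
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  if (!is.null(traits)) colnames(m) <- traits
  else if (is.null(colnames(m))) colnames(m) <- paste0("t", seq_len(ncol(m)))
  m
}

named_labels <- function(labels, species) stats::setNames(as.character(labels), species)

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}
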