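# Independent oracles, written as explicit element-by-element computations
# so they share no code path with the package implementations.

# One-way ANOVA mean squares by explicit loops over deviations.
oracleAnova <- function(groups) {
  g <- length(groups)
  all <- c()
  for (v in groups) all <- c(all, v)
  n <- length(all)
  grand <- sum(all) / n
  ssb <- 0
  ssw <- 0
  for (v in groups) {
    gm <- sum(v) / length(v)
    ssb <- ssb + length(v) * (gm - grand)^2
    for (y in v) ssw <- ssw + (y - gm)^2
  }
  sumSq <- 0
  for (v in groups) sumSq <- sumSq + length(v)^2
  list(msb = ssb / (g - 1), msw = ssw / (n - g),
       k0 = (n - sumSq / n) / (g - 1))
}

# Average ranks computed from pairwise comparisons (no call to rank()).
oracleAverageRanks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    below <- 0
    ties <- 0
    for (j in seq_len(n)) {
      if (x[j] < x[i]) below <- below + 1
      if (x[j] == x[i]) ties <- ties + 1
    }
    r[i] <- below + (ties + 1) / 2
  }
  r
}

# Spearman rho as the Pearson correlation of average ranks, by explicit sums.
oracleSpearman <- function(x, y) {
  rx <- oracleAverageRanks(x)
  ry <- oracleAverageRanks(y)
  n <- length(x)
  mx <- sum(rx) / n
  my <- sum(ry) / n
  num <- 0
  dx2 <- 0
  dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (rx[i] - mx) * (ry[i] - my)
    dx2 <- dx2 + (rx[i] - mx)^2
    dy2 <- dy2 + (ry[i] - my)^2
  }
  num / sqrt(dx2 * dy2)
}

# Random grouped data for property tests.
randomGroups <- function(nGroups, minSize = 2, maxSize = 4, balanced = FALSE) {
  sizes <- if (balanced) rep(sample(minSize:maxSize, 1), nGroups)
           else sample(minSize:maxSize, nGroups, replace = TRUE)
  lapply(sizes, function(k) rnorm(k, mean = runif(1, -2, 2)))
}

# A tiny triplicate table: one patient, one sample, one target plus the
# three reference channels, all wells at the given Cq values.
tinyTriplicateTable <- function(targetCq = c(20, 20, 20), normCq = 20,
                                target = "miR-21") {
  norm <- c("miR-193a-5p", "miR-27a", "let-7g")
  data.frame(
    patient_id = "P1", sample_id = "S1", deepest_flag = TRUE,
    mirna_id = c(target, norm),
    rep1_cq = c(targetCq[1], rep(normCq, 3)),
    rep2_cq = c(targetCq[2], rep(normCq, 3)),
    rep3_cq = c(targetCq[3], rep(normCq, 3)),
    stringsAsFactors = FALSE
  )
}
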