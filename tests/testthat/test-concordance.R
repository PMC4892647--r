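test_that("rank correlation handles monotone, anti-monotone and tied data", {
  expect_equal(spearmanRho(1:4, c(10, 20, 30, 40)), 1)
  expect_equal(spearmanRho(1:4, c(8, 6, 4, 2)), -1)
  # tie case, frozen from the average-rank oracle
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  expect_equal(oracleSpearman(x, y), 0.9486833, tolerance = 1e-7)
  expect_equal(spearmanRho(x, y), oracleSpearman(x, y), tolerance = 1e-12)
  expect_true(is.na(spearmanRho(c(2, 2, 2), c(1, 2, 3))))  # zero rank variance
  expect_error(spearmanRho(1:3, 1:4), "equal length")
  expect_error(spearmanRho(1:2, 1:2), "at least 3")
})

test_that("rank correlation is invariant under strictly increasing transforms", {
  set.seed(31)
  for (i in 1:30) {
    x <- rnorm(10); y <- rnorm(10)
    rho <- spearmanRho(x, y)
    expect_equal(spearmanRho(exp(x), y), rho, tolerance = 1e-12)
    expect_equal(spearmanRho(x, 3 * y + 7), rho, tolerance = 1e-12)
    expect_equal(spearmanRho(x, x), 1)
  }
  # agreement with the explicit oracle on random tied data
  for (i in 1:30) {
    x <- sample(1:5, 8, replace = TRUE); y <- sample(1:5, 8, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    expect_equal(spearmanRho(x, y), oracleSpearman(x, y), tolerance = 1e-12)
  }
})

makePairFixture <- function() {
  qp <- data.frame(
    patient_id = rep(c("P1", "P2", "P3", "P4"), each = 3),
    sample_id = rep(c("S1", "S2", "S3"), 4),
    deepest_flag = rep(c(FALSE, TRUE, FALSE), 4),
    mirna_id = "miR-21",
    mean_cq = 20, delta_cq = 0,
    linear_value = c(2, 4, 6, 1, 2, 3, 5, 5, 5, 9, 8, 7),
    stringsAsFactors = FALSE)
  ish <- ishFromTable(data.frame(
    patient_id = rep(c("P1", "P2", "P3"), each = 3),
    sample_id = rep(c("S1", "S2", "S3"), 3),
    deepest_flag = rep(c(FALSE, TRUE, FALSE), 3),
    mirna_id = "miR-21",
    area_iB = 0.01, area_wB = (1:9) / 100, area_pB = 0.01,
    roi_area_mm2 = 1, stringsAsFactors = FALSE))
  list(qp = qp, ish = ish)
}

test_that("pairing aggregates within patients and drops incomplete pairs with a count", {
  fx <- makePairFixture()
  expect_warning(pm <- aggregatePairs(fx$qp, fx$ish, "miR-21", "patient_mean"),
                 "dropped 1 patient")
  expect_equal(pm$patient_id, c("P1", "P2", "P3"))
  expect_equal(pm$qpcr, c(4, 2, 5))  # per-patient means of the qPCR values
  expect_equal(attr(pm, "dropped"), 1L)  # P4 has no ISH data
  # deepest-section mode picks exactly the flagged sample
  expect_warning(dp <- aggregatePairs(fx$qp, fx$ish, "miR-21", "deepest_section"))
  expect_equal(dp$qpcr, c(4, 2, 5))
  expect_equal(dp$ish, fx$ish$fraction_TBp[fx$ish$sample_id == "S2"])
})

test_that("the concordance report computes both aggregations per miRNA", {
  st <- genPairedStudy(syntheticConfig(seed = 13))
  et <- buildExpressionTable(st$qpcr)
  rec <- applyRoiFilter(ishFromTable(st$ish))
  rep <- concordanceReport(et, rec)
  expect_setequal(rep$mirna, c("miR-21", "miR-125b", "miR-145", "miR-630"))
  expect_true(all(abs(rep$rho_mean) <= 1 & abs(rep$rho_deepest) <= 1))
  expect_true(all(rep$n_mean <= 27 & rep$n_deepest <= 27))
})

test_that("latent sharing drives cross-modality concordance", {
  # fully shared latent, no within-patient or modality noise: rho = 1
  panel <- defaultMirnaPanel()
  panel$sigma_w <- 0
  cfg1 <- syntheticConfig(panel = panel, technicalSd = 0, latentWeight = 1,
                          ishSigmaW = 0, seed = 17)
  st <- genPairedStudy(cfg1)
  et <- buildExpressionTable(st$qpcr)
  rec <- ishFromTable(st$ish)
  pm <- aggregatePairs(et, rec, "miR-21", "patient_mean")
  expect_equal(spearmanRho(pm$qpcr, pm$ish), 1)
  # shared vs independent latents, averaged over replicates
  rhoAt <- function(w, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- syntheticConfig(latentWeight = w, seed = s)
      st <- genPairedStudy(cfg)
      pm <- aggregatePairs(buildExpressionTable(st$qpcr),
                           ishFromTable(st$ish), "miR-21", "patient_mean")
      spearmanRho(pm$qpcr, pm$ish)
    }, 0))
  }
  seeds <- 1:20
  r0 <- rhoAt(0, seeds); r5 <- rhoAt(0.5, seeds); r9 <- rhoAt(0.95, seeds)
  expect_lt(abs(r0), 0.2)   # independent modalities
  expect_gt(r9, r5)         # monotone in the sharing weight
  expect_gt(r5, r0)
})

test_that("common-scale standardisation centres and scales per stratum", {
  expect_equal(commonScaleNormalise(c(1, 2, 3)), c(-1, 0, 1))  # sample SD = 1
  expect_error(commonScaleNormalise(c(2, 2, 2)), "zero spread")
  expect_error(commonScaleNormalise(3), "at least 2")
  set.seed(41)
  tab <- data.frame(
    mirna_id = rep(c("a", "b"), each = 12),
    modality = rep(c("qpcr", "ish"), times = 12),
    patient_id = rep(c("P1", "P2"), 12),
    sample_id = "S1",
    value = c(rlnorm(12), runif(12)),
    stringsAsFactors = FALSE)
  z <- standardiseCommonScale(tab)
  for (key in unique(paste(z$mirna_id, z$modality))) {
    sub <- z$z[paste(z$mirna_id, z$modality) == key]
    expect_equal(mean(sub), 0, tolerance = 1e-12)
    expect_equal(sd(sub), 1, tolerance = 1e-12)
  }
})
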