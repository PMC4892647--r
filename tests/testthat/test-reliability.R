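test_that("one-way decomposition matches hand-computed sums of squares", {
  d <- onewayAnova(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(msBetween(d), 27)   # SSB = 3*((2-5)^2 + 0 + (8-5)^2) = 54, df 2
  expect_equal(msWithin(d), 1)     # SSW = 2 + 2 + 2 = 6, df 6
  expect_equal(effectiveGroupSize(d), 3)
  expect_equal(iccSingle(d), 26 / 29)
  expect_equal(iccMean(d), 26 / 27)
  expect_equal(varWithin(d), 1)
  expect_equal(varBetween(d), 26 / 3)
})

test_that("unbalanced designs use the effective group size", {
  d <- onewayAnova(list(1:3, 4:6, 7:8))
  expect_equal(effectiveGroupSize(d), (8 - 22 / 8) / 2)  # = 2.625
})

test_that("degenerate inputs are handled explicitly", {
  d <- onewayAnova(list(c(5, 5), c(5, 5)))
  expect_equal(msBetween(d), 0)
  expect_equal(msWithin(d), 0)
  expect_true(is.na(iccSingle(d)))   # undefined, not 0/0
  expect_true(is.na(iccMean(d)))
  expect_warning(d2 <- onewayAnova(list(1:3, numeric(0), 4:6)), "no values")
  expect_equal(d2@nGroups, 2L)
  expect_error(suppressWarnings(onewayAnova(list(1:3, numeric(0)))), "2 groups")
  expect_error(onewayAnova(list(1, 2)), "replication")
  # within-agreement extremes
  perfect <- onewayAnova(list(c(1, 1), c(2, 2), c(3, 3)))
  expect_equal(iccSingle(perfect), 1)
  expect_equal(iccMean(perfect), 1)
})

test_that("mean squares agree with an explicit-loop oracle and with aov on balanced data", {
  set.seed(101)
  for (i in 1:200) {
    g <- randomGroups(sample(2:5, 1), balanced = i %% 2 == 0)
    d <- onewayAnova(g)
    o <- oracleAnova(g)
    expect_equal(msBetween(d), o$msb, tolerance = 1e-12)
    expect_equal(msWithin(d), o$msw, tolerance = 1e-12)
    expect_equal(effectiveGroupSize(d), o$k0, tolerance = 1e-12)
  }
  # independent route: stats::aov mean squares on a balanced design
  g <- randomGroups(5, balanced = TRUE)
  fit <- summary(stats::aov(y ~ f, data.frame(y = unlist(g),
                                              f = factor(rep(seq_along(g), lengths(g))))))
  ms <- fit[[1]][["Mean Sq"]]
  d <- onewayAnova(g)
  expect_equal(msBetween(d), ms[1], tolerance = 1e-10)
  expect_equal(msWithin(d), ms[2], tolerance = 1e-10)
})

test_that("balanced designs satisfy the Spearman-Brown identity to machine precision", {
  set.seed(202)
  for (i in 1:100) {
    g <- randomGroups(sample(3:6, 1), balanced = TRUE)
    d <- onewayAnova(g)
    k <- lengths(g)[1]
    expect_equal(iccMean(d), spearmanBrown(iccSingle(d), k), tolerance = 1e-12)
  }
})

test_that("ICC estimates are scale invariant and negative estimates are not truncated", {
  set.seed(303)
  g <- randomGroups(6)
  d1 <- onewayAnova(g)
  d2 <- onewayAnova(lapply(g, function(v) v * 1000))
  expect_equal(iccSingle(d1), iccSingle(d2), tolerance = 1e-12)
  expect_equal(iccMean(d1), iccMean(d2), tolerance = 1e-12)
  # groups with identical means but huge within-spread give a negative estimate
  gneg <- list(c(-10, 10), c(-10, 10), c(-10, 10), c(-10, 10))
  expect_lt(iccSingle(onewayAnova(gneg)), 0)
  rep <- iccReport(list(sampleMatrix(gneg, "x", "qpcr", "linear")))
  expect_lt(rep$icc_single, 0)
  expect_match(rep$flag, "negative_icc")
})

test_that("spearmanBrown reproduces the single-to-mean transform", {
  expect_equal(round(spearmanBrown(0.650, 3), 3), 0.848)
  expect_equal(spearmanBrown(0, 3), 0)
  expect_equal(spearmanBrown(1, 5), 1)
  expect_error(spearmanBrown(-0.6, 3), "exceed")
})

test_that("the report covers every miRNA x modality and survives per-matrix failures", {
  st <- genPairedStudy(syntheticConfig(seed = 5))
  et <- buildExpressionTable(st$qpcr)
  qe <- makeQpcrExperiment(et)
  ie <- makeIshExperiment(applyRoiFilter(ishFromTable(st$ish)))
  rep <- studyIccReport(qe, ie)
  expect_equal(nrow(rep), 9L)  # 5 qPCR + 4 ISH channels
  expect_equal(rep$signal[rep$mirna == "miR-125b" & rep$method == "ish"], "wpB")
  expect_equal(rep$signal[rep$mirna == "miR-21" & rep$method == "ish"], "TBp")
  # balanced identity holds on the balanced strata of the report
  full <- rep[rep$n_values == 81, ]
  expect_equal(full$icc_mean, spearmanBrown(full$icc_single, 3), tolerance = 1e-12)
  # an unusable matrix yields a flagged row, not an abort
  mats <- list(sampleMatrix(list(P1 = c(1, 2), P2 = c(2, 3)), "ok", "qpcr"),
               new("SampleMatrix", groups = list(P1 = 1, P2 = 2),
                   mirnaId = "bad", modality = "qpcr", signal = "linear"))
  rep2 <- iccReport(mats)
  expect_equal(nrow(rep2), 2L)
  expect_match(rep2$flag[2], "error")
  expect_false(is.na(rep2$icc_single[1]))
})

test_that("exact-F confidence interval brackets the point estimate", {
  set.seed(7)
  g <- lapply(1:20, function(i) rnorm(3, rnorm(1, 0, 2)))
  d <- onewayAnova(g)
  ci <- iccSingleConfint(d)
  expect_lt(ci["lower"], iccSingle(d))
  expect_gt(ci["upper"], iccSingle(d))
})
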