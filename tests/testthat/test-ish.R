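# Build a uniform image of one configured class colour.
uniformImage <- function(class, n = 20, config = colorClassConfig()) {
  col <- unlist(config[config$class == class, c("r", "g", "b")])
  array(rep(col, each = n * n), c(n, n, 3))
}

test_that("pixels at a class centroid colour classify to that class", {
  cfg <- colorClassConfig()
  for (cl in cfg$class) {
    lab <- classifyPixels(uniformImage(cl), matrix(TRUE, 20, 20), cfg)
    expect_true(all(lab == cl))
  }
})

test_that("known class composition is recovered exactly for centroid colours", {
  cfg <- colorClassConfig()
  n <- 100
  img <- uniformImage("nuclear_red", n)          # 70% red
  blue <- unlist(cfg[cfg$class == "intense_blue", c("r", "g", "b")])
  weak <- unlist(cfg[cfg$class == "weak_blue", c("r", "g", "b")])
  for (ch in 1:3) {
    img[1:10, , ch] <- blue[ch]                  # 10% intense blue
    img[11:30, , ch] <- weak[ch]                 # 20% weak blue
  }
  lab <- classifyPixels(img, matrix(TRUE, n, n), cfg)
  prop <- table(lab[!is.na(lab)]) / (n * n)
  expect_equal(as.numeric(prop["intense_blue"]), 0.10)
  expect_equal(as.numeric(prop["weak_blue"]), 0.20)
  expect_equal(as.numeric(prop["nuclear_red"]), 0.70)
})

test_that("tissue-free images contain no blue pixels and ROI handling is validated", {
  lab <- classifyPixels(uniformImage("tissue_free"), matrix(TRUE, 20, 20))
  expect_equal(sum(lab %in% c("intense_blue", "weak_blue", "purple_blue")), 0L)
  # pixels outside the ROI stay unlabeled
  mask <- matrix(FALSE, 20, 20); mask[1:5, 1:5] <- TRUE
  lab <- classifyPixels(uniformImage("unstained"), mask)
  expect_equal(sum(!is.na(lab)), 25L)
  expect_error(classifyPixels(uniformImage("unstained"), matrix(FALSE, 20, 20)),
               "foreground")
  expect_error(classifyPixels(uniformImage("unstained"), matrix(TRUE, 10, 10)),
               "dimensions")
})

test_that("area fractions follow pixel counts and the pixel size", {
  # 1000 x 1000 ROI at 1 um/pixel with 150 000 blue pixels
  labInt <- matrix(match("unstained", defaultColorClasses()$class), 1000, 1000)
  labInt[1:150, ] <- match("weak_blue", defaultColorClasses()$class)
  lab <- structure(as.integer(labInt), dim = c(1000, 1000),
                   levels = defaultColorClasses()$class, class = "factor")
  rec <- computeAreaFractions(lab, pixelSizeUm = 1)
  expect_equal(rec$roi_area_mm2, 1.0)
  expect_equal(rec$fraction_TBp, 0.15)
  expect_equal(rec$fraction_iB, 0)
  expect_equal(rec$fraction_wpB, 0.15)
  # no blue at all
  labInt[] <- match("unstained", defaultColorClasses()$class)
  lab0 <- structure(as.integer(labInt), dim = c(1000, 1000),
                    levels = defaultColorClasses()$class, class = "factor")
  rec0 <- computeAreaFractions(lab0, pixelSizeUm = 1)
  expect_equal(rec0$fraction_TBp + rec0$fraction_iB + rec0$fraction_wpB, 0)
  # all intense blue
  labInt[] <- match("intense_blue", defaultColorClasses()$class)
  lab1 <- structure(as.integer(labInt), dim = c(1000, 1000),
                    levels = defaultColorClasses()$class, class = "factor")
  rec1 <- computeAreaFractions(lab1, pixelSizeUm = 1)
  expect_equal(rec1$fraction_TBp, 1)
  expect_equal(rec1$fraction_iB, 1)
  expect_equal(rec1$fraction_wpB, 0)
})

test_that("fractions are invariant to the physical pixel size; areas are not", {
  im <- genIshImage(c(intense_blue = 0.05, weak_blue = 0.1), imageSize = 64, seed = 2)
  lab <- classifyPixels(im$image, im$roiMask)
  r1 <- computeAreaFractions(lab, pixelSizeUm = 0.22)
  r2 <- computeAreaFractions(lab, pixelSizeUm = 0.44)
  expect_equal(r1$fraction_TBp, r2$fraction_TBp)
  expect_equal(r1$fraction_iB, r2$fraction_iB)
  expect_equal(r2$roi_area_mm2, 4 * r1$roi_area_mm2)
})

test_that("blue area is conserved across the fraction split", {
  st <- genPairedStudy(syntheticConfig(seed = 9))
  rec <- ishFromTable(st$ish)
  expect_equal(rec$fraction_iB + rec$fraction_wpB, rec$fraction_TBp)
  expect_true(all(rec$fraction_iB >= 0 & rec$fraction_TBp <= 1))
})

test_that("the ROI filter excludes strictly below the minimum area, keeping the boundary", {
  rec <- ishFromTable(data.frame(
    patient_id = c("P1", "P2", "P3"), sample_id = "S1", mirna_id = "miR-21",
    area_iB = 0.01, area_wB = 0.02, area_pB = 0.01,
    roi_area_mm2 = c(1.9, 2.0, 5.0), stringsAsFactors = FALSE))
  out <- applyRoiFilter(rec, minArea = 2.0)
  expect_equal(out$excluded, c(TRUE, FALSE, FALSE))
  expect_equal(out$reason, c("small_roi", NA, NA))
  excl <- attr(out, "patientExclusions")
  expect_equal(excl$patient_id, "P1")
  # no exclusions when all ROIs are large enough
  out2 <- applyRoiFilter(rec[rec$roi_area_mm2 >= 2, ], minArea = 2.0)
  expect_false(any(out2$excluded))
})

test_that("signal selection uses wpB for the intense-blue-excluded miRNA in ICC mode only", {
  rec <- ishFromTable(data.frame(
    patient_id = "P1", sample_id = "S1",
    mirna_id = c("miR-125b", "miR-21"),
    area_iB = c(0.002, 0.06), area_wB = c(0.030, 0.14), area_pB = c(0.018, 0.10),
    roi_area_mm2 = 1, stringsAsFactors = FALSE))
  expect_equal(selectSignalFraction(rec, "icc"), c(0.048, 0.30))
  expect_equal(selectSignalFraction(rec, "concordance"), c(0.050, 0.30))
  rec$excluded[1] <- TRUE
  expect_error(selectSignalFraction(rec, "icc"), "excluded")
})

test_that("centroid fitting recovers class colours from labeled pixels", {
  cfg <- colorClassConfig()
  set.seed(4)
  px <- rbind(matrix(rep(c(0.1, 0.1, 0.5), each = 30), 30) + rnorm(90, 0, 0.01),
              matrix(rep(c(0.9, 0.3, 0.4), each = 30), 30) + rnorm(90, 0, 0.01))
  fit <- fitClassCentroids(px, rep(c("intense_blue", "nuclear_red"), each = 30), cfg)
  expect_equal(unlist(fit[fit$class == "intense_blue", c("r", "g", "b")]),
               c(r = 0.1, g = 0.1, b = 0.5), tolerance = 0.02)
  expect_error(fitClassCentroids(px, rep("nonsense", 60), cfg), "unknown class")
})
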