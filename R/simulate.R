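#' Default per-miRNA simulation parameters
#'
#' One row per target miRNA of the study panel with the Cq-scale location
#' and variance components and the ISH area-fraction band. Cq bands and
#' ISH fraction ranges follow the observed ranges of the study design this
#' generator emulates (e.g. raw miR-21 Cq within 17.4-21.6, miR-21 TBp
#' fractions within 0.0091-0.5751). `has_ish` is `FALSE` for miR-31, which
#' is measured by RT-qPCR only. `ib_share` is the share of the total blue
#' signal belonging to the intense-blue class (kept very small for
#' miR-125b, where intense blue marks enteric neurons).
#'
#' @return A data frame of per-miRNA parameters.
#' @export
defaultMirnaPanel <- function() {
  data.frame(
    mirna_id = c("miR-21", "miR-31", "miR-125b", "miR-145", "miR-630"),
    mean_cq = c(19.5, 24.5, 23.3, 20.2, 32.6),
    sigma_b = c(0.50, 1.20, 0.70, 0.60, 0.80),
    sigma_w = c(0.30, 0.55, 0.75, 1.10, 1.10),
    cq_lo = c(17.4, 20.9, 20.4, 15.9, 28.5),
    cq_hi = c(21.6, 28.7, 26.3, 24.4, 36.7),
    has_ish = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    ish_lo = c(0.0091, NA, 0.0004, 0.0002, 0.0012),
    ish_hi = c(0.5751, NA, 0.0848, 0.1141, 0.1302),
    ib_share = c(0.20, NA, 0.02, 0.15, 0.15),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic two-modality study
#'
#' Collects everything the generator needs: the study design (27 patients,
#' 3 within-tumour samples, triplicate wells), the Cq-scale variance
#' components per miRNA, the reference-miRNA channels, the detection
#' ceiling, the ISH noise and cross-modality latent sharing, and the image
#' geometry.
#'
#' @param nPatients number of patients (default 27).
#' @param k within-tumour samples per patient (default 3).
#' @param panel per-miRNA parameters, see [defaultMirnaPanel()].
#' @param normaliserMeanCq named mean Cq of the three reference miRNAs.
#' @param normaliserSd SD of the per-sample reference-channel fluctuation
#'   (cycles); it cancels out of delta-Cq by construction.
#' @param technicalSd SD of replicate-level technical noise (cycles).
#' @param detectionCeiling Cq above which a replicate is undetected.
#' @param latentWeight cross-modality sharing weight in \[0, 1\]: 1 makes
#'   the ISH patient signal a deterministic monotone function of the qPCR
#'   patient effect, 0 makes the modalities independent.
#' @param ishSigmaW within-patient SD of the ISH latent (logit-like scale).
#' @param roiMeanLog,roiSdLog log-normal parameters of the simulated ROI
#'   areas (mm^2).
#' @param imageSize edge length in pixels of generated ISH images.
#' @param seed integer random seed; every generator output is a pure
#'   function of the configuration including this seed.
#' @return A validated configuration list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(nPatients = 27, k = 3,
                            panel = defaultMirnaPanel(),
                            normaliserMeanCq = c("miR-193a-5p" = 22.0,
                                                 "miR-27a" = 19.0,
                                                 "let-7g" = 21.0),
                            normaliserSd = 0.3,
                            technicalSd = 0.1,
                            detectionCeiling = 37,
                            latentWeight = 0.3,
                            ishSigmaW = 0.5,
                            roiMeanLog = log(8), roiSdLog = 0.6,
                            imageSize = 256L,
                            seed = 1L) {
  stopifnot(nPatients >= 2, k >= 1, length(normaliserMeanCq) == 3L,
            normaliserSd >= 0, technicalSd >= 0, detectionCeiling > 0,
            latentWeight >= 0, latentWeight <= 1, ishSigmaW >= 0,
            imageSize >= 16)
  stopifnot(all(panel$sigma_b >= 0), all(panel$sigma_w >= 0))
  structure(list(
    nPatients = as.integer(nPatients), k = as.integer(k), panel = panel,
    normaliserMeanCq = normaliserMeanCq, normaliserSd = normaliserSd,
    technicalSd = technicalSd, detectionCeiling = detectionCeiling,
    latentWeight = latentWeight, ishSigmaW = ishSigmaW,
    roiMeanLog = roiMeanLog, roiSdLog = roiSdLog,
    imageSize = as.integer(imageSize), seed = as.integer(seed)
  ), class = "SyntheticConfig")
}

#' Cq-scale variance components for a target linear-scale ICC
#'
#' The analysis runs on linear \eqn{2^{-\Delta Cq}} values, which are
#' log-normal when the Cq-scale effects are Gaussian. For between-SD
#' \eqn{\sigma_b} and within-SD \eqn{\sigma_w} on the Cq scale, the
#' intraclass correlation of the linear values is
#' \deqn{ICC_{lin} = (e^{c^2\sigma_b^2} - 1) / (e^{c^2(\sigma_b^2+\sigma_w^2)} - 1),
#'   \quad c = \ln 2.}
#' This helper inverts that relation: given a target linear-scale ICC and
#' a total Cq-scale SD, it returns the `sigma_b`/`sigma_w` pair realising
#' it.
#'
#' @param icc target linear-scale ICC in (0, 1).
#' @param totalSd total Cq-scale SD \eqn{\sqrt{\sigma_b^2 + \sigma_w^2}}
#'   (default 1 cycle).
#' @return Named list `sigma_b`, `sigma_w`, plus `icc_cq` (the Cq-scale
#'   ICC implied by the same components).
#' @export
sigmaForLinearIcc <- function(icc, totalSd = 1) {
  stopifnot(icc > 0, icc < 1, totalSd > 0)
  c2 <- log(2)^2
  v <- totalSd^2
  sb2 <- log(1 + icc * (exp(c2 * v) - 1)) / c2
  stopifnot(sb2 < v)
  list(sigma_b = sqrt(sb2), sigma_w = sqrt(v - sb2), icc_cq = sb2 / v)
}

#' @describeIn sigmaForLinearIcc forward direction: the linear-scale ICC
#'   implied by Cq-scale components.
#' @param sigmaB,sigmaW Cq-scale between- and within-patient SDs.
#' @export
linearIccFromSigmas <- function(sigmaB, sigmaW) {
  c2 <- log(2)^2
  (exp(c2 * sigmaB^2) - 1) / (exp(c2 * (sigmaB^2 + sigmaW^2)) - 1)
}

#' Generate a synthetic RT-qPCR triplicate table
#'
#' Simulates the two-level Gaussian model on the Cq scale: per patient
#' \eqn{i} a patient effect \eqn{b_i \sim N(0, \sigma_b^2)}, per sample
#' \eqn{j} a delta-Cq \eqn{\Delta Cq_{ij} = \mu + b_i + e_{ij}},
#' \eqn{e_{ij} \sim N(0, \sigma_w^2)}; reference channels fluctuate per
#' sample and the target Cq is constructed so that arithmetic-mean
#' normalisation recovers \eqn{\Delta Cq_{ij}} exactly (before technical
#' noise). Replicate wells add \eqn{N(0, \sigma_{tech}^2)} noise and any
#' replicate Cq above the detection ceiling is blanked (undetected).
#'
#' @param cfg a [syntheticConfig()].
#' @return List with `table` (triplicate layout: `patient_id`,
#'   `sample_id`, `deepest_flag`, `mirna_id`, `rep1_cq`, `rep2_cq`,
#'   `rep3_cq`) and `truth` (per-miRNA patient effects, delta-Cq matrices,
#'   and the Cq-scale and linear-scale ICC implied by the configuration).
#' @export
genQpcrDataset <- function(cfg = syntheticConfig()) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  set.seed(cfg$seed)
  .genQpcr(cfg, u = NULL)
}

# Internal: generate the qPCR table given (optionally) pre-drawn standard
# normal patient effects per miRNA (for latent sharing with the ISH side).
# Uses the current RNG state.
.genQpcr <- function(cfg, u = NULL) {
  n <- cfg$nPatients
  k <- cfg$k
  panel <- cfg$panel
  patients <- sprintf("P%02d", seq_len(n))
  samples <- sprintf("S%d", seq_len(k))
  normMu <- cfg$normaliserMeanCq
  normIds <- names(normMu)
  muNorm <- mean(normMu)
  deepestIdx <- sample.int(k, n, replace = TRUE)

  # per-sample reference-channel fluctuations (shared by all miRNAs of a sample)
  normDev <- array(stats::rnorm(n * k * 3L, 0, cfg$normaliserSd), c(n, k, 3L))

  truth <- list(patientEffects = list(), deltaCq = list(),
                iccCq = stats::setNames(numeric(0), character(0)),
                iccLinear = stats::setNames(numeric(0), character(0)),
                deepestIdx = stats::setNames(deepestIdx, patients))
  rows <- vector("list", nrow(panel) + 1L)

  for (p in seq_len(nrow(panel))) {
    mid <- panel$mirna_id[p]
    sb <- panel$sigma_b[p]; sw <- panel$sigma_w[p]
    ui <- if (is.null(u)) stats::rnorm(n) else u[[mid]]
    b <- sb * ui
    e <- matrix(stats::rnorm(n * k, 0, sw), n, k)
    muDelta <- panel$mean_cq[p] - muNorm
    dcq <- muDelta + b + e  # n x k true delta-Cq
    normSampleMean <- muNorm + apply(normDev, c(1, 2), mean)
    targetCq <- dcq + normSampleMean
    reps <- array(rep(targetCq, 3L) +
                    stats::rnorm(n * k * 3L, 0, cfg$technicalSd), c(n, k, 3L))
    reps[reps > cfg$detectionCeiling] <- NA_real_
    rows[[p]] <- data.frame(
      patient_id = rep(patients, times = k),
      sample_id = rep(samples, each = n),
      deepest_flag = rep(deepestIdx, times = k) == rep(seq_len(k), each = n),
      mirna_id = mid,
      rep1_cq = as.vector(reps[, , 1L]),
      rep2_cq = as.vector(reps[, , 2L]),
      rep3_cq = as.vector(reps[, , 3L]),
      stringsAsFactors = FALSE)
    truth$patientEffects[[mid]] <- stats::setNames(b, patients)
    truth$deltaCq[[mid]] <- dcq
    truth$iccCq[mid] <- if (sb + sw > 0) sb^2 / (sb^2 + sw^2) else NA_real_
    truth$iccLinear[mid] <- linearIccFromSigmas(sb, sw)
  }

  # reference-miRNA channels
  normRows <- vector("list", 3L)
  for (q in seq_len(3L)) {
    cq <- normMu[q] + normDev[, , q]  # n x k mean Cq of this reference channel
    reps <- array(rep(cq, 3L) + stats::rnorm(n * cfg$k * 3L, 0, cfg$technicalSd),
                  c(n, k, 3L))
    normRows[[q]] <- data.frame(
      patient_id = rep(patients, times = k),
      sample_id = rep(samples, each = n),
      deepest_flag = rep(deepestIdx, times = k) == rep(seq_len(k), each = n),
      mirna_id = normIds[q],
      rep1_cq = as.vector(reps[, , 1L]),
      rep2_cq = as.vector(reps[, , 2L]),
      rep3_cq = as.vector(reps[, , 3L]),
      stringsAsFactors = FALSE)
  }
  rows[[nrow(panel) + 1L]] <- do.call(rbind, normRows)
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$patient_id, tab$sample_id, tab$mirna_id), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, truth = truth)
}

#' Generate a synthetic ISH image with known class fractions
#'
#' Draws non-overlapping elliptical blobs at the colour-class centroid
#' colours on an unstained-tissue background until each class's pixel
#' share reaches its target within 0.5 percentage points; blob edges get
#' one pixel of linear colour blending (anti-aliasing). The realised
#' fractions (exact pixel counts of the label raster) are returned as
#' ground truth.
#'
#' @param targetFractions named numeric vector of target area fractions
#'   for any of `intense_blue`, `weak_blue`, `purple_blue`, `nuclear_red`;
#'   must sum to at most 1 (the remainder is unstained background).
#' @param imageSize image edge length in pixels.
#' @param seed integer seed; identical seeds give bit-identical images.
#' @param config colour configuration, see [colorClassConfig()].
#' @return List with `image` (RGB array), `roiMask` (all-`TRUE` logical
#'   matrix), `labels` (the generator's label factor matrix) and
#'   `fractions` (realised per-class pixel fractions).
#' @export
genIshImage <- function(targetFractions, imageSize = 256L, seed = 1L,
                        config = colorClassConfig()) {
  allowed <- c("intense_blue", "weak_blue", "purple_blue", "nuclear_red")
  bad <- setdiff(names(targetFractions), allowed)
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
  if (any(targetFractions < 0) || sum(targetFractions) > 1)
    stop("target fractions must be non-negative and sum to at most 1")
  set.seed(seed)
  h <- w <- as.integer(imageSize)
  npx <- h * w
  bg <- unlist(config[config$class == "unstained", c("r", "g", "b")])
  bgIdx <- match("unstained", config$class)
  img <- array(rep(bg, each = npx), c(h, w, 3L))
  labInt <- matrix(bgIdx, h, w)

  ew <- 0.5  # anti-aliased edge width, pixels

  for (cl in names(targetFractions)) {
    target <- targetFractions[[cl]] * npx
    if (target <= 0) next
    # stop once within 0.15 percentage points of the target, but never
    # demand a resolution finer than one minimal blob (~14 px)
    tol <- max(14, min(0.0015 * npx, 0.25 * target))
    col <- unlist(config[config$class == cl, c("r", "g", "b")])
    clIdx <- match(cl, config$class)
    placed <- 0
    tries <- 0L
    while (target - placed > tol && tries < 50000L) {
      tries <- tries + 1L
      deficit <- target - placed
      rmax <- max(2, min(12, floor(sqrt(deficit / pi))))
      a <- stats::runif(1, 2, rmax)
      b <- stats::runif(1, 2, rmax)
      cx <- stats::runif(1, b + 2, w - b - 1)
      cy <- stats::runif(1, a + 2, h - a - 1)
      # rasterise only the blob's bounding box
      rows <- max(1L, floor(cy - a - 1)):min(h, ceiling(cy + a + 1))
      colsIdx <- max(1L, floor(cx - b - 1)):min(w, ceiling(cx + b + 1))
      d <- sqrt(outer(((rows - cy) / a)^2, ((colsIdx - cx) / b)^2, "+"))
      reach <- d <= 1 + ew / min(a, b)
      gIdx <- as.vector(outer(rows, (colsIdx - 1L) * h, "+"))  # global indices
      reachIdx <- gIdx[reach]
      # blobs of the same class may coalesce; other classes are never touched
      lab <- labInt[reachIdx]
      if (any(lab != bgIdx & lab != clIdx)) next
      inner <- d[reach] <= 1
      innerIdx <- reachIdx[inner]
      edgeIdx <- reachIdx[!inner]
      # blend fraction of the blob colour in the edge ring (1 at d = 1)
      wgt <- 1 - (d[reach][!inner] - 1) * min(a, b) / ew
      for (ch in 1:3) {
        off <- (ch - 1L) * npx
        img[off + innerIdx] <- col[ch]
        img[off + edgeIdx] <- wgt * col[ch] + (1 - wgt) * img[off + edgeIdx]
      }
      # a pixel belongs to the class when the blob colour dominates
      claimIdx <- c(innerIdx, edgeIdx[wgt > 0.5])
      newPx <- sum(labInt[claimIdx] != clIdx)
      labInt[claimIdx] <- clIdx
      placed <- placed + newPx
    }
  }
  labels <- structure(as.integer(labInt), dim = c(h, w),
                      levels = config$class, class = "factor")
  counts <- tabulate(labInt, nbins = nrow(config))
  list(image = img, roiMask = matrix(TRUE, h, w), labels = labels,
       fractions = stats::setNames(counts / npx, config$class))
}

#' Generate a full paired synthetic study
#'
#' Couples the two modalities through shared patient-level structure: the
#' qPCR side follows the two-level Cq model of [genQpcrDataset()]; the ISH
#' side maps, per miRNA, a patient latent
#' \eqn{\eta_i = w\,\ell_i + \sqrt{1-w^2}\,z_i} (where \eqn{\ell_i} is the
#' standardised qPCR patient effect on the expression scale, \eqn{z_i}
#' independent noise and \eqn{w} the latent-sharing weight) plus
#' within-patient noise through a monotone transform into the miRNA's
#' area-fraction band. ROI areas are log-normal; blue areas follow the
#' simulated TBp fraction split into intense/weak/purple blue by
#' `ib_share`.
#'
#' @param cfg a [syntheticConfig()].
#' @return List with `qpcr` (triplicate table), `ish` (ISH area table with
#'   `deepest_flag`), and `truth` (qPCR truth plus per-miRNA ISH latents,
#'   true TBp fractions and the latent weight).
#' @export
genPairedStudy <- function(cfg = syntheticConfig()) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  set.seed(cfg$seed)
  n <- cfg$nPatients
  k <- cfg$k
  panel <- cfg$panel
  patients <- sprintf("P%02d", seq_len(n))
  samples <- sprintf("S%d", seq_len(k))

  u <- stats::setNames(lapply(seq_len(nrow(panel)), function(p) stats::rnorm(n)),
                       panel$mirna_id)
  qp <- .genQpcr(cfg, u = u)
  w <- cfg$latentWeight

  ishPanel <- panel[panel$has_ish, , drop = FALSE]
  rows <- vector("list", nrow(ishPanel))
  truthIsh <- list()
  for (p in seq_len(nrow(ishPanel))) {
    mid <- ishPanel$mirna_id[p]
    # expression-scale latent: high expression = low Cq, hence -u
    ell <- -u[[mid]]
    z <- stats::rnorm(n)
    eta <- w * ell + sqrt(max(0, 1 - w^2)) * z
    etaSamp <- matrix(eta, n, k) + matrix(stats::rnorm(n * k, 0, cfg$ishSigmaW), n, k)
    lo <- ishPanel$ish_lo[p]; hi <- ishPanel$ish_hi[p]
    tbp <- lo * (hi / lo)^stats::plogis(etaSamp)
    roi <- matrix(stats::rlnorm(n * k, cfg$roiMeanLog, cfg$roiSdLog), n, k)
    ibs <- ishPanel$ib_share[p]
    areaTBp <- tbp * roi
    rows[[p]] <- data.frame(
      patient_id = rep(patients, times = k),
      sample_id = rep(samples, each = n),
      deepest_flag = rep(qp$truth$deepestIdx, times = k) ==
        rep(seq_len(k), each = n),
      mirna_id = mid,
      area_iB = as.vector(areaTBp * ibs),
      area_wB = as.vector(areaTBp * (1 - ibs) * 0.6),
      area_pB = as.vector(areaTBp * (1 - ibs) * 0.4),
      roi_area_mm2 = as.vector(roi),
      stringsAsFactors = FALSE)
    truthIsh[[mid]] <- list(eta = stats::setNames(eta, patients), tbp = tbp)
  }
  ish <- do.call(rbind, rows)
  ish <- ish[order(ish$patient_id, ish$sample_id, ish$mirna_id), , drop = FALSE]
  rownames(ish) <- NULL
  list(qpcr = qp$table, ish = ish,
       truth = c(qp$truth, list(ish = truthIsh, latentWeight = w)))
}
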