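#' Colour-class configuration for ISH pixel classification
#'
#' The chromogenic ISH slides contain six pixel populations: the dark blue
#' NBT/BCIP precipitate (`intense_blue`), weaker background blue
#' (`weak_blue`), blue overlying the nuclear-fast-red counterstain
#' (`purple_blue`), the red counterstain itself (`nuclear_red`), unstained
#' or weakly stained tissue (`unstained`) and tissue-free glass
#' (`tissue_free`). Each class is described by an RGB centroid plus
#' per-channel tolerances in HSV space; classification assigns every ROI
#' pixel to the nearest centroid, so the classes are exhaustive and
#' mutually exclusive.
#'
#' @param centroids data frame with columns `class`, `r`, `g`, `b` (RGB in
#'   \[0, 1\]) and `tol_h`, `tol_s`, `tol_v` (positive HSV tolerances used
#'   as per-channel distance scales). Defaults to [defaultColorClasses()].
#' @return The validated centroid data frame, classed `"ColorClassConfig"`.
#' @export
colorClassConfig <- function(centroids = defaultColorClasses()) {
  need <- c("class", "r", "g", "b", "tol_h", "tol_s", "tol_v")
  miss <- setdiff(need, names(centroids))
  if (length(miss))
    stop("color class config missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(centroids$class)) stop("duplicate class names")
  rgb <- as.matrix(centroids[, c("r", "g", "b")])
  if (any(rgb < 0 | rgb > 1)) stop("RGB centroids must lie in [0, 1]")
  tol <- as.matrix(centroids[, c("tol_h", "tol_s", "tol_v")])
  if (any(tol <= 0)) stop("tolerances must be positive")
  structure(centroids, class = c("ColorClassConfig", class(centroids)))
}

#' @describeIn colorClassConfig default centroids and tolerances for the six
#'   classes. Hue tolerances are widened for the two near-achromatic classes,
#'   where hue is uninformative.
#' @export
defaultColorClasses <- function() {
  data.frame(
    class = c("intense_blue", "weak_blue", "purple_blue",
              "nuclear_red", "unstained", "tissue_free"),
    r = c(0.08, 0.60, 0.45, 0.83, 0.93, 0.99),
    g = c(0.08, 0.68, 0.25, 0.33, 0.88, 0.99),
    b = c(0.40, 0.88, 0.55, 0.42, 0.90, 0.99),
    tol_h = c(0.08, 0.08, 0.08, 0.08, 0.50, 0.50),
    tol_s = c(0.30, 0.30, 0.30, 0.30, 0.30, 0.30),
    tol_v = c(0.30, 0.30, 0.30, 0.30, 0.30, 0.30),
    stringsAsFactors = FALSE
  )
}

# Scaled HSV distance between pixel HSV triples and one class centroid.
# Hue distance is circular (hue lives on [0, 1) mod 1).
.classDistance <- function(hsv, centroidHsv, tol) {
  dh <- abs(hsv[1L, ] - centroidHsv[1L])
  dh <- pmin(dh, 1 - dh)
  ds <- hsv[2L, ] - centroidHsv[2L]
  dv <- hsv[3L, ] - centroidHsv[3L]
  sqrt((dh / tol[1L])^2 + (ds / tol[2L])^2 + (dv / tol[3L])^2)
}

#' Classify ROI pixels into colour classes
#'
#' Deterministic nearest-centroid classification in HSV space: every pixel
#' inside the ROI is assigned the class whose centroid is closest under a
#' tolerance-scaled HSV distance with circular hue; pixels outside the ROI
#' are left unlabeled (`NA`).
#'
#' @param image numeric array `height x width x 3`, RGB in \[0, 1\].
#' @param roiMask logical matrix of the same height/width; `TRUE` = inside
#'   the ROI. An artefact mask can be pre-subtracted by clearing its pixels.
#' @param config a [colorClassConfig()].
#' @return A factor matrix (`height x width`) with the class levels of
#'   `config`; `NA` outside the ROI.
#' @export
classifyPixels <- function(image, roiMask, config = colorClassConfig()) {
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("image must be a height x width x 3 RGB array")
  if (!identical(dim(image)[1:2], dim(roiMask)))
    stop("image and roiMask dimensions differ")
  roiMask <- roiMask & !is.na(roiMask)
  if (!any(roiMask)) stop("ROI mask has no foreground pixels")
  config <- colorClassConfig(config)

  idx <- which(roiMask)
  n <- length(idx)
  npx <- prod(dim(roiMask))
  px <- rbind(image[idx], image[npx + idx], image[2L * npx + idx])
  hsv <- grDevices::rgb2hsv(px[1L, ], px[2L, ], px[3L, ], maxColorValue = 1)
  cenHsv <- grDevices::rgb2hsv(config$r, config$g, config$b, maxColorValue = 1)

  best <- rep.int(1L, n)
  bestD <- .classDistance(hsv, cenHsv[, 1L], unlist(config[1L, c("tol_h", "tol_s", "tol_v")]))
  for (j in seq_len(nrow(config))[-1L]) {
    d <- .classDistance(hsv, cenHsv[, j], unlist(config[j, c("tol_h", "tol_s", "tol_v")]))
    upd <- d < bestD
    best[upd] <- j
    bestD[upd] <- d[upd]
  }
  labInt <- rep.int(NA_integer_, npx)
  labInt[idx] <- best
  structure(labInt, dim = dim(roiMask), levels = config$class,
            class = "factor")
}

#' Compute class areas and area fractions for one ROI
#'
#' Converts pixel counts of the blue classes into areas (mm^2) and area
#' fractions of the ROI: `fraction_TBp` is the total blue fraction
#' (intense + weak + purple blue), `fraction_iB` the intense-blue fraction
#' and `fraction_wpB = fraction_TBp - fraction_iB` the blue fraction with
#' the intense class removed.
#'
#' @param labels factor matrix from [classifyPixels()] (`NA` outside ROI).
#' @param pixelSizeUm physical pixel edge length in micrometres
#'   (default 0.22, a typical 20x slide-scanner resolution).
#' @param patientId,sampleId,mirnaId identifiers carried into the record.
#' @return One-row data frame with columns `patient_id`, `sample_id`,
#'   `mirna_id`, `area_iB`, `area_wB`, `area_pB`, `roi_area_mm2`,
#'   `fraction_TBp`, `fraction_iB`, `fraction_wpB`, `excluded`, `reason`.
#' @export
computeAreaFractions <- function(labels, pixelSizeUm = 0.22,
                                 patientId = NA_character_,
                                 sampleId = NA_character_,
                                 mirnaId = NA_character_) {
  stopifnot(is.numeric(pixelSizeUm), pixelSizeUm > 0)
  inRoi <- !is.na(labels)
  nRoi <- sum(inRoi)
  if (nRoi == 0L) stop("ROI area is zero")
  mm2PerPx <- (pixelSizeUm / 1000)^2
  cnt <- table(labels[inRoi])
  nIB <- as.numeric(cnt["intense_blue"])
  nWB <- as.numeric(cnt["weak_blue"])
  nPB <- as.numeric(cnt["purple_blue"])
  nIB <- if (is.na(nIB)) 0 else nIB
  nWB <- if (is.na(nWB)) 0 else nWB
  nPB <- if (is.na(nPB)) 0 else nPB
  data.frame(
    patient_id = as.character(patientId),
    sample_id = as.character(sampleId),
    mirna_id = as.character(mirnaId),
    area_iB = nIB * mm2PerPx,
    area_wB = nWB * mm2PerPx,
    area_pB = nPB * mm2PerPx,
    roi_area_mm2 = nRoi * mm2PerPx,
    fraction_TBp = (nIB + nWB + nPB) / nRoi,
    fraction_iB = nIB / nRoi,
    fraction_wpB = (nWB + nPB) / nRoi,
    excluded = FALSE,
    reason = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Build ISH quantification records from a tabular export
#'
#' Constructs the per-ROI records directly from class areas (the layout of
#' an image-analysis export: one row per patient x sample x miRNA with the
#' three blue-class areas and the ROI area), bypassing pixel
#' classification.
#'
#' @param tab data frame with columns `patient_id`, `sample_id`,
#'   `mirna_id`, `area_iB`, `area_wB`, `area_pB`, `roi_area_mm2` and
#'   optionally `deepest_flag`.
#' @return Records in the same shape as [computeAreaFractions()], with a
#'   `deepest_flag` column.
#' @export
ishFromTable <- function(tab) {
  need <- c("patient_id", "sample_id", "mirna_id",
            "area_iB", "area_wB", "area_pB", "roi_area_mm2")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("ISH table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(tab$roi_area_mm2 <= 0)) stop("roi_area_mm2 must be positive")
  areas <- as.matrix(tab[, c("area_iB", "area_wB", "area_pB")])
  if (any(areas < 0)) stop("class areas must be non-negative")
  if (any(rowSums(areas) > tab$roi_area_mm2 * (1 + 1e-9)))
    stop("blue class areas exceed the ROI area")
  out <- data.frame(
    patient_id = as.character(tab$patient_id),
    sample_id = as.character(tab$sample_id),
    mirna_id = as.character(tab$mirna_id),
    area_iB = tab$area_iB,
    area_wB = tab$area_wB,
    area_pB = tab$area_pB,
    roi_area_mm2 = tab$roi_area_mm2,
    fraction_TBp = rowSums(areas) / tab$roi_area_mm2,
    fraction_iB = tab$area_iB / tab$roi_area_mm2,
    fraction_wpB = (tab$area_wB + tab$area_pB) / tab$roi_area_mm2,
    excluded = FALSE,
    reason = NA_character_,
    stringsAsFactors = FALSE
  )
  out$deepest_flag <- if ("deepest_flag" %in% names(tab))
    as.logical(tab$deepest_flag) else FALSE
  out
}

#' Flag records with a small ROI
#'
#' Marks records whose ROI is smaller than `minArea` as excluded (reason
#' `"small_roi"`); a record at exactly `minArea` is retained. A per-miRNA
#' patient-exclusion report (patients with at least one excluded sample) is
#' attached as attribute `"patientExclusions"`.
#'
#' @param records ISH records ([ishFromTable()] / [computeAreaFractions()]).
#' @param minArea minimal ROI area in mm^2 (default 2.0).
#' @return The records with updated `excluded`/`reason` columns.
#' @export
applyRoiFilter <- function(records, minArea = 2.0) {
  stopifnot(is.numeric(minArea), minArea > 0)
  small <- records$roi_area_mm2 < minArea
  records$excluded <- records$excluded | small
  records$reason[small] <- "small_roi"
  excl <- records[records$excluded, c("mirna_id", "patient_id"), drop = FALSE]
  excl <- unique(excl)
  excl <- excl[order(excl$mirna_id, excl$patient_id), , drop = FALSE]
  rownames(excl) <- NULL
  attr(records, "patientExclusions") <- excl
  records
}

#' Select the signal fraction for an analysis purpose
#'
#' For the reliability (ICC) analysis, miRNAs listed in `wpbMirnas` use the
#' `wpB` fraction (total blue minus intense blue; by default miR-125b,
#' whose intense-blue staining marks enteric neurons present regardless of
#' cancer) and all others use the total blue fraction `TBp`. For the
#' cross-modality concordance analysis `TBp` is used for every miRNA,
#' since RT-qPCR measures total expression regardless of localisation.
#'
#' @param records ISH records; must not contain excluded rows.
#' @param purpose `"icc"` or `"concordance"`.
#' @param wpbMirnas miRNAs whose ICC uses the `wpB` fraction.
#' @return Numeric vector of fractions, one per record row.
#' @export
selectSignalFraction <- function(records, purpose = c("icc", "concordance"),
                                 wpbMirnas = "miR-125b") {
  purpose <- match.arg(purpose)
  if (any(records$excluded))
    stop("excluded records must be removed before selecting signal fractions")
  if (purpose == "concordance") {
    return(records$fraction_TBp)
  }
  ifelse(records$mirna_id %in% wpbMirnas,
         records$fraction_wpB, records$fraction_TBp)
}

#' Fit colour-class centroids from labeled pixel samples
#'
#' A minimal training helper: given example pixels and their class labels,
#' sets each class centroid to the mean RGB of its examples (tolerances are
#' kept from `template`).
#'
#' @param pixels numeric matrix `n x 3` of RGB values in \[0, 1\].
#' @param labels character/factor vector of class names, length `n`.
#' @param template config providing the class set and tolerances.
#' @return A [colorClassConfig()] with refitted centroids.
#' @export
fitClassCentroids <- function(pixels, labels, template = colorClassConfig()) {
  stopifnot(is.matrix(pixels), ncol(pixels) == 3L, nrow(pixels) == length(labels))
  labels <- as.character(labels)
  unknown <- setdiff(unique(labels), template$class)
  if (length(unknown))
    stop("unknown class label(s): ", paste(unknown, collapse = ", "))
  for (cl in intersect(template$class, labels)) {
    i <- labels == cl
    template[template$class == cl, c("r", "g", "b")] <-
      as.list(colMeans(pixels[i, , drop = FALSE]))
  }
  colorClassConfig(template)
}
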