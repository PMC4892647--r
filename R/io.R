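#' Read a raw RT-qPCR triplicate table
#'
#' Reads the canonical CSV/TSV layout (one row per patient x sample x
#' miRNA with up to three replicate Cq values; the layout the synthetic
#' generator emits). Blank cells become undetected replicates (`NA`);
#' non-numeric Cq entries and missing columns are reported with their
#' location.
#'
#' @param path path to a CSV (or TSV, by extension) file with columns
#'   `patient_id`, `sample_id`, `deepest_flag`, `mirna_id`, `rep1_cq`,
#'   `rep2_cq`, `rep3_cq`.
#' @return A data frame of triplicates.
#' @export
readQpcrTable <- function(path) {
  tab <- .readTable(path)
  need <- c("patient_id", "sample_id", "mirna_id", "rep1_cq", "rep2_cq", "rep3_cq")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("qPCR table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("rep1_cq", "rep2_cq", "rep3_cq")) {
    raw <- tab[[col]]
    blank <- is.na(raw) | trimws(as.character(raw)) == ""
    num <- suppressWarnings(as.numeric(as.character(raw)))
    bad <- which(!blank & is.na(num))
    if (length(bad))
      stop("non-numeric Cq in column ", col, " at data row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    num[blank] <- NA_real_
    tab[[col]] <- num
  }
  if (!"deepest_flag" %in% names(tab)) tab$deepest_flag <- FALSE
  tab$deepest_flag <- .asLogical(tab$deepest_flag)
  tab
}

#' Read an ISH image-quantification table
#'
#' Reads the tabular ISH export (per patient x sample x miRNA class areas
#' and ROI area in mm^2) used by the tabular bypass of the image module.
#'
#' @param path path to a CSV/TSV file with columns `patient_id`,
#'   `sample_id`, `mirna_id`, `area_iB`, `area_wB`, `area_pB`,
#'   `roi_area_mm2` and optionally `deepest_flag`.
#' @return The validated data frame.
#' @export
readIshTable <- function(path) {
  tab <- .readTable(path)
  need <- c("patient_id", "sample_id", "mirna_id",
            "area_iB", "area_wB", "area_pB", "roi_area_mm2")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("ISH table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("area_iB", "area_wB", "area_pB", "roi_area_mm2")) {
    num <- suppressWarnings(as.numeric(as.character(tab[[col]])))
    bad <- which(is.na(num) & !is.na(tab[[col]]))
    if (length(bad))
      stop("non-numeric value in column ", col, " at data row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    tab[[col]] <- num
  }
  if ("deepest_flag" %in% names(tab)) tab$deepest_flag <- .asLogical(tab$deepest_flag)
  tab
}

.readTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), check.names = TRUE)
}

.asLogical <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Pipeline configuration
#'
#' Bundles the file paths and thresholds of a full two-modality run.
#' A YAML file with the same field names can be loaded via `configFile`;
#' explicitly supplied arguments override file values.
#'
#' @param qpcrPath path to the raw triplicate table.
#' @param ishPath path to the ISH quantification table.
#' @param outDir output directory (created if missing).
#' @param outlierThreshold replicate outlier threshold, cycles.
#' @param minRoiMm2 minimal ROI area, mm^2.
#' @param pixelSizeUm physical pixel size for image-based quantification.
#' @param wpbMirnas miRNAs whose ICC uses the wpB fraction.
#' @param k design target samples per patient.
#' @param configFile optional YAML file with any of the above fields.
#' @return A named list of class `"RunConfig"`.
#' @export
pipelineConfig <- function(qpcrPath = NULL, ishPath = NULL, outDir = "mirith-out",
                           outlierThreshold = 0.5, minRoiMm2 = 2.0,
                           pixelSizeUm = 0.22, wpbMirnas = "miR-125b",
                           k = 3, configFile = NULL) {
  cfg <- list(qpcrPath = qpcrPath, ishPath = ishPath, outDir = outDir,
              outlierThreshold = outlierThreshold, minRoiMm2 = minRoiMm2,
              pixelSizeUm = pixelSizeUm, wpbMirnas = wpbMirnas, k = k)
  if (!is.null(configFile)) {
    fromFile <- yaml::read_yaml(configFile)
    explicit <- names(as.list(match.call())[-1])
    for (f in setdiff(intersect(names(fromFile), names(cfg)), explicit))
      cfg[[f]] <- fromFile[[f]]
  }
  stopifnot(cfg$outlierThreshold > 0, cfg$minRoiMm2 > 0, cfg$pixelSizeUm > 0)
  structure(cfg, class = "RunConfig")
}

#' Run the full two-modality heterogeneity pipeline
#'
#' Reads the raw tables, builds the normalised expression table and the
#' ISH quantification records, applies the ROI-size filter, computes the
#' reliability (ICC) report and the cross-modality concordance report,
#' standardises all values to the common scale for plotting, and writes
#' everything to `outDir`:
#' \itemize{
#'   \item `expression.csv` — per-measurement qPCR results
#'   \item `ish_quant.csv` — per-ROI ISH fractions with exclusion flags
#'   \item `icc_report.csv` — ICC(single)/ICC(mean) per miRNA x modality
#'   \item `concordance_report.csv` — Spearman rho per miRNA
#'   \item `common_scale.csv` — standardised values for the range plot
#'   \item `exclusions.csv` — every excluded record with a reason code
#'   \item `run_summary.json` — configuration echo and counts
#' }
#' The run is deterministic: rerunning with identical inputs and
#' configuration yields byte-identical outputs.
#'
#' @param config a [pipelineConfig()].
#' @return Invisibly, a list with all in-memory results
#'   (`expression`, `ish`, `icc`, `concordance`, `commonScale`,
#'   `exclusions`, `files`).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(config$qpcrPath) && is.null(config$ishPath))
    stop("pipeline: at least one of qpcrPath/ishPath is required")
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  exclusions <- list()
  files <- character()

  exprTab <- NULL
  qpcrExp <- NULL
  if (!is.null(config$qpcrPath)) {
    trip <- tryCatch(readQpcrTable(config$qpcrPath),
                     error = function(e) stop("stage qpcr_read: ",
                                              conditionMessage(e), call. = FALSE))
    exprTab <- tryCatch(buildExpressionTable(trip, config$outlierThreshold),
                        error = function(e) stop("stage qpcr_quant: ",
                                                 conditionMessage(e), call. = FALSE))
    lg <- expressionLog(exprTab)
    if (nrow(lg)) {
      lg$stage <- "qpcr_quant"
      exclusions[[length(exclusions) + 1L]] <- lg
    }
    qpcrExp <- makeQpcrExperiment(exprTab)
    f <- file.path(config$outDir, "expression.csv")
    utils::write.csv(exprTab, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }

  ishRecords <- NULL
  ishExp <- NULL
  if (!is.null(config$ishPath)) {
    ishTab <- tryCatch(readIshTable(config$ishPath),
                       error = function(e) stop("stage ish_read: ",
                                                conditionMessage(e), call. = FALSE))
    ishRecords <- tryCatch(ishFromTable(ishTab),
                           error = function(e) stop("stage ish_quant: ",
                                                    conditionMessage(e), call. = FALSE))
    ishRecords <- applyRoiFilter(ishRecords, config$minRoiMm2)
    ex <- ishRecords[ishRecords$excluded,
                     c("patient_id", "sample_id", "mirna_id", "reason")]
    if (nrow(ex)) {
      ex$stage <- "ish_quant"
      exclusions[[length(exclusions) + 1L]] <- ex
    }
    ishExp <- makeIshExperiment(ishRecords)
    f <- file.path(config$outDir, "ish_quant.csv")
    utils::write.csv(ishRecords, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }

  icc <- studyIccReport(qpcr = qpcrExp, ish = ishExp, k = config$k,
                        wpbMirnas = config$wpbMirnas)
  f <- file.path(config$outDir, "icc_report.csv")
  utils::write.csv(icc, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  concord <- NULL
  if (!is.null(exprTab) && !is.null(ishRecords)) {
    concord <- concordanceReport(exprTab, ishRecords)
    f <- file.path(config$outDir, "concordance_report.csv")
    utils::write.csv(concord, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }

  long <- list()
  if (!is.null(exprTab))
    long[[1L]] <- data.frame(mirna_id = exprTab$mirna_id, modality = "qpcr",
                             patient_id = exprTab$patient_id,
                             sample_id = exprTab$sample_id,
                             value = exprTab$linear_value,
                             stringsAsFactors = FALSE)
  if (!is.null(ishRecords)) {
    keep <- !ishRecords$excluded
    long[[length(long) + 1L]] <- data.frame(
      mirna_id = ishRecords$mirna_id[keep], modality = "ish",
      patient_id = ishRecords$patient_id[keep],
      sample_id = ishRecords$sample_id[keep],
      value = ishRecords$fraction_TBp[keep],
      stringsAsFactors = FALSE)
  }
  common <- standardiseCommonScale(do.call(rbind, long))
  f <- file.path(config$outDir, "common_scale.csv")
  utils::write.csv(common, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  excl <- if (length(exclusions)) {
    cols <- c("patient_id", "sample_id", "mirna_id", "reason", "stage")
    do.call(rbind, lapply(exclusions, function(d) d[, cols]))
  } else {
    data.frame(patient_id = character(), sample_id = character(),
               mirna_id = character(), reason = character(),
               stage = character(), stringsAsFactors = FALSE)
  }
  excl <- excl[order(excl$stage, excl$patient_id, excl$sample_id,
                     excl$mirna_id, excl$reason), , drop = FALSE]
  rownames(excl) <- NULL
  f <- file.path(config$outDir, "exclusions.csv")
  utils::write.csv(excl, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  summary <- list(
    config = unclass(config)[c("outlierThreshold", "minRoiMm2", "pixelSizeUm",
                               "wpbMirnas", "k")],
    n_expression = if (is.null(exprTab)) 0L else nrow(exprTab),
    n_ish = if (is.null(ishRecords)) 0L else nrow(ishRecords),
    n_exclusions = nrow(excl),
    exclusion_reasons = as.list(table(excl$reason))
  )
  f <- file.path(config$outDir, "run_summary.json")
  jsonlite::write_json(summary, f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, f)

  invisible(list(expression = exprTab, ish = ishRecords, icc = icc,
                 concordance = concord, commonScale = common,
                 exclusions = excl, files = files))
}

#' Write a synthetic study to disk
#'
#' Emits the qPCR triplicate table and the ISH quantification table of a
#' [genPairedStudy()] result in the canonical CSV layouts, plus a JSON
#' truth file sufficient to recompute every downstream expected value.
#'
#' @param study result of [genPairedStudy()].
#' @param dir output directory.
#' @return Named character vector of the written paths.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qf <- file.path(dir, "qpcr_triplicates.csv")
  sf <- file.path(dir, "ish_quant_table.csv")
  tf <- file.path(dir, "truth.json")
  utils::write.csv(study$qpcr, qf, row.names = FALSE, quote = FALSE)
  utils::write.csv(study$ish, sf, row.names = FALSE, quote = FALSE)
  truth <- study$truth
  truth$deltaCq <- lapply(truth$deltaCq, function(m) unname(as.data.frame(m)))
  truth$ish <- lapply(truth$ish, function(x)
    list(eta = as.list(x$eta), tbp = unname(as.data.frame(x$tbp))))
  jsonlite::write_json(truth, tf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(qpcr = qf, ish = sf, truth = tf)
}

#' Write / read an RGB image as PNG
#'
#' Thin wrappers over the png package for the synthetic ISH images and
#' binary masks.
#'
#' @param image numeric array `h x w x 3` (or a logical matrix for masks).
#' @param path file path.
#' @return `writeImagePng()` returns `path` invisibly; `readImagePng()`
#'   returns a numeric array.
#' @export
writeImagePng <- function(image, path) {
  if (is.logical(image)) image <- matrix(as.numeric(image), nrow(image))
  png::writePNG(image, path)
  invisible(path)
}

#' @rdname writeImagePng
#' @export
readImagePng <- function(path) {
  png::readPNG(path)
}
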