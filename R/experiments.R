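#' Assemble a QpcrExperiment from an expression table
#'
#' Pivots the tidy expression table ([buildExpressionTable()]) into a
#' miRNA x (patient x sample) [QpcrExperiment]. Missing (undetected or
#' non-normalisable) measurements become `NA` entries.
#'
#' @param expressionTable data frame with columns `patient_id`,
#'   `sample_id`, `deepest_flag`, `mirna_id`, `mean_cq`, `delta_cq`,
#'   `linear_value`.
#' @return A [QpcrExperiment].
#' @export
makeQpcrExperiment <- function(expressionTable) {
  .makeMeasurementSE(expressionTable,
                     values = c(meanCq = "mean_cq", deltaCq = "delta_cq",
                                linear = "linear_value"),
                     class = "QpcrExperiment")
}

#' Assemble an IshExperiment from quantification records
#'
#' Pivots ISH records ([ishFromTable()] / [computeAreaFractions()], after
#' [applyRoiFilter()]) into a miRNA x (patient x sample) [IshExperiment].
#'
#' @param records ISH record data frame with a `deepest_flag` column.
#' @return An [IshExperiment].
#' @export
makeIshExperiment <- function(records) {
  records$excluded_num <- as.numeric(records$excluded)
  .makeMeasurementSE(records,
                     values = c(TBp = "fraction_TBp", iB = "fraction_iB",
                                wpB = "fraction_wpB", roiArea = "roi_area_mm2",
                                excluded = "excluded_num"),
                     class = "IshExperiment")
}

.makeMeasurementSE <- function(tab, values, class) {
  need <- c("patient_id", "sample_id", "mirna_id", unname(values))
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"deepest_flag" %in% names(tab)) tab$deepest_flag <- FALSE
  colKey <- paste(tab$patient_id, tab$sample_id, sep = ".")
  cols <- unique(data.frame(key = colKey, patient = as.character(tab$patient_id),
                            sample = as.character(tab$sample_id),
                            deepest = as.logical(tab$deepest_flag),
                            stringsAsFactors = FALSE))
  cols <- cols[order(cols$patient, cols$sample), , drop = FALSE]
  mirnas <- sort(unique(as.character(tab$mirna_id)))
  assays <- lapply(values, function(col) {
    m <- matrix(NA_real_, nrow = length(mirnas), ncol = nrow(cols),
                dimnames = list(mirnas, cols$key))
    m[cbind(match(tab$mirna_id, mirnas), match(colKey, cols$key))] <- tab[[col]]
    m
  })
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    colData = S4Vectors::DataFrame(patient = cols$patient, sample = cols$sample,
                                   deepest = cols$deepest, row.names = cols$key))
  methods::new(class, se)
}

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "QpcrExperiment", function(x, mirna, ...) {
  if (!mirna %in% rownames(x)) stop("unknown miRNA: ", mirna)
  v <- SummarizedExperiment::assay(x, "linear")[mirna, ]
  patient <- SummarizedExperiment::colData(x)$patient
  sampleMatrix(split(unname(v), patient), mirnaId = mirna,
               modality = "qpcr", signal = "linear")
})

#' @rdname sampleGroups
#' @param purpose,wpbMirnas see [selectSignalFraction()].
#' @export
setMethod("sampleGroups", "IshExperiment",
          function(x, mirna, purpose = c("icc", "concordance"),
                   wpbMirnas = "miR-125b", ...) {
  purpose <- match.arg(purpose)
  if (!mirna %in% rownames(x)) stop("unknown miRNA: ", mirna)
  signal <- if (purpose == "icc" && mirna %in% wpbMirnas) "wpB" else "TBp"
  v <- SummarizedExperiment::assay(x, signal)[mirna, ]
  excl <- SummarizedExperiment::assay(x, "excluded")[mirna, ]
  v[!is.na(excl) & excl > 0] <- NA_real_
  patient <- SummarizedExperiment::colData(x)$patient
  sampleMatrix(split(unname(v), patient), mirnaId = mirna,
               modality = "ish", signal = signal)
})

setMethod("show", "VarianceComponents", function(object) {
  cat("One-way random-effects variance decomposition\n")
  cat(sprintf("  groups: %d  total N: %d  k0: %.4g\n",
              object@nGroups, object@totalN, object@k0))
  cat(sprintf("  MS between: %.6g  MS within: %.6g\n",
              object@msBetween, object@msWithin))
  cat(sprintf("  var between: %.6g  var within: %.6g\n",
              object@varBetween, object@varWithin))
})

setMethod("show", "IccEstimate", function(object) {
  cat("Intraclass correlation (one-way random effects)\n")
  cat(sprintf("  ICC(single): %.4f  ICC(mean of k=%g): %.4f\n",
              object@iccSingle, object@k, object@iccMean))
})

setMethod("show", "SampleMatrix", function(object) {
  cat(sprintf("SampleMatrix: %s [%s, %s] — %d patients, %d values\n",
              object@mirnaId, object@modality, object@signal,
              length(object@groups), sum(lengths(object@groups))))
})

setMethod("show", "QpcrExperiment", function(object) {
  methods::callNextMethod()
  cat(sprintf("qPCR relative expression: %d miRNA(s), %d patient-sample column(s)\n",
              nrow(object), ncol(object)))
})

setMethod("show", "IshExperiment", function(object) {
  methods::callNextMethod()
  excl <- SummarizedExperiment::assay(object, "excluded")
  cat(sprintf("ISH area fractions: %d miRNA(s), %d excluded record(s)\n",
              nrow(object), sum(excl > 0, na.rm = TRUE)))
})

#' Compute an IccEstimate from grouped data
#'
#' Convenience wrapper pairing [iccSingle()] and [iccMean()] with the
#' design k in one object.
#'
#' @param x a [SampleMatrix] or list of per-patient numeric vectors.
#' @param k design target samples per patient (default 3).
#' @return An [IccEstimate].
#' @export
iccEstimate <- function(x, k = 3) {
  d <- onewayAnova(x)
  methods::new("IccEstimate", iccSingle = iccSingle(d), iccMean = iccMean(d),
               k = k, components = d)
}
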