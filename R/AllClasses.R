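#' Variance components from a one-way random-effects decomposition
#'
#' Holds the between-patient and within-patient mean squares, degrees of
#' freedom, the effective group size \eqn{k_0} for unbalanced designs, and
#' the derived variance components. Produced by [onewayAnova()].
#'
#' The effective group size is
#' \eqn{k_0 = (N - \sum_i k_i^2 / N) / (g - 1)} where \eqn{k_i} are the
#' group sizes, \eqn{N} the total number of values and \eqn{g} the number
#' of groups; for balanced designs \eqn{k_0 = k}.
#'
#' @slot nGroups number of patients (groups) retained.
#' @slot totalN total number of measurements.
#' @slot groupSizes integer vector of per-group sizes.
#' @slot msBetween between-group mean square.
#' @slot msWithin within-group mean square.
#' @slot k0 effective group size.
#' @slot varBetween between-patient variance component,
#'   \eqn{\max(0, (MS_B - MS_W)/k_0)}.
#' @slot varWithin within-patient variance component (\eqn{= MS_W}).
#' @aliases msBetween msWithin varBetween varWithin effectiveGroupSize
#' @seealso [iccSingle()], [iccMean()]
#' @export
setClass("VarianceComponents",
  representation(
    nGroups = "integer",
    totalN = "integer",
    groupSizes = "integer",
    msBetween = "numeric",
    msWithin = "numeric",
    k0 = "numeric",
    varBetween = "numeric",
    varWithin = "numeric"
  )
)

setValidity("VarianceComponents", function(object) {
  msgs <- character()
  if (object@nGroups < 2L)
    msgs <- c(msgs, "nGroups must be >= 2")
  if (object@totalN <= object@nGroups)
    msgs <- c(msgs, "totalN must exceed nGroups (within-group replication required)")
  if (!is.finite(object@msBetween) || object@msBetween < 0)
    msgs <- c(msgs, "msBetween must be finite and >= 0")
  if (!is.finite(object@msWithin) || object@msWithin < 0)
    msgs <- c(msgs, "msWithin must be finite and >= 0")
  if (length(object@groupSizes) != object@nGroups)
    msgs <- c(msgs, "groupSizes length must equal nGroups")
  if (length(msgs)) msgs else TRUE
})

#' Per-patient measurement groups for one miRNA and modality
#'
#' A light container for the grouped data entering the reliability
#' analysis: one list element per patient holding that patient's available
#' measurements (linear qPCR values or ISH area fractions). Excluded or
#' undetected samples are simply absent, so unbalanced designs are allowed.
#'
#' @slot groups named list of numeric vectors, one per patient.
#' @slot mirnaId miRNA identifier.
#' @slot modality `"qpcr"` or `"ish"`.
#' @slot signal label of the value used (e.g. `"linear"`, `"TBp"`, `"wpB"`).
#' @seealso [sampleMatrix()], [onewayAnova()]
#' @export
setClass("SampleMatrix",
  representation(
    groups = "list",
    mirnaId = "character",
    modality = "character",
    signal = "character"
  )
)

setValidity("SampleMatrix", function(object) {
  msgs <- character()
  if (length(object@groups) < 2L)
    msgs <- c(msgs, "need at least 2 patient groups")
  ok <- vapply(object@groups, function(v) is.numeric(v) && all(is.finite(v)), TRUE)
  if (!all(ok))
    msgs <- c(msgs, "all group values must be finite numerics")
  if (!object@modality %in% c("qpcr", "ish"))
    msgs <- c(msgs, "modality must be 'qpcr' or 'ish'")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SampleMatrix-class constructor.
#' @param groups named list of per-patient numeric vectors (empty groups are
#'   dropped with a warning by [onewayAnova()], not here).
#' @param mirnaId,modality,signal metadata carried along into reports.
#' @export
sampleMatrix <- function(groups, mirnaId = NA_character_,
                         modality = c("qpcr", "ish"), signal = NA_character_) {
  modality <- match.arg(modality)
  groups <- lapply(groups, function(v) as.numeric(v[!is.na(v)]))
  groups <- groups[lengths(groups) > 0L]
  new("SampleMatrix", groups = groups, mirnaId = as.character(mirnaId),
      modality = modality, signal = as.character(signal))
}

#' Intraclass correlation estimates for one miRNA and modality
#'
#' Pairs the single-sample and mean-of-k ICC with the design target k and
#' the underlying [VarianceComponents]. For balanced designs the two ICCs
#' are linked by the Spearman-Brown relation
#' \eqn{ICC_{mean} = k\,ICC_{single} / (1 + (k-1)\,ICC_{single})}.
#'
#' @slot iccSingle single-sample ICC (may be negative; never truncated).
#' @slot iccMean mean-of-k ICC.
#' @slot k design target number of samples per patient.
#' @slot components the [VarianceComponents] behind the estimates.
#' @export
setClass("IccEstimate",
  representation(
    iccSingle = "numeric",
    iccMean = "numeric",
    k = "numeric",
    components = "VarianceComponents"
  )
)

#' RT-qPCR expression measurements as a SummarizedExperiment
#'
#' Rows are miRNAs, columns are patient x sample combinations. Required
#' assays: `meanCq`, `deltaCq`, `linear` (\eqn{2^{-\Delta Cq}}); required
#' colData columns: `patient`, `sample`, `deepest` (logical flag marking
#' the section containing the deepest tumour invasion). Undetected
#' measurements are `NA`.
#'
#' @seealso [makeQpcrExperiment()]
#' @export
setClass("QpcrExperiment", contains = "SummarizedExperiment")

setValidity("QpcrExperiment", function(object) {
  msgs <- character()
  need <- c("meanCq", "deltaCq", "linear")
  miss <- setdiff(need, SummarizedExperiment::assayNames(object))
  if (length(miss))
    msgs <- c(msgs, paste("missing assay(s):", paste(miss, collapse = ", ")))
  needCol <- c("patient", "sample", "deepest")
  missCol <- setdiff(needCol, colnames(SummarizedExperiment::colData(object)))
  if (length(missCol))
    msgs <- c(msgs, paste("missing colData column(s):", paste(missCol, collapse = ", ")))
  if (!length(miss)) {
    lin <- SummarizedExperiment::assay(object, "linear")
    if (any(lin <= 0, na.rm = TRUE))
      msgs <- c(msgs, "linear values must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' ISH area-fraction measurements as a SummarizedExperiment
#'
#' Rows are miRNAs, columns are patient x sample combinations. Required
#' assays: `TBp`, `iB`, `wpB` (area fractions in \[0, 1\]), `roiArea`
#' (mm^2) and `excluded` (0/1 flag for records removed by the ROI-size
#' filter); required colData columns: `patient`, `sample`, `deepest`.
#'
#' @seealso [makeIshExperiment()]
#' @export
setClass("IshExperiment", contains = "SummarizedExperiment")

setValidity("IshExperiment", function(object) {
  msgs <- character()
  need <- c("TBp", "iB", "wpB", "roiArea", "excluded")
  miss <- setdiff(need, SummarizedExperiment::assayNames(object))
  if (length(miss))
    msgs <- c(msgs, paste("missing assay(s):", paste(miss, collapse = ", ")))
  needCol <- c("patient", "sample", "deepest")
  missCol <- setdiff(needCol, colnames(SummarizedExperiment::colData(object)))
  if (length(missCol))
    msgs <- c(msgs, paste("missing colData column(s):", paste(missCol, collapse = ", ")))
  if (!length(miss)) {
    tbp <- SummarizedExperiment::assay(object, "TBp")
    ib <- SummarizedExperiment::assay(object, "iB")
    bad <- !is.na(tbp) & !is.na(ib) & (tbp < 0 | tbp > 1 | ib < 0 | ib > tbp + 1e-12)
    if (any(bad))
      msgs <- c(msgs, "fractions must satisfy 0 <= iB <= TBp <= 1")
  }
  if (length(msgs)) msgs else TRUE
})
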