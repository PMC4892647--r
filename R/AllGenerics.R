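#' @include AllClasses.R
NULL

#' Intraclass correlation for a single sample
#'
#' One-way random-effects ICC for a single measurement per patient,
#' \eqn{(MS_B - MS_W) / (MS_B + (k_0 - 1) MS_W)}.
#'
#' @param x a [VarianceComponents], [IccEstimate] or [SampleMatrix] object.
#' @return A numeric scalar, or `NA` when both mean squares are zero
#'   (the estimate is undefined for perfectly constant data).
#' @seealso [iccMean()], [spearmanBrown()], [onewayAnova()]
#' @export
setGeneric("iccSingle", function(x) standardGeneric("iccSingle"))

#' Intraclass correlation for the mean of k samples
#'
#' One-way random-effects ICC for the per-patient mean,
#' \eqn{(MS_B - MS_W) / MS_B}. For balanced designs it equals
#' `spearmanBrown(iccSingle(x), k)` exactly.
#'
#' @inheritParams iccSingle
#' @return A numeric scalar, or `NA` when `msBetween` is zero.
#' @export
setGeneric("iccMean", function(x) standardGeneric("iccMean"))

#' @rdname VarianceComponents-class
#' @param x a `VarianceComponents` object.
#' @export
setGeneric("msBetween", function(x) standardGeneric("msBetween"))

#' @rdname VarianceComponents-class
#' @export
setGeneric("msWithin", function(x) standardGeneric("msWithin"))

#' @rdname VarianceComponents-class
#' @export
setGeneric("varBetween", function(x) standardGeneric("varBetween"))

#' @rdname VarianceComponents-class
#' @export
setGeneric("varWithin", function(x) standardGeneric("varWithin"))

#' @rdname VarianceComponents-class
#' @export
setGeneric("effectiveGroupSize", function(x) standardGeneric("effectiveGroupSize"))

#' Extract per-patient measurement groups
#'
#' Builds a [SampleMatrix] (per-patient lists of values for one miRNA and
#' one modality) from a measurement container, dropping missing values so
#' that unbalanced designs are represented faithfully.
#'
#' @param x a [QpcrExperiment] or [IshExperiment].
#' @param mirna miRNA identifier (a rowname of `x`).
#' @param ... passed to methods; for `IshExperiment`, `purpose` selects the
#'   signal fraction (see [selectSignalFraction()]).
#' @return A [SampleMatrix].
#' @export
setGeneric("sampleGroups", function(x, mirna, ...) standardGeneric("sampleGroups"))
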