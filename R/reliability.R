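#' One-way random-effects variance decomposition
#'
#' Decomposes grouped measurements (patients as groups, within-tumour
#' samples as replicates) into between- and within-patient mean squares:
#' \eqn{MS_B = SS_B/(g-1)}, \eqn{MS_W = SS_W/(N-g)}, with the effective
#' group size \eqn{k_0 = (N - \sum k_i^2/N)/(g-1)} handling unbalanced
#' designs (undetected or excluded samples). Variance components are
#' \eqn{\hat\sigma^2_w = MS_W} and
#' \eqn{\hat\sigma^2_b = \max(0, (MS_B - MS_W)/k_0)}.
#'
#' @param x a [SampleMatrix] or a list of per-patient numeric vectors.
#' @param ... unused.
#' @return A [VarianceComponents] object.
#' @examples
#' d <- onewayAnova(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' msBetween(d)  # 27
#' msWithin(d)   # 1
#' @export
setGeneric("onewayAnova", function(x, ...) standardGeneric("onewayAnova"))

.onewayAnovaCore <- function(groups) {
  groups <- lapply(groups, function(v) as.numeric(v[!is.na(v)]))
  empty <- lengths(groups) == 0L
  if (any(empty)) {
    warning(sprintf("dropping %d group(s) with no values", sum(empty)))
    groups <- groups[!empty]
  }
  g <- length(groups)
  if (g < 2L) stop("need at least 2 groups with values")
  y <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(y))) stop("all values must be finite")
  n <- length(y)
  if (n <= g) stop("need within-group replication (total N must exceed group count)")
  sizes <- lengths(groups)
  means <- vapply(groups, mean, 0)
  grand <- mean(y)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  msb <- ssb / (g - 1L)
  msw <- ssw / (n - g)
  k0 <- (n - sum(sizes^2) / n) / (g - 1L)
  new("VarianceComponents",
      nGroups = as.integer(g), totalN = as.integer(n),
      groupSizes = as.integer(sizes),
      msBetween = msb, msWithin = msw, k0 = k0,
      varBetween = max(0, (msb - msw) / k0), varWithin = msw)
}

#' @rdname onewayAnova
#' @export
setMethod("onewayAnova", "list", function(x, ...) .onewayAnovaCore(x))

#' @rdname onewayAnova
#' @export
setMethod("onewayAnova", "SampleMatrix", function(x, ...) .onewayAnovaCore(x@groups))

#' @rdname VarianceComponents-class
#' @export
setMethod("msBetween", "VarianceComponents", function(x) x@msBetween)

#' @rdname VarianceComponents-class
#' @export
setMethod("msWithin", "VarianceComponents", function(x) x@msWithin)

#' @rdname VarianceComponents-class
#' @export
setMethod("varBetween", "VarianceComponents", function(x) x@varBetween)

#' @rdname VarianceComponents-class
#' @export
setMethod("varWithin", "VarianceComponents", function(x) x@varWithin)

#' @rdname VarianceComponents-class
#' @export
setMethod("effectiveGroupSize", "VarianceComponents", function(x) x@k0)

#' @rdname iccSingle
#' @export
setMethod("iccSingle", "VarianceComponents", function(x) {
  if (x@msBetween == 0 && x@msWithin == 0) return(NA_real_)
  (x@msBetween - x@msWithin) / (x@msBetween + (x@k0 - 1) * x@msWithin)
})

#' @rdname iccMean
#' @export
setMethod("iccMean", "VarianceComponents", function(x) {
  if (x@msBetween == 0) return(NA_real_)
  (x@msBetween - x@msWithin) / x@msBetween
})

#' @rdname iccSingle
#' @export
setMethod("iccSingle", "SampleMatrix", function(x) iccSingle(onewayAnova(x)))

#' @rdname iccMean
#' @export
setMethod("iccMean", "SampleMatrix", function(x) iccMean(onewayAnova(x)))

#' @rdname iccSingle
#' @export
setMethod("iccSingle", "IccEstimate", function(x) x@iccSingle)

#' @rdname iccMean
#' @export
setMethod("iccMean", "IccEstimate", function(x) x@iccMean)

#' Spearman-Brown step-up of a reliability coefficient
#'
#' Reliability of the mean of `k` measurements given the single-measurement
#' reliability: \eqn{k\,r / (1 + (k-1)\,r)}. For a balanced one-way
#' random-effects design this is exactly the relation between the
#' single-sample and mean-of-k ICC.
#'
#' @param icc single-measurement reliability; vectorised.
#' @param k number of measurements averaged (default 3, the study design).
#' @return The stepped-up reliability.
#' @examples
#' spearmanBrown(0.650, 3)  # 0.848 to 3 decimals
#' @export
spearmanBrown <- function(icc, k = 3) {
  stopifnot(is.numeric(icc), is.numeric(k), k >= 1)
  if (k > 1 && any(icc <= -1 / (k - 1), na.rm = TRUE))
    stop("icc must exceed -1/(k-1)")
  k * icc / (1 + (k - 1) * icc)
}

#' Reliability report across miRNAs and modalities
#'
#' Computes the single-sample and mean-of-k ICC for each [SampleMatrix] in
#' `matrices`. A matrix that fails (too few groups, no replication) yields
#' a flagged row with `NA` estimates rather than aborting the report.
#' Negative ICC estimates are reported as computed and flagged, never
#' truncated at zero.
#'
#' @param matrices list of [SampleMatrix] objects.
#' @param k design target number of samples per patient used for reporting
#'   context (the mean-of-k ICC itself comes from the mean-squares formula,
#'   which for balanced designs equals the Spearman-Brown step-up of the
#'   single ICC with `k = k0`).
#' @param designN expected number of patients x samples per miRNA
#'   (`n_missing` in the report counts shortfall from this; default `NA`
#'   skips the count).
#' @return Data frame with one row per input matrix: `mirna`, `method`,
#'   `signal`, `n_patients`, `n_values`, `n_missing`, `icc_single`,
#'   `icc_mean`, `flag`.
#' @export
iccReport <- function(matrices, k = 3, designN = NA_integer_) {
  rows <- lapply(matrices, function(m) {
    base <- data.frame(
      mirna = m@mirnaId, method = m@modality, signal = m@signal,
      n_patients = NA_integer_, n_values = NA_integer_,
      n_missing = NA_integer_,
      icc_single = NA_real_, icc_mean = NA_real_, flag = "",
      stringsAsFactors = FALSE)
    d <- tryCatch(onewayAnova(m), error = function(e) e)
    if (inherits(d, "error")) {
      base$flag <- paste0("error: ", conditionMessage(d))
      return(base)
    }
    base$n_patients <- d@nGroups
    base$n_values <- d@totalN
    if (!is.na(designN)) base$n_missing <- as.integer(designN - d@totalN)
    base$icc_single <- iccSingle(d)
    base$icc_mean <- iccMean(d)
    flags <- character()
    if (!is.na(base$icc_single) && base$icc_single < 0) flags <- c(flags, "negative_icc")
    if (any(d@groupSizes != d@groupSizes[1L])) flags <- c(flags, "unbalanced")
    base$flag <- paste(flags, collapse = ";")
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reliability report for a two-modality study
#'
#' Builds the per-miRNA [SampleMatrix] objects from a [QpcrExperiment]
#' (linear values) and an [IshExperiment] (ICC signal fractions, i.e. wpB
#' for the miRNAs in `wpbMirnas` and TBp otherwise) and runs [iccReport()].
#'
#' @param qpcr a [QpcrExperiment] or `NULL`.
#' @param ish an [IshExperiment] or `NULL`.
#' @param k design target samples per patient.
#' @param wpbMirnas passed to [sampleGroups()] for the ISH side.
#' @return The [iccReport()] data frame, qPCR rows first.
#' @export
studyIccReport <- function(qpcr = NULL, ish = NULL, k = 3, wpbMirnas = "miR-125b") {
  mats <- list()
  if (!is.null(qpcr)) {
    designN <- ncol(qpcr)
    for (m in rownames(qpcr)) {
      mats[[paste0("qpcr:", m)]] <- sampleGroups(qpcr, m)
    }
  }
  if (!is.null(ish)) {
    for (m in rownames(ish)) {
      mats[[paste0("ish:", m)]] <- sampleGroups(ish, m, purpose = "icc",
                                                wpbMirnas = wpbMirnas)
    }
  }
  designN <- max(c(if (!is.null(qpcr)) ncol(qpcr), if (!is.null(ish)) ncol(ish)))
  iccReport(mats, k = k, designN = designN)
}

#' Exact-F confidence interval for the single-sample ICC
#'
#' An optional extension: the exact one-way random-effects interval based
#' on the F statistic \eqn{MS_B/MS_W} with \eqn{(g-1, N-g)} degrees of
#' freedom (balanced-theory interval, using `k0` for unbalanced data).
#'
#' @param d a [VarianceComponents] object.
#' @param level confidence level (default 0.95).
#' @return Named numeric vector `lower`, `upper`.
#' @export
iccSingleConfint <- function(d, level = 0.95) {
  stopifnot(is(d, "VarianceComponents"), level > 0, level < 1)
  if (d@msWithin == 0) return(c(lower = NA_real_, upper = NA_real_))
  fobs <- d@msBetween / d@msWithin
  df1 <- d@nGroups - 1L
  df2 <- d@totalN - d@nGroups
  alpha <- 1 - level
  fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
  fu <- fobs / stats::qf(alpha / 2, df1, df2)
  c(lower = (fl - 1) / (fl + d@k0 - 1), upper = (fu - 1) / (fu + d@k0 - 1))
}
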