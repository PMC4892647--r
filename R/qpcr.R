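#' Aggregate a qPCR triplicate into a mean Cq
#'
#' Averages the detected replicate Cq values of one well triplicate after a
#' conservative outlier screen: with two or more detected replicates, a
#' replicate whose absolute deviation from the median of the detected
#' values exceeds `outlierThreshold` is dropped (at most one per
#' triplicate, the worst offender; a tie in the maximal deviation is left
#' alone since the outlier cannot be identified). A single detected
#' replicate is returned as is; an all-undetected triplicate yields `NA`.
#'
#' @param cqs numeric vector of up to 3 replicate Cq values; `NA` marks an
#'   undetected replicate.
#' @param outlierThreshold maximal tolerated deviation from the triplicate
#'   median, in cycles (default 0.5).
#' @return The mean Cq of the retained replicates, or `NA_real_` if all
#'   replicates were undetected. The number of dropped replicates is
#'   attached as attribute `"nOutliers"`.
#' @examples
#' aggregateTriplicate(c(20.0, 20.1, 20.2))          # 20.1
#' aggregateTriplicate(c(20.0, 20.1, 25.0))          # 20.05, one outlier
#' aggregateTriplicate(c(NA, NA, NA))                # NA (undetected)
#' @export
aggregateTriplicate <- function(cqs, outlierThreshold = 0.5) {
  stopifnot(length(cqs) >= 1L, length(cqs) <= 3L,
            is.numeric(outlierThreshold), outlierThreshold > 0)
  detected <- cqs[!is.na(cqs)]
  if (length(detected) == 0L) {
    return(structure(NA_real_, nOutliers = 0L))
  }
  if (any(!is.finite(detected)) || any(detected <= 0)) {
    stop("detected Cq values must be finite and positive")
  }
  nOut <- 0L
  if (length(detected) >= 2L) {
    dev <- abs(detected - stats::median(detected))
    worst <- which(dev == max(dev))
    if (max(dev) > outlierThreshold && length(worst) == 1L) {
      detected <- detected[-worst]
      nOut <- 1L
    }
  }
  structure(mean(detected), nOutliers = nOut)
}

#' Delta-Cq normalisation against reference miRNAs
#'
#' Subtracts the arithmetic mean of the reference-miRNA mean Cq values
#' from the target mean Cq.
#'
#' @param targetCq mean Cq of the target miRNA (cycles).
#' @param normaliserCqs numeric vector of the three reference-miRNA mean
#'   Cq values for the same patient x sample.
#' @return The delta-Cq value (cycles).
#' @examples
#' normaliseDeltaCq(22.5, c(20, 20, 20))  # 2.5
#' @export
normaliseDeltaCq <- function(targetCq, normaliserCqs) {
  if (!is.finite(targetCq)) stop("targetCq must be finite")
  if (length(normaliserCqs) != 3L || any(!is.finite(normaliserCqs)))
    stop("exactly three finite normaliser Cq values are required")
  targetCq - mean(normaliserCqs)
}

#' Linearise a delta-Cq value
#'
#' Converts a delta-Cq to the relative linear expression \eqn{2^{-\Delta Cq}},
#' assuming 100\% amplification efficiency (doubling per cycle).
#'
#' @param deltaCq delta-Cq value(s), cycles; vectorised.
#' @return Positive linear expression value(s).
#' @examples
#' linearise(c(0, 1, -1))  # 1, 0.5, 2
#' @export
linearise <- function(deltaCq) {
  if (any(!is.finite(deltaCq))) stop("deltaCq must be finite")
  2^(-deltaCq)
}

#' Build the normalised expression table from raw triplicates
#'
#' Runs the full relative-quantification chain on a triplicate table:
#' replicate aggregation (with the outlier screen), arithmetic-mean
#' normalisation against the reference miRNAs, and linearisation. Target
#' measurements that are undetected, or whose sample lacks a detected value
#' for any reference miRNA, yield no output row; every omission and every
#' removed replicate is recorded in the attached log.
#'
#' @param triplicates data frame with columns `patient_id`, `sample_id`,
#'   `mirna_id`, `rep1_cq`, `rep2_cq`, `rep3_cq` (NA = undetected) and
#'   optionally `deepest_flag`; one row per patient x sample x miRNA.
#' @param outlierThreshold passed to [aggregateTriplicate()].
#' @param normaliserIds identifiers of the three reference miRNAs.
#' @return Data frame with columns `patient_id`, `sample_id`,
#'   `deepest_flag`, `mirna_id`, `mean_cq`, `delta_cq`, `linear_value`,
#'   one row per detected target measurement. The exclusion/outlier log
#'   (columns `patient_id`, `sample_id`, `mirna_id`, `reason`) is attached
#'   as attribute `"log"` and retrievable with [expressionLog()].
#' @export
buildExpressionTable <- function(triplicates, outlierThreshold = 0.5,
                                 normaliserIds = c("miR-193a-5p", "miR-27a", "let-7g")) {
  need <- c("patient_id", "sample_id", "mirna_id", "rep1_cq", "rep2_cq", "rep3_cq")
  miss <- setdiff(need, names(triplicates))
  if (length(miss))
    stop("triplicate table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"deepest_flag" %in% names(triplicates)) triplicates$deepest_flag <- FALSE
  key <- paste(triplicates$patient_id, triplicates$sample_id, triplicates$mirna_id,
               sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (patient, sample, miRNA) keys in triplicate table")

  reps <- as.matrix(triplicates[, c("rep1_cq", "rep2_cq", "rep3_cq")])
  agg <- lapply(seq_len(nrow(reps)), function(i)
    aggregateTriplicate(reps[i, ], outlierThreshold))
  meanCq <- vapply(agg, as.numeric, 0)
  nOut <- vapply(agg, attr, 0L, "nOutliers")

  tab <- data.frame(
    patient_id = as.character(triplicates$patient_id),
    sample_id = as.character(triplicates$sample_id),
    deepest_flag = as.logical(triplicates$deepest_flag),
    mirna_id = as.character(triplicates$mirna_id),
    mean_cq = meanCq,
    stringsAsFactors = FALSE
  )

  logRows <- list()
  if (any(nOut > 0L)) {
    i <- which(nOut > 0L)
    logRows[[length(logRows) + 1L]] <- data.frame(
      patient_id = tab$patient_id[i], sample_id = tab$sample_id[i],
      mirna_id = tab$mirna_id[i], reason = "replicate_outlier",
      stringsAsFactors = FALSE)
  }

  isNorm <- tab$mirna_id %in% normaliserIds
  normTab <- tab[isNorm, ]
  sampleKey <- function(d) paste(d$patient_id, d$sample_id, sep = "\r")
  normMean <- tapply(normTab$mean_cq, sampleKey(normTab), function(v) {
    if (length(v) < 3L || anyNA(v)) NA_real_ else mean(v)
  })

  targets <- tab[!isNorm, ]
  nm <- as.numeric(normMean[sampleKey(targets)])
  undet <- is.na(targets$mean_cq)
  nonNorm <- !undet & is.na(nm)
  if (any(undet)) {
    i <- which(undet)
    logRows[[length(logRows) + 1L]] <- data.frame(
      patient_id = targets$patient_id[i], sample_id = targets$sample_id[i],
      mirna_id = targets$mirna_id[i], reason = "undetected",
      stringsAsFactors = FALSE)
  }
  if (any(nonNorm)) {
    i <- which(nonNorm)
    logRows[[length(logRows) + 1L]] <- data.frame(
      patient_id = targets$patient_id[i], sample_id = targets$sample_id[i],
      mirna_id = targets$mirna_id[i], reason = "non_normalisable",
      stringsAsFactors = FALSE)
  }

  keep <- !undet & !nonNorm
  out <- targets[keep, , drop = FALSE]
  out$delta_cq <- out$mean_cq - nm[keep]
  out$linear_value <- 2^(-out$delta_cq)
  rownames(out) <- NULL

  log <- if (length(logRows)) do.call(rbind, logRows) else
    data.frame(patient_id = character(), sample_id = character(),
               mirna_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  log <- log[order(log$patient_id, log$sample_id, log$mirna_id, log$reason), ,
             drop = FALSE]
  rownames(log) <- NULL
  attr(out, "log") <- log
  out
}

#' @describeIn buildExpressionTable retrieve the exclusion/outlier log of an
#'   expression table.
#' @param x an expression table returned by `buildExpressionTable()`.
#' @export
expressionLog <- function(x) {
  attr(x, "log")
}
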