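#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (the Pearson correlation
#' of the rank-transformed data), via [stats::cor()].
#'
#' @param x,y numeric vectors of equal length `n >= 3`, all finite.
#' @return The correlation in \[-1, 1\], or `NA_real_` when either vector
#'   has zero rank variance (constant input — the coefficient is
#'   undefined).
#' @examples
#' spearmanRho(1:4, c(10, 20, 30, 40))  # 1
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) return(NA_real_)
  unname(stats::cor(x, y, method = "spearman"))
}

#' Pair qPCR and ISH values per patient
#'
#' Builds the paired series entering the cross-modality concordance
#' analysis for one miRNA. `"patient_mean"` averages the available
#' per-sample values within each patient and modality;
#' `"deepest_section"` pairs the values of the sample flagged as
#' containing the deepest part of the tumour (pairing within `sample_id`).
#' The ISH side always uses the total blue fraction `TBp`. Patients
#' missing either modality (or, in deepest mode, the flagged sample) are
#' dropped and counted in the attached `"dropped"` attribute.
#'
#' @param qpcrTable expression table ([buildExpressionTable()]).
#' @param ishRecords ISH records with `deepest_flag`; excluded rows are
#'   ignored.
#' @param mirna miRNA identifier present in both modalities.
#' @param mode `"patient_mean"` or `"deepest_section"`.
#' @return Data frame with columns `patient_id`, `qpcr`, `ish`; attribute
#'   `"dropped"` gives the number of patients lost to incomplete pairs.
#' @export
aggregatePairs <- function(qpcrTable, ishRecords, mirna,
                           mode = c("patient_mean", "deepest_section")) {
  mode <- match.arg(mode)
  q <- qpcrTable[qpcrTable$mirna_id == mirna, , drop = FALSE]
  s <- ishRecords[ishRecords$mirna_id == mirna & !ishRecords$excluded, , drop = FALSE]
  if (mode == "deepest_section") {
    if (!"deepest_flag" %in% names(q) || !"deepest_flag" %in% names(s))
      stop("deepest_flag column required for deepest_section mode")
    q <- q[q$deepest_flag, , drop = FALSE]
    s <- s[s$deepest_flag, , drop = FALSE]
    qv <- stats::setNames(q$linear_value, q$patient_id)
    sv <- stats::setNames(s$fraction_TBp, s$patient_id)
  } else {
    qv <- tapply(q$linear_value, q$patient_id, mean)
    sv <- tapply(s$fraction_TBp, s$patient_id, mean)
  }
  patients <- union(names(qv), names(sv))
  common <- intersect(names(qv), names(sv))
  common <- sort(common)
  out <- data.frame(patient_id = common,
                    qpcr = as.numeric(qv[common]),
                    ish = as.numeric(sv[common]),
                    stringsAsFactors = FALSE)
  dropped <- length(patients) - length(common)
  if (dropped > 0)
    warning(sprintf("%s (%s): dropped %d patient(s) with incomplete pairs",
                    mirna, mode, dropped))
  attr(out, "dropped") <- dropped
  out
}

#' Cross-modality concordance report
#'
#' Spearman correlation between qPCR linear values and ISH TBp fractions
#' per miRNA, both for per-patient means and for the deepest section.
#'
#' @inheritParams aggregatePairs
#' @param mirnas miRNAs to report; defaults to those present in both
#'   modalities.
#' @return Data frame with columns `mirna`, `rho_mean`, `n_mean`,
#'   `rho_deepest`, `n_deepest`.
#' @export
concordanceReport <- function(qpcrTable, ishRecords, mirnas = NULL) {
  if (is.null(mirnas)) {
    mirnas <- intersect(unique(qpcrTable$mirna_id),
                        unique(ishRecords$mirna_id[!ishRecords$excluded]))
    mirnas <- sort(mirnas)
  }
  rows <- lapply(mirnas, function(m) {
    pm <- suppressWarnings(aggregatePairs(qpcrTable, ishRecords, m, "patient_mean"))
    dp <- suppressWarnings(aggregatePairs(qpcrTable, ishRecords, m, "deepest_section"))
    data.frame(
      mirna = m,
      rho_mean = if (nrow(pm) >= 3L) spearmanRho(pm$qpcr, pm$ish) else NA_real_,
      n_mean = nrow(pm),
      rho_deepest = if (nrow(dp) >= 3L) spearmanRho(dp$qpcr, dp$ish) else NA_real_,
      n_deepest = nrow(dp),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standardise values to a common scale
#'
#' Centres and scales by the sample standard deviation (n - 1), so the
#' output has mean 0 and SD 1.
#'
#' @param x numeric vector with at least 2 values and nonzero spread.
#' @return The standardised values.
#' @export
commonScaleNormalise <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values")
  if (any(!is.finite(x))) stop("values must be finite")
  s <- stats::sd(x)
  if (s == 0) stop("zero spread: standardisation undefined")
  (x - mean(x)) / s
}

#' Standardise a two-modality measurement table for joint plotting
#'
#' Applies [commonScaleNormalise()] within each miRNA x modality stratum
#' (all samples of all patients together), the common-scale transformation
#' behind the joint range plot: each stratum ends up with mean 0 and SD 1
#' so both modalities share one axis.
#'
#' @param tab data frame with columns `mirna_id`, `modality`,
#'   `patient_id`, `sample_id`, `value`.
#' @return The input with an added `z` column.
#' @export
standardiseCommonScale <- function(tab) {
  need <- c("mirna_id", "modality", "patient_id", "sample_id", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("table is missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(tab$mirna_id, tab$modality, sep = "\r")
  tab$z <- stats::ave(tab$value, key, FUN = commonScaleNormalise)
  tab
}

#' Range plot of per-patient variation on the common scale
#'
#' Renders the joint heterogeneity plot: for each miRNA, one vertical line
#' per patient spanning the range of that patient's standardised
#' measurements, coloured by modality, with patients ordered by their mean
#' standardised qPCR value.
#'
#' @param standardised output of [standardiseCommonScale()].
#' @return A ggplot object.
#' @export
plotCommonScale <- function(standardised) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  agg <- stats::aggregate(z ~ mirna_id + modality + patient_id, standardised,
                          function(v) c(lo = min(v), hi = max(v), mid = mean(v)))
  agg <- cbind(agg[c("mirna_id", "modality", "patient_id")],
               as.data.frame(agg$z))
  ord <- agg[agg$modality == "qpcr", ]
  lev <- ord$patient_id[order(ord$mirna_id, ord$mid)]
  agg$patient <- factor(agg$patient_id, levels = unique(lev))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$patient, ymin = .data$lo,
                                    ymax = .data$hi, colour = .data$modality)) +
    ggplot2::geom_linerange(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~mirna_id, scales = "free_x") +
    ggplot2::labs(x = "patient (ordered by mean qPCR z)",
                  y = "standardised expression (z)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
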