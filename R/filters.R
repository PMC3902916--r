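#' Overall expression level of one gene
#'
#' The median of all finite sample-channel intensities for the gene, across
#' every array and time point; used as an ordinal screen of expression.
#'
#' @param sample_signals Numeric vector of sample-channel intensities.
#' @return The median of the finite values.
#' @export
overall_expression_level <- function(sample_signals) {
  v <- sample_signals[is.finite(sample_signals)]
  if (!length(v)) stop("overall_expression_level: no finite values")
  median(v)
}

#' Quartile categories of overall expression levels
#'
#' Splits genes into categories I-IV at the first, second and third quartiles
#' of the overall-level distribution (linear-interpolation quantiles):
#' I below Q1, II in \[Q1, Q2), III in \[Q2, Q3), IV at or above Q3.
#'
#' @param levels Named numeric vector of per-gene overall levels.
#' @return List with `thresholds` (Q1, Q2, Q3) and `category` (factor
#'   I/II/III/IV per gene).
#' @export
quartile_categories <- function(levels) {
  stopifnot(length(levels) >= 4)
  qs <- quantile(levels, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  # boundary rule: I < Q1 <= II < Q2 <= III < Q3 <= IV (ties go upward, so a
  # degenerate all-equal distribution lands in IV)
  category <- rep("IV", length(levels))
  category[levels < qs[3]] <- "III"
  category[levels < qs[2]] <- "II"
  category[levels < qs[1]] <- "I"
  category <- factor(category, levels = c("I", "II", "III", "IV"))
  list(thresholds = setNames(qs, c("Q1", "Q2", "Q3")),
       category = setNames(category, names(levels)))
}

#' Summarize and select highly expressed genes
#'
#' A gene is highly expressed when its overall sample-channel level is at or
#' above the first quartile (categories II-IV). A category-I gene is rescued
#' when its profile carries a significant peak, operationalized as a maximum
#' per-time-point sample-channel value at or above the global median (Q2) of
#' overall levels.
#'
#' @param signal_by_time Numeric matrix of per-time-point sample-channel
#'   values (genes x time points); per-gene maxima define the peak. Row
#'   order must match `signals_all`.
#' @param signals_all Numeric matrix (genes x arrays) of all sample-channel
#'   intensities, used for the overall level.
#' @param peak_quantile Quantile of overall levels a peak must reach to
#'   rescue a category-I gene; default 0.5 (the global median).
#' @return Data frame with `gene_id`, `overall_level`, `category`,
#'   `highly_expressed`, `rescued_by_peak`, plus the quartile thresholds as
#'   attribute `"thresholds"`.
#' @export
select_highly_expressed <- function(signal_by_time, signals_all,
                                    peak_quantile = 0.5) {
  stopifnot(nrow(signal_by_time) == nrow(signals_all))
  levels <- apply(signals_all, 1, overall_expression_level)
  qc <- quartile_categories(levels)
  peak <- apply(signal_by_time, 1, function(v)
    if (any(is.finite(v))) max(v[is.finite(v)]) else -Inf)
  peak_thr <- quantile(levels, peak_quantile, names = FALSE, type = 7)
  is_I <- qc$category == "I"
  rescued <- is_I & peak >= peak_thr
  out <- data.frame(gene_id = rownames(signals_all) %||% seq_along(levels),
                    overall_level = unname(levels),
                    category = unname(qc$category),
                    highly_expressed = unname(!is_I | rescued),
                    rescued_by_peak = unname(rescued),
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- qc$thresholds
  out
}

#' Select genes with low replicate variance
#'
#' Keeps a gene when its per-time-point replicate coefficient of variation
#' is below `cv_max` at no fewer than `min_points` time points. Time points
#' where the CV is undefined (fewer than 2 replicates) do not count toward
#' the quota.
#'
#' @param profiles A `profile_set` with a `cv` matrix.
#' @param cv_max CV threshold (strict); default 0.47.
#' @param min_points Minimum number of qualifying time points; default 8.
#' @return Character vector of retained gene ids.
#' @export
select_low_cv <- function(profiles, cv_max = 0.47, min_points = 8) {
  cv <- profiles$cv
  if (is.null(cv)) stop("select_low_cv: profile set has no cv matrix")
  n_ok <- rowSums(cv < cv_max, na.rm = TRUE)
  rownames(cv)[n_ok >= min_points]
}
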