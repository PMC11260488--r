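#' qPCR relative fold change by the 2^-ddCt method
#'
#' ddCt = (Ct_target,test - Ct_control,test) - (Ct_target,ref -
#' Ct_control,ref); the relative expression fold change is 2^(-ddCt). The
#' control gene is the endogenous normalizer (e.g. UBC6).
#'
#' @param ct_target_test,ct_control_test Ct values in the test condition.
#' @param ct_target_ref,ct_control_ref Ct values in the reference
#'   condition.
#' @return Fold change (dimensionless).
#' @export
ddct_fold_change <- function(ct_target_test, ct_control_test,
                             ct_target_ref, ct_control_ref) {
  cts <- c(ct_target_test, ct_control_test, ct_target_ref, ct_control_ref)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_test - ct_control_test) -
    (ct_target_ref - ct_control_ref)
  2^(-ddct)
}

#' Maximal growth rate from a growth curve
#'
#' Ordinary least-squares slope of OD on time in every contiguous window of
#' `window` points; returns the maximum slope (OD/min for time in minutes)
#' and its window. Ties go to the earliest window.
#'
#' @param curve Data.frame with `time` and `od` columns (times strictly
#'   increasing).
#' @param window Points per window (default 20).
#' @return List: `rate` (max slope), `window_start` (index), `t_start`,
#'   `t_end`.
#' @export
max_growth_rate <- function(curve, window = 20) {
  stopifnot(all(c("time", "od") %in% names(curve)))
  t <- curve$time; y <- curve$od
  n <- length(t)
  if (any(diff(t) <= 0)) stop("time vector must be strictly increasing")
  if (n < window) stop("need at least ", window, " time points")
  n_win <- n - window + 1
  slopes <- numeric(n_win)
  for (i in seq_len(n_win)) {
    idx <- i:(i + window - 1)
    tt <- t[idx] - mean(t[idx])
    slopes[i] <- sum(tt * (y[idx] - mean(y[idx]))) / sum(tt^2)
  }
  best <- which.max(slopes)  # which.max takes the earliest tie
  list(rate = slopes[best], window_start = best,
       t_start = t[best], t_end = t[best + window - 1])
}

#' Polysome-to-monosome (P/M) ratio from an A254 trace
#'
#' Trapezoidal integration of baseline-subtracted absorbance over each
#' labelled segment; the baseline is the minimum absorbance within the full
#' span of the supplied boundaries. The ratio is the combined polysome peak
#' area over the 80S (monosome) peak area; 40S/60S segments, if supplied,
#' do not enter the denominator.
#'
#' @param trace Data.frame with `position` and `a254` columns.
#' @param boundaries Data.frame with `label` (one of "40S", "60S", "80S",
#'   "polysome"), `start`, `end`; at least one polysome segment and one 80S
#'   segment are required.
#' @return List: `ratio`, `polysome_area`, `monosome_area`, `baseline`.
#' @export
pm_ratio <- function(trace, boundaries) {
  stopifnot(all(c("position", "a254") %in% names(trace)),
            all(c("label", "start", "end") %in% names(boundaries)))
  if (!any(boundaries$label == "polysome"))
    stop("no polysome segment in boundaries")
  if (!any(boundaries$label == "80S"))
    stop("no 80S segment in boundaries")
  span <- c(min(boundaries$start), max(boundaries$end))
  in_span <- trace$position >= span[1] & trace$position <= span[2]
  if (!any(in_span)) stop("boundaries outside trace range")
  baseline <- min(trace$a254[in_span])
  seg_area <- function(start, end) {
    sel <- trace$position >= start & trace$position <= end
    if (sum(sel) < 2) return(0)
    pracma::trapz(trace$position[sel], trace$a254[sel] - baseline)
  }
  poly <- boundaries[boundaries$label == "polysome", , drop = FALSE]
  mono <- boundaries[boundaries$label == "80S", , drop = FALSE]
  pa <- sum(mapply(seg_area, poly$start, poly$end))
  ma <- sum(mapply(seg_area, mono$start, mono$end))
  if (ma <= 0) stop("80S area <= 0 after baseline subtraction")
  list(ratio = pa / ma, polysome_area = pa, monosome_area = ma,
       baseline = baseline)
}

#' Marker-normalized competition fitness
#'
#' In a competition assay the mutant-to-reference strain ratio is
#' normalized, time point by time point, to the ancestral-to-reference
#' ratio measured in the same condition, cancelling the fitness effect of
#' the marker gene: normalized(t) = experimental(t) / control(t).
#'
#' @param experimental_ratios Numeric series of mutant/reference ratios.
#' @param control_ratios Matched series of ancestral/reference ratios.
#' @return Numeric series of normalized ratios; a missing control point
#'   yields `NA` at that position, with the count in attribute
#'   `n_missing`.
#' @export
competition_fitness <- function(experimental_ratios, control_ratios) {
  if (length(experimental_ratios) != length(control_ratios))
    stop("experimental and control series must share time points")
  if (any(control_ratios == 0, na.rm = TRUE))
    stop("control ratio of 0: normalization undefined")
  out <- experimental_ratios / control_ratios
  attr(out, "n_missing") <- sum(is.na(control_ratios))
  out
}
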