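#' Systolic/diastolic pressure extraction
#'
#' Per-segment SBP is the maximum and DBP the minimum of the ABP waveform,
#' in mmHg.
#'
#' @param abp Non-empty ABP signal in mmHg.
#' @return A scalar pressure in mmHg.
#' @export
extract_sbp <- function(abp) {
  if (!length(abp)) stop("empty ABP signal", call. = FALSE)
  max(abp)
}

#' @rdname extract_sbp
#' @export
extract_dbp <- function(abp) {
  if (!length(abp)) stop("empty ABP signal", call. = FALSE)
  min(abp)
}

#' Pearson product-moment correlation
#'
#' Standard product-moment correlation between two equal-length series, used
#' both for the morphology-similarity quality rule and for the SBP/DBP
#' prediction analysis.  Constant input makes the correlation undefined; in
#' that case `NA` is returned (with a warning) and quality control treats it
#' as a low-correlation failure.
#'
#' @param a,p Equal-length numeric vectors of length at least 3.
#' @return Correlation in `[-1, 1]`, or `NA` if either input is constant.
#' @export
pearson_r <- function(a, p) {
  if (length(a) != length(p)) stop("inputs must have equal lengths",
                                   call. = FALSE)
  if (length(a) < 3) stop("need at least 3 samples", call. = FALSE)
  if (sd(a) == 0 || sd(p) == 0) {
    warning("constant input: correlation undefined")
    return(NA_real_)
  }
  as.numeric(cor(a, p))
}

#' Detect PPG systolic peaks with an adaptive rolling-mean threshold
#'
#' Candidate peaks are the maxima of regions where the signal exceeds a
#' 0.75 s rolling mean raised by a percentage of the signal amplitude.
#' Detections implying an instantaneous rate above 180 bpm are rejected
#' (this also discards dicrotic-lobe detections, which trail the systolic
#' peak by less than the minimum beat interval).  Several threshold levels
#' are tried and the one whose surviving peaks have the most regular rhythm
#' (smallest robust interval dispersion) with a median rate inside
#' 40–180 bpm wins; if no level yields a plausible rhythm the signal has no
#' usable peaks and an empty vector is returned.
#'
#' @param ppg Filtered PPG signal.
#' @param fs Sampling rate in Hz.
#' @return Integer vector of peak sample indices (possibly empty).
#' @export
detect_systolic_peaks <- function(ppg, fs = 125) {
  n <- length(ppg)
  if (n < fs || sd(ppg) == 0) return(integer(0))
  w <- round(0.75 * fs)
  if (w %% 2 == 0) w <- w + 1
  hw <- (w - 1) / 2
  padded <- c(rep(ppg[1], hw), ppg, rep(ppg[n], hw))
  sm <- as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))
  sm <- sm[(hw + 1):(hw + n)]
  amp <- max(ppg) - min(ppg)
  min_int <- 60 / 180 * fs   # shortest plausible beat interval
  max_int <- 60 / 40 * fs

  best <- NULL
  best_score <- Inf
  for (perc in c(0.02, 0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.40, 0.50)) {
    above <- ppg > sm + perc * amp
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    cand <- vapply(runs, function(k) {
      i <- starts[k]:ends[k]
      i[which.max(ppg[i])]
    }, 0L)
    cand <- cand[cand > hw / 4 & cand <= n - hw / 4]  # trim edge artefacts
    if (length(cand) < 2) next
    # rhythm regularity judged on the raw detections: spurious maxima (noise,
    # dicrotic lobes) make the raw intervals irregular at this threshold
    raw_ints <- diff(cand)
    med <- median(raw_ints)
    if (med < min_int || med > max_int) next
    score <- stats::mad(raw_ints, constant = 1) / med
    if (score > 0.25 || score >= best_score) next
    # instantaneous-rate rejection: drop detections arriving too soon
    accepted <- cand[1]
    for (p in cand[-1]) if (p - accepted[length(accepted)] >= min_int)
      accepted <- c(accepted, p)
    if (length(accepted) < 2) next
    best <- accepted
    best_score <- score
  }
  if (is.null(best)) return(integer(0))
  # periodicity check: the detected rhythm must be visible in the signal's
  # autocorrelation at the median beat interval (noise-only signals fail)
  m <- round(median(diff(best)))
  if (m < n - 3) {
    r_per <- suppressWarnings(cor(ppg[1:(n - m)], ppg[(1 + m):n]))
    if (!is.finite(r_per) || r_per < 0.25) return(integer(0))
  }
  as.integer(best)
}

#' Default quality-control thresholds
#'
#' Segments are retained only when 80 <= SBP <= 180 mmHg,
#' 60 <= DBP <= 130 mmHg, the PPG/ABP morphology correlation is at least
#' 0.8, and at least one systolic peak is detectable.  The pressure bounds
#' are strict on the outside: exactly 180 or exactly 60 still pass.
#'
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function() {
  list(sbp_min = 80, sbp_max = 180, dbp_min = 60, dbp_max = 130,
       r_min = 0.8)
}

#' Apply the four elimination rules to an aligned segment
#'
#' All four rules are always evaluated and reported; degenerate signals
#' produce failure reasons, never errors.  SBP/DBP are computed over the raw
#' (unnormalized) ABP in mmHg; the correlation is computed on the aligned
#' pair (correlation is scale-invariant, so raw channels are used).
#'
#' @param ppg Aligned, filtered PPG.
#' @param abp Aligned raw ABP in mmHg.
#' @param segment_id Identifier echoed in the report.
#' @param fs Sampling rate in Hz.
#' @param thresholds See [qc_thresholds()].
#' @return A `qc_report`: list with `segment_id`, `sbp_mmHg`, `dbp_mmHg`,
#'   `pearson_r`, `peaks_found`, `passed`, `failure_reasons` (subset of
#'   `sbp_range`, `dbp_range`, `low_correlation`, `no_peak`).
#' @export
qc_filter <- function(ppg, abp, segment_id = "segment", fs = 125,
                      thresholds = qc_thresholds()) {
  sbp <- extract_sbp(abp)
  dbp <- extract_dbp(abp)
  r <- suppressWarnings(
    if (length(ppg) >= 3 && sd(ppg) > 0 && sd(abp) > 0)
      pearson_r(abp, ppg) else NA_real_)
  peaks <- detect_systolic_peaks(ppg, fs)
  reasons <- character()
  if (sbp > thresholds$sbp_max || sbp < thresholds$sbp_min)
    reasons <- c(reasons, "sbp_range")
  if (dbp > thresholds$dbp_max || dbp < thresholds$dbp_min)
    reasons <- c(reasons, "dbp_range")
  if (is.na(r) || r < thresholds$r_min)
    reasons <- c(reasons, "low_correlation")
  if (!length(peaks))
    reasons <- c(reasons, "no_peak")
  structure(list(segment_id = segment_id, sbp_mmHg = sbp, dbp_mmHg = dbp,
                 pearson_r = r, peaks_found = length(peaks), peaks = peaks,
                 passed = !length(reasons), failure_reasons = reasons),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report %s> SBP %.1f DBP %.1f r %.3f peaks %d -> %s%s\n",
              x$segment_id, x$sbp_mmHg, x$dbp_mmHg, x$pearson_r,
              x$peaks_found, if (x$passed) "PASS" else "FAIL",
              if (x$passed) "" else paste0(" [",
                paste(x$failure_reasons, collapse = ", "), "]")))
  invisible(x)
}

#' Tabulate quality-control reports
#'
#' @param reports List of `qc_report`s.
#' @return Data frame with one row per segment (failure reasons collapsed
#'   with `;`).
#' @export
qc_table <- function(reports) {
  do.call(rbind, lapply(reports, function(x)
    data.frame(segment_id = x$segment_id, sbp_mmHg = x$sbp_mmHg,
               dbp_mmHg = x$dbp_mmHg, pearson_r = x$pearson_r,
               peaks_found = x$peaks_found, passed = x$passed,
               failure_reasons = paste(x$failure_reasons, collapse = ";"),
               stringsAsFactors = FALSE)))
}
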