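#' Error metrics for blood-pressure prediction
#'
#' `mae()` is the mean absolute error and `rmse()` the root mean square
#' error over per-segment signed errors (predicted minus observed, mmHg).
#'
#' @param errors Non-empty numeric vector of signed errors in mmHg.
#' @return A scalar in mmHg.
#' @export
mae <- function(errors) {
  if (!length(errors)) stop("empty error set", call. = FALSE)
  mean(abs(errors))
}

#' @rdname mae
#' @export
rmse <- function(errors) {
  if (!length(errors)) stop("empty error set", call. = FALSE)
  sqrt(mean(errors^2))
}

BHS_GRADES <- list(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))

#' Grade cumulative error percentages on the BHS scale
#'
#' A device earns the best grade whose thresholds it meets at all three
#' levels: at least 60/85/95% of absolute errors within 5/10/15 mmHg for
#' grade A, 50/75/90 for B, 40/65/85 for C; anything less fails.
#' Comparisons on the percentages are inclusive (meeting a threshold exactly
#' earns the grade).
#'
#' @param pct_le_5,pct_le_10,pct_le_15 Cumulative percentages of absolute
#'   errors at or below 5, 10 and 15 mmHg.
#' @return `"A"`, `"B"`, `"C"` or `"fail"`.
#' @export
bhs_grade_from_pct <- function(pct_le_5, pct_le_10, pct_le_15) {
  p <- c(pct_le_5, pct_le_10, pct_le_15)
  for (g in names(BHS_GRADES)) if (all(p >= BHS_GRADES[[g]])) return(g)
  "fail"
}

#' BHS cumulative-error grading of an error set
#'
#' Computes the percentages of absolute errors within 5, 10 and 15 mmHg
#' (inclusive: an error of exactly 5 mmHg counts as within 5) and grades
#' them with [bhs_grade_from_pct()].
#'
#' @param errors Non-empty numeric vector of errors in mmHg (signs are
#'   ignored).
#' @return A `bhs_result`: list with `pct_le_5`, `pct_le_10`, `pct_le_15`
#'   and `grade`.
#' @export
bhs_grade <- function(errors) {
  if (!length(errors)) stop("empty error set", call. = FALSE)
  a <- abs(errors)
  p <- vapply(c(5, 10, 15), function(thr) 100 * mean(a <= thr), 0.0)
  structure(list(pct_le_5 = p[1], pct_le_10 = p[2], pct_le_15 = p[3],
                 grade = bhs_grade_from_pct(p[1], p[2], p[3])),
            class = "bhs_result")
}

#' @export
print.bhs_result <- function(x, ...) {
  cat(sprintf("<bhs_result> %.1f%% / %.1f%% / %.1f%% within 5/10/15 mmHg -> grade %s\n",
              x$pct_le_5, x$pct_le_10, x$pct_le_15, x$grade))
  invisible(x)
}

#' AAMI criterion check
#'
#' The device standard as applied here: mean absolute error below 5 mmHg,
#' standard deviation of the errors below 8 mmHg, evaluated on more than 85
#' subjects.  All three comparisons are strict.  The standard deviation uses
#' the population (divide-by-n) formula.
#'
#' @param errors Non-empty signed errors in mmHg.
#' @param n_subjects Number of distinct subjects behind the errors.
#' @return An `aami_result`: list with `mae`, `std`, `n_subjects`, `pass`.
#' @export
aami_check <- function(errors, n_subjects) {
  if (!length(errors)) stop("empty error set", call. = FALSE)
  m <- mae(errors)
  s <- sqrt(mean((errors - mean(errors))^2))
  structure(list(mae = m, std = s, n_subjects = as.integer(n_subjects),
                 pass = (m < 5) && (s < 8) && (n_subjects > 85)),
            class = "aami_result")
}

#' @export
print.aami_result <- function(x, ...) {
  cat(sprintf("<aami_result> MAE %.2f, STD %.2f mmHg over %d subjects -> %s\n",
              x$mae, x$std, x$n_subjects, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Correlation between predicted and observed SBP/DBP
#'
#' @param pred_sbp,obs_sbp,pred_dbp,obs_dbp Equal-length vectors (mmHg).
#' @return List with `r_sbp` and `r_dbp`.
#' @export
bp_correlation <- function(pred_sbp, obs_sbp, pred_dbp, obs_dbp) {
  list(r_sbp = pearson_r(obs_sbp, pred_sbp),
       r_dbp = pearson_r(obs_dbp, pred_dbp))
}

#' Evaluate predicted against observed ABP waveforms
#'
#' Extracts per-segment SBP (max) and DBP (min) from both waveform sets,
#' forms signed errors (predicted minus observed), and assembles the full
#' evaluation: MAE, RMSE, error standard deviation, BHS grading, the AAMI
#' verdict, predicted-vs-observed correlations, and an absolute-error
#' histogram summary.
#'
#' @param predicted,observed Lists of ABP waveforms in mmHg, matched by
#'   `ids`.
#' @param ids Segment identifiers (must match pairwise; a mismatch is an
#'   error).
#' @param subject_ids Subject identifier per segment (used for the AAMI
#'   subject count).
#' @return An `evaluation_report`.
#' @export
evaluate_run <- function(predicted, observed,
                         ids = names(predicted),
                         subject_ids = NULL) {
  if (length(predicted) != length(observed))
    stop("predicted and observed segment counts differ", call. = FALSE)
  if (!is.null(ids) && !is.null(names(observed)) &&
      !identical(as.character(ids), names(observed)))
    stop("segment id mismatch between predicted and observed sets",
         call. = FALSE)
  if (is.null(subject_ids)) subject_ids <- seq_along(predicted)
  n_subjects <- length(unique(subject_ids))

  pred_sbp <- vapply(predicted, extract_sbp, 0.0)
  pred_dbp <- vapply(predicted, extract_dbp, 0.0)
  obs_sbp <- vapply(observed, extract_sbp, 0.0)
  obs_dbp <- vapply(observed, extract_dbp, 0.0)
  e_sbp <- pred_sbp - obs_sbp
  e_dbp <- pred_dbp - obs_dbp

  per_bp <- function(e) {
    list(mae = mae(e), rmse = rmse(e),
         std = sqrt(mean((e - mean(e))^2)),
         bhs = bhs_grade(e), aami = aami_check(e, n_subjects),
         abs_error_hist = hist(abs(e), breaks = seq(0, max(abs(e), 15) + 5,
                                                    by = 5), plot = FALSE))
  }
  errors <- data.frame(segment_id = if (is.null(ids)) seq_along(e_sbp)
                       else as.character(ids),
                       subject_id = subject_ids,
                       obs_sbp = obs_sbp, pred_sbp = pred_sbp,
                       e_sbp = e_sbp, obs_dbp = obs_dbp,
                       pred_dbp = pred_dbp, e_dbp = e_dbp,
                       stringsAsFactors = FALSE)
  structure(list(errors = errors, n_subjects = n_subjects,
                 sbp = per_bp(e_sbp), dbp = per_bp(e_dbp),
                 correlation = bp_correlation(pred_sbp, obs_sbp, pred_dbp,
                                              obs_dbp)),
            class = "evaluation_report")
}

#' @importFrom graphics hist
#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d segments, %d subjects\n",
              nrow(x$errors), x$n_subjects))
  for (bp in c("sbp", "dbp")) {
    s <- x[[bp]]
    cat(sprintf(
      "  %s: MAE %.2f RMSE %.2f STD %.2f mmHg | BHS %.1f/%.1f/%.1f%% -> %s | AAMI %s | r %.3f\n",
      toupper(bp), s$mae, s$rmse, s$std, s$bhs$pct_le_5, s$bhs$pct_le_10,
      s$bhs$pct_le_15, s$bhs$grade,
      if (s$aami$pass) "pass" else "fail",
      x$correlation[[paste0("r_", bp)]]))
  }
  invisible(x)
}
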