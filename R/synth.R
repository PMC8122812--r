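#' Synthetic paired PPG/ABP waveform generation
#'
#' The generator emulates simultaneously recorded photoplethysmography (PPG)
#' and arterial blood pressure (ABP) at 125 Hz with known ground truth, so the
#' whole pipeline (preprocessing, quality control, training, evaluation) can be
#' exercised without access to an ICU waveform database.
#'
#' Each beat is the sum of two Gaussian lobes: a systolic lobe centred at 30%
#' of the beat period and a dicrotic (reflected-wave) lobe at 65% with relative
#' amplitude `dicrotic_rel_amp`, reproducing the four classic pulse landmarks
#' (foot, systolic peak, dicrotic notch, diastolic peak).  The ABP waveform is
#' affinely rescaled so its extrema equal `sbp_mmHg` and `dbp_mmHg` exactly
#' when no noise or corruption is configured.  The PPG channel is emitted in
#' arbitrary units centred near zero and is circularly delayed by
#' `lag_samples` relative to the ABP, emulating the pulse-transit phase lag.
#'
#' PPG morphology is coupled to the pressure level, emulating the dependence
#' of peripheral pulse shape on vascular tone: the systolic lobe width grows
#' linearly with DBP and the dicrotic amplitude falls linearly with SBP.  This
#' deterministic morphology-to-pressure map is what makes the synthetic
#' PPG-to-ABP translation task learnable and well-posed.
#'
#' @param sampling_rate_hz Sampling frequency; fixed at 125 Hz.
#' @param segment_len Samples per segment (default 1024, ~8.2 s).
#' @param heart_rate_bpm Mean heart rate in beats per minute.
#' @param hr_jitter Fractional beat-to-beat period jitter (0 = exactly
#'   periodic).
#' @param sbp_mmHg,dbp_mmHg Target systolic/diastolic extrema of the ABP
#'   waveform in mmHg; `dbp_mmHg < sbp_mmHg` required.
#' @param dicrotic_rel_amp Relative amplitude of the ABP dicrotic lobe in
#'   `[0, 1)`.
#' @param lag_samples Integer circular delay applied to the PPG channel;
#'   must be non-negative and shorter than one (jittered) pulse period.
#' @param noise_sd Standard deviation of additive Gaussian noise, per channel
#'   in channel units (arbitrary units for PPG, mmHg for ABP).
#' @param baseline_wander_amp Amplitude of a 0.25 Hz sinusoidal baseline
#'   drift added to the PPG channel (removed later by the bandpass filter).
#' @param corruption One of `"none"`, `"flatline"`, `"dropout_burst"`,
#'   `"saturation"`.  Each mode is engineered to trip exactly one quality
#'   control rule: flatline kills peak detection, a dropout burst destroys
#'   PPG/ABP morphology correlation, and saturation rails the ABP at
#'   200 mmHg so the systolic bound is violated.
#' @param seed Integer RNG seed; generation is fully deterministic given the
#'   configuration.
#' @return A validated configuration object of class `synth_config`.
#' @export
synth_config <- function(sampling_rate_hz = 125, segment_len = 1024,
                         heart_rate_bpm = 75, hr_jitter = 0.02,
                         sbp_mmHg = 120, dbp_mmHg = 80,
                         dicrotic_rel_amp = 0.4, lag_samples = 35,
                         noise_sd = 0.05, baseline_wander_amp = 0.1,
                         corruption = c("none", "flatline", "dropout_burst",
                                        "saturation"),
                         seed = 1L) {
  corruption <- match.arg(corruption)
  cfg <- list(sampling_rate_hz = sampling_rate_hz, segment_len = segment_len,
              heart_rate_bpm = heart_rate_bpm, hr_jitter = hr_jitter,
              sbp_mmHg = sbp_mmHg, dbp_mmHg = dbp_mmHg,
              dicrotic_rel_amp = dicrotic_rel_amp,
              lag_samples = as.integer(lag_samples), noise_sd = noise_sd,
              baseline_wander_amp = baseline_wander_amp,
              corruption = corruption, seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  period <- cfg$sampling_rate_hz * 60 / cfg$heart_rate_bpm
  problems <- character()
  if (cfg$sampling_rate_hz != 125)
    problems <- c(problems, "sampling_rate_hz must be 125")
  if (cfg$dbp_mmHg >= cfg$sbp_mmHg)
    problems <- c(problems, sprintf(
      "dbp_mmHg (%g) must be smaller than sbp_mmHg (%g)",
      cfg$dbp_mmHg, cfg$sbp_mmHg))
  if (cfg$noise_sd < 0)
    problems <- c(problems, "noise_sd must be non-negative")
  if (cfg$hr_jitter < 0 || cfg$hr_jitter >= 0.5)
    problems <- c(problems, "hr_jitter must be in [0, 0.5)")
  if (cfg$lag_samples < 0 ||
      cfg$lag_samples >= floor(period * (1 - cfg$hr_jitter)))
    problems <- c(problems, sprintf(
      "lag_samples (%d) must be in [0, one pulse period = %d samples)",
      cfg$lag_samples, as.integer(floor(period * (1 - cfg$hr_jitter)))))
  if (cfg$segment_len < 2 * period)
    problems <- c(problems, sprintf(
      "segment_len (%d) must cover at least 2 pulse periods (%g samples)",
      cfg$segment_len, 2 * period))
  if (cfg$dicrotic_rel_amp < 0 || cfg$dicrotic_rel_amp >= 1)
    problems <- c(problems, "dicrotic_rel_amp must be in [0, 1)")
  if (cfg$baseline_wander_amp < 0)
    problems <- c(problems, "baseline_wander_amp must be non-negative")
  if (length(problems))
    stop("invalid synth_config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  invisible(cfg)
}

# Sum-of-Gaussian-lobes pulse train evaluated at integer sample times
# 0..(n-1).  onsets are beat start times (samples, may extend outside the
# segment); widths/centres are fractions of each beat's own period.
pulse_train <- function(n, onsets, periods, sys_frac, sys_width,
                        dic_frac, dic_width, dic_amp) {
  t <- seq_len(n) - 1
  out <- numeric(n)
  for (k in seq_along(onsets)) {
    cs <- onsets[k] + sys_frac * periods[k]
    cd <- onsets[k] + dic_frac * periods[k]
    ws <- sys_width * periods[k]
    wd <- dic_width * periods[k]
    out <- out + exp(-(t - cs)^2 / (2 * ws^2)) +
      dic_amp * exp(-(t - cd)^2 / (2 * wd^2))
  }
  out
}

# PPG morphology coupled to pressure: systolic width follows DBP, dicrotic
# amplitude falls with SBP (stiffer, higher-pressure beds damp the reflected
# wave).  Kept linear so the translation task has a clean deterministic map.
ppg_morphology <- function(sbp, dbp) {
  list(sys_width = 0.09 + 0.06 * (dbp - 60) / 70,
       dic_amp = min(0.65, max(0.15, 0.20 + 0.40 * (180 - sbp) / 100)),
       dic_width = 0.10)
}

#' Generate one paired PPG/ABP segment
#'
#' Deterministic for a fixed configuration (including seed).  With
#' `noise_sd = 0` and `corruption = "none"`, `max(abp) == sbp_mmHg` and
#' `min(abp) == dbp_mmHg` exactly.
#'
#' @param config A [synth_config()].
#' @param subject_id,segment_id Identifiers recorded on the segment.
#' @return A `paired_segment`: list with `ppg` (arbitrary units), `abp`
#'   (mmHg), `sampling_rate_hz`, identifiers, and `meta` carrying the ground
#'   truth (configuration echo, true beat onsets and systolic peak indices).
#' @export
generate_segment <- function(config, subject_id = "S001",
                             segment_id = "S001_0001") {
  validate_synth_config(config)
  with_local_seed(config$seed, {
    fs <- config$sampling_rate_hz
    n <- config$segment_len
    period <- fs * 60 / config$heart_rate_bpm

    # beat onsets covering the segment plus margins for lobe tails
    n_beats <- ceiling(n / period) + 4
    jit <- if (config$hr_jitter > 0)
      runif(n_beats, -config$hr_jitter, config$hr_jitter) else numeric(n_beats)
    periods <- period * (1 + jit)
    onsets <- -2 * period + c(0, cumsum(periods[-n_beats]))

    abp_shape <- pulse_train(n, onsets, periods,
                             sys_frac = 0.30, sys_width = 0.12,
                             dic_frac = 0.65, dic_width = 0.10,
                             dic_amp = config$dicrotic_rel_amp)
    rng <- range(abp_shape)
    abp <- config$dbp_mmHg + (config$sbp_mmHg - config$dbp_mmHg) *
      (abp_shape - rng[1]) / (rng[2] - rng[1])

    morph <- ppg_morphology(config$sbp_mmHg, config$dbp_mmHg)
    ppg_shape <- pulse_train(n, onsets, periods,
                             sys_frac = 0.30, sys_width = morph$sys_width,
                             dic_frac = 0.65, dic_width = morph$dic_width,
                             dic_amp = morph$dic_amp)
    ppg <- 2 * (ppg_shape - mean(ppg_shape)) / diff(range(ppg_shape))

    # Calibrate the in-phase reference: PPG and ABP lobe shapes differ, so
    # their raw cross-correlation optimum sits a couple of samples off the
    # shared beat clock.  Pre-advance the PPG so that optimum is at offset
    # zero; lag_samples is then exactly the offset alignment must recover.
    p_int <- min(floor(min(periods)), n - 1)
    cc <- vapply(0:(p_int - 1), function(k)
      sum(abp[1:(n - k)] * ppg[(1 + k):n]), 0.0)
    ostar <- which.max(cc) - 1L
    if (ostar > 0) ppg <- ppg[((seq_len(n) - 1 + ostar) %% n) + 1]

    # circular delay of the PPG channel (the pulse arrives late peripherally)
    lag <- config$lag_samples
    if (lag > 0) ppg <- ppg[((seq_len(n) - 1 - lag) %% n) + 1]

    # true systolic peak sample indices after the net shift (0-based ->
    # 1-based)
    cs <- onsets + 0.30 * periods
    cs <- cs[cs >= 0 & cs < n]
    true_peaks <- sort(((round(cs) + lag - ostar) %% n) + 1)

    if (config$baseline_wander_amp > 0)
      ppg <- ppg + config$baseline_wander_amp *
        sin(2 * pi * 0.25 * (seq_len(n) - 1) / fs + runif(1, 0, 2 * pi))
    if (config$noise_sd > 0) {
      ppg <- ppg + rnorm(n, 0, config$noise_sd)
      abp <- abp + rnorm(n, 0, config$noise_sd)
    }

    if (config$corruption == "flatline") {
      ppg[] <- mean(ppg)
    } else if (config$corruption == "dropout_burst") {
      burst <- seq(floor(n * 0.25), floor(n * 0.25) + floor(n * 0.45))
      ppg[burst] <- 0
    } else if (config$corruption == "saturation") {
      rail <- seq(floor(n * 0.40), floor(n * 0.40) + floor(n * 0.15))
      abp[rail] <- 200
    }

    structure(list(ppg = ppg, abp = abp, sampling_rate_hz = fs,
                   subject_id = subject_id, segment_id = segment_id,
                   meta = list(config = config, true_peaks = true_peaks,
                               onsets = onsets, periods = periods)),
              class = "paired_segment")
  })
}

#' @export
print.paired_segment <- function(x, ...) {
  cat(sprintf("<paired_segment %s> %d samples @ %g Hz", x$segment_id,
              length(x$ppg), x$sampling_rate_hz))
  if (!is.null(x$meta$config))
    cat(sprintf(" | SBP %g / DBP %g mmHg, lag %d, corruption %s",
                x$meta$config$sbp_mmHg, x$meta$config$dbp_mmHg,
                x$meta$config$lag_samples, x$meta$config$corruption))
  cat("\n")
  invisible(x)
}

#' Generate a multi-subject synthetic dataset
#'
#' Subject-level heart rate and pressure targets are drawn from the given
#' ranges with a per-subject sub-seed, so subjects differ but any run with the
#' same base seed reproduces the dataset bit-for-bit.  Diastolic draws are
#' constrained to leave at least 20 mmHg of pulse pressure.
#'
#' @param config Base [synth_config()]; its `seed` drives all draws.
#' @param n_subjects,segments_per_subject Counts (both at least 1).
#' @param sbp_range,dbp_range,hr_range Per-subject uniform draw ranges.
#' @param corrupt_frac Fraction of segments to corrupt (rounded down), drawn
#'   without replacement across the whole dataset.
#' @param corrupt_mode Corruption applied to the selected segments.
#' @return A `paired_dataset`: list of `segments` and a `manifest` data frame
#'   with the per-segment ground truth.
#' @export
generate_dataset <- function(config = synth_config(), n_subjects = 10,
                             segments_per_subject = 4,
                             sbp_range = c(90, 175), dbp_range = c(60, 110),
                             hr_range = c(55, 95), corrupt_frac = 0,
                             corrupt_mode = "flatline") {
  stopifnot(n_subjects >= 1, segments_per_subject >= 1,
            corrupt_frac >= 0, corrupt_frac <= 1)
  n_total <- n_subjects * segments_per_subject
  corrupted_idx <- with_local_seed(config$seed, {
    k <- floor(corrupt_frac * n_total)
    if (k > 0) sort(sample.int(n_total, k)) else integer(0)
  })

  segments <- vector("list", n_total)
  rows <- vector("list", n_total)
  i <- 0L
  for (s in seq_len(n_subjects)) {
    sub_seed <- (config$seed + 77003L * s) %% .Machine$integer.max
    draws <- with_local_seed(sub_seed, {
      sbp <- runif(1, max(sbp_range[1], dbp_range[1] + 25), sbp_range[2])
      dbp <- runif(1, dbp_range[1], min(dbp_range[2], sbp - 20))
      hr <- runif(1, hr_range[1], hr_range[2])
      list(sbp = sbp, dbp = dbp, hr = hr)
    })
    subject_id <- sprintf("S%03d", s)
    for (g in seq_len(segments_per_subject)) {
      i <- i + 1L
      corr <- if (i %in% corrupted_idx) corrupt_mode else "none"
      cfg <- config
      cfg$heart_rate_bpm <- draws$hr
      cfg$sbp_mmHg <- draws$sbp
      cfg$dbp_mmHg <- draws$dbp
      cfg$corruption <- corr
      cfg$seed <- (sub_seed + 131L * g) %% .Machine$integer.max
      segment_id <- sprintf("%s_%04d", subject_id, g)
      segments[[i]] <- generate_segment(cfg, subject_id, segment_id)
      rows[[i]] <- data.frame(subject_id = subject_id,
                              segment_id = segment_id,
                              sbp_mmHg = draws$sbp, dbp_mmHg = draws$dbp,
                              heart_rate_bpm = draws$hr,
                              lag_samples = cfg$lag_samples,
                              corrupted = corr != "none",
                              corruption = corr,
                              stringsAsFactors = FALSE)
    }
  }
  structure(list(segments = segments, manifest = do.call(rbind, rows)),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<paired_dataset> %d segments, %d subjects, %d corrupted\n",
              nrow(m), length(unique(m$subject_id)), sum(m$corrupted)))
  invisible(x)
}

#' Digest of a dataset's waveform content
#'
#' Hash over every segment's PPG and ABP samples; identical seeds must yield
#' identical digests.
#'
#' @param dataset A `paired_dataset`.
#' @return A character scalar hash.
#' @export
dataset_digest <- function(dataset) {
  digest::digest(lapply(dataset$segments, function(s) list(s$ppg, s$abp)))
}
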