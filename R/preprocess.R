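#' Bandpass denoising of PPG waveforms
#'
#' Third-order Butterworth bandpass (default 0.5–8 Hz at 125 Hz sampling),
#' applied forward-backward (zero phase).  Zero-phase application is chosen
#' because the PPG/ABP phase lag is estimated and corrected separately by
#' [align_signals()], and phase distortion would corrupt the derivative
#' feature channels.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz (must exceed twice `high`).
#' @param low,high Passband edges in Hz.
#' @param order Butterworth order of the analogue prototype (the digital
#'   bandpass has twice this order).
#' @return Filtered signal, same length as the input.
#' @export
bandpass_filter <- function(x, fs = 125, low = 0.5, high = 8, order = 3) {
  stopifnot(fs > 2 * high, low > 0, low < high)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  min_len <- 3 * max(length(bf$b), length(bf$a))
  if (length(x) <= min_len)
    stop(sprintf("signal too short to filter: %d samples (need > %d)",
                 length(x), min_len), call. = FALSE)
  as.numeric(signal::filtfilt(bf, x))
}

#' Squared magnitude response of the zero-phase bandpass
#'
#' Evaluates the Butterworth transfer function at the requested frequencies
#' and squares it, matching the effective gain of the forward-backward
#' application in [bandpass_filter()].
#'
#' @inheritParams bandpass_filter
#' @param f Frequencies in Hz at which to evaluate.
#' @return Linear amplitude gain of the zero-phase cascade at each `f`.
#' @export
filter_response <- function(f, fs = 125, low = 0.5, high = 8, order = 3) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  w <- 2 * pi * f / fs
  zinv <- exp(-1i * w)
  ev <- function(coef) {
    acc <- 0+0i
    for (k in seq_along(coef)) acc <- acc + coef[k] * zinv^(k - 1)
    acc
  }
  Mod(ev(bf$b) / ev(bf$a))^2
}

#' Z-score normalization
#'
#' Transforms a signal to zero mean and unit standard deviation using the
#' population (divide-by-n) standard deviation, returning the parameters so
#' the transform can be inverted.
#'
#' @param x Numeric signal; must be non-constant.
#' @return List with `x` (normalized signal) and `params` (list `mu`,
#'   `sigma`).
#' @export
zscore <- function(x) {
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0)
    stop("constant signal: standard deviation is zero; cannot z-score",
         call. = FALSE)
  list(x = (x - mu) / sigma, params = list(mu = mu, sigma = sigma))
}

#' Invert a z-score transform
#'
#' @param x Normalized signal.
#' @param params List with `mu` and `sigma` (from [zscore()] or
#'   [fit_global_norm()], whose `mu_bar`/`sigma_bar` are also accepted).
#' @return The signal on its original scale.
#' @export
invert_zscore <- function(x, params) {
  mu <- if (!is.null(params$mu)) params$mu else params$mu_bar
  sigma <- if (!is.null(params$sigma)) params$sigma else params$sigma_bar
  x * sigma + mu
}

#' Average per-signal normalization parameters over a training set
#'
#' Training signals are each z-scored with their own parameters; at test time
#' a single global pair — the mean of the per-signal means and the mean of
#' the per-signal standard deviations — is applied to every signal.
#'
#' @param params_list Non-empty list of `list(mu, sigma)` pairs.
#' @return List with `mu_bar` and `sigma_bar`.
#' @export
fit_global_norm <- function(params_list) {
  if (!length(params_list))
    stop("cannot fit global normalization from an empty parameter list",
         call. = FALSE)
  list(mu_bar = mean(vapply(params_list, `[[`, 0, "mu")),
       sigma_bar = mean(vapply(params_list, `[[`, 0, "sigma")))
}

#' Cross-correlation phase alignment of PPG against ABP
#'
#' Finds the integer lag maximizing the valid-overlap cross-correlation
#' `g(dt) = sum_t ABP[t] * PPG[t + dt]` over `dt` in `[0, max_lag)`, then
#' advances the PPG by that lag.  The ABP channel is never shifted; the
#' trailing samples exposed by the shift are dropped, so both returned
#' channels are shortened to `length(x) - delta_t`.
#'
#' @param ppg,abp Equal-length numeric signals.
#' @param max_lag Number of lags searched (defaults to one second of samples,
#'   roughly one pulse period).
#' @param fs Sampling rate in Hz, used only for the default `max_lag`.
#' @return List with `delta_t` (samples; `NA` when the correlation is
#'   degenerate), `score` (`g` at `delta_t`), `g` (the full searched
#'   correlation), `shifted_ppg`, and `abp` (both cropped).
#' @export
align_signals <- function(ppg, abp, max_lag = NULL, fs = 125) {
  if (length(ppg) != length(abp))
    stop("ppg and abp must have equal lengths", call. = FALSE)
  n <- length(ppg)
  if (is.null(max_lag)) max_lag <- fs
  stopifnot(max_lag >= 1, max_lag < n)
  lags <- 0:(max_lag - 1)
  g <- vapply(lags, function(L) sum(abp[1:(n - L)] * ppg[(1 + L):n]), 0.0)
  if (all(g == 0) || all(!is.finite(g))) {
    warning("degenerate signals: cross-correlation is identically zero; ",
            "lag undefined")
    return(list(delta_t = NA_integer_, score = NA_real_, g = g,
                shifted_ppg = ppg, abp = abp))
  }
  dt <- lags[which.max(g)]
  keep <- n - dt
  list(delta_t = dt, score = max(g), g = g,
       shifted_ppg = ppg[(1 + dt):n], abp = abp[1:keep])
}

#' Central-difference derivative
#'
#' Interior points use the second-order central formula
#' `(x[i+1] - x[i-1]) / (2h)`; the two endpoints use one-sided first-order
#' differences so the output has the same length as the input (the model
#' requires equal-length channels).
#'
#' @param x Numeric signal of length at least 3.
#' @param h Sample spacing in seconds (1/125 for this pipeline).
#' @return Derivative series, same length as `x`.
#' @export
central_difference <- function(x, h = 1 / 125) {
  n <- length(x)
  if (n < 3)
    stop("need at least 3 samples for a central difference", call. = FALSE)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * h)
  d[1] <- (x[2] - x[1]) / h
  d[n] <- (x[n] - x[n - 1]) / h
  d
}

#' Build the 3-channel model input (PPG, dPPG, sdPPG)
#'
#' Stacks the preprocessed PPG with its first derivative (blood-volume-change
#' velocity) and second derivative (acceleration), the model-ready feature
#' representation.
#'
#' @param ppg Preprocessed (filtered, normalized, aligned) PPG signal.
#' @param h Sample spacing in seconds.
#' @return A `length(ppg) x 3` matrix with columns `ppg`, `dppg`, `sdppg`
#'   and attribute `step_h`.
#' @export
make_feature_stack <- function(ppg, h = 1 / 125) {
  dppg <- central_difference(ppg, h)
  sdppg <- central_difference(dppg, h)
  m <- cbind(ppg = ppg, dppg = dppg, sdppg = sdppg)
  attr(m, "step_h") <- h
  m
}
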