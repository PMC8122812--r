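# Shared fixtures: small, deterministic synthetic inputs.

clean_config <- function(...) {
  args <- list(...)
  base <- list(noise_sd = 0, baseline_wander_amp = 0, hr_jitter = 0,
               lag_samples = 0, seed = 7)
  base[names(args)] <- args
  do.call(synth_config, base)
}

# filter + align + crop, mirroring the pipeline's preprocessing of one
# segment (max_lag in samples)
prep_pair <- function(seg, max_lag = 75) {
  ppg_f <- bandpass_filter(seg$ppg)
  al <- suppressWarnings(align_signals(ppg_f, seg$abp, max_lag = max_lag))
  n <- length(seg$ppg) - max_lag
  list(ppg = al$shifted_ppg[seq_len(n)], abp = al$abp[seq_len(n)],
       delta_t = al$delta_t)
}

# tiny translator configuration for fast training tests
tiny_model_config <- function(...) {
  args <- list(...)
  base <- list(hidden_units = 8, dropout_rate = 0.2, learning_rate = 0.01,
               max_epochs = 5, batch_size = 8, patience = 0, seed = 11)
  base[names(args)] <- args
  do.call(model_config, base)
}

# small synthetic regression task: stacks plus targets that are a smooth
# deterministic function of the input
tiny_task <- function(n = 12, T = 40, seed = 5) {
  set.seed(seed)
  stacks <- vector("list", n)
  targets <- vector("list", n)
  for (i in seq_len(n)) {
    x <- sin(2 * pi * (seq_len(T) / T) * runif(1, 1, 3) + runif(1, 0, 6))
    stacks[[i]] <- make_feature_stack(x)
    targets[[i]] <- 0.5 * x + 0.2
  }
  list(stacks = stacks, targets = targets)
}
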