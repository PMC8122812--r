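#' Default pipeline configuration
#'
#' One nested, auditable home for every constant the pipeline uses:
#' synthetic-data conditions, filter band (0.5–8 Hz, order 3), alignment
#' search window, quality-control thresholds (SBP 80–180, DBP 60–130,
#' r >= 0.8), model hyperparameters (2+2 LSTM layers of 128 units, dropout
#' 0.2, learning rate 0.0025, Adam, <= 50 epochs), and the subject-level
#' 70/10/20 train/validation/test split.  A serialized copy is embedded in
#' every run manifest.
#'
#' @param seed Global seed; every stage derives its randomness from it.
#' @return A nested `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    synth = list(n_subjects = 20, segments_per_subject = 4,
                 segment_len = 1024, heart_rate_bpm = 75, hr_jitter = 0.02,
                 sbp_range = c(90, 175), dbp_range = c(60, 110),
                 hr_range = c(55, 95), dicrotic_rel_amp = 0.4,
                 lag_samples = 20, noise_sd = 0.05,
                 baseline_wander_amp = 0.1, corrupt_frac = 0,
                 corrupt_mode = "flatline"),
    preprocess = list(low_hz = 0.5, high_hz = 8, order = 3,
                      max_lag_s = 0.6),
    qc = list(sbp_min = 80, sbp_max = 180, dbp_min = 60, dbp_max = 130,
              r_min = 0.8),
    model = list(hidden_units = 128, encoder_layers = 2, decoder_layers = 2,
                 dropout_rate = 0.2, learning_rate = 0.0025,
                 max_epochs = 50, batch_size = 128, patience = 5,
                 grad_clip = 5, train_window = 0, compare_random = FALSE),
    split = list(train = 0.7, val = 0.1, test = 0.2)),
    class = "pipeline_config")
}

#' Reference desk-scale validation configuration
#'
#' The package's standard small-compute study: 250 synthetic subjects of 8
#' noise-free 256-sample segments each (about 2,000 segments), a 32-unit
#' model trained for up to 15 epochs per stage with batch size 64, and the
#' random-encoder control arm enabled.  Used by the acceptance script and
#' the end-to-end recovery tests; completes in minutes on one CPU.
#'
#' @param seed Global seed.
#' @return A validated `pipeline_config`.
#' @export
desk_config <- function(seed = 1L) {
  validate_config(list(
    seed = as.integer(seed),
    synth = list(n_subjects = 250, segments_per_subject = 8,
                 segment_len = 256, hr_range = c(70, 95), lag_samples = 20,
                 noise_sd = 0, baseline_wander_amp = 0),
    preprocess = list(max_lag_s = 0.3),
    model = list(hidden_units = 32, max_epochs = 15, batch_size = 64,
                 learning_rate = 0.005, compare_random = TRUE)))
}

merge_config <- function(defaults, override, path = "") {
  errs <- character()
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      errs <- c(errs, sprintf("unknown key '%s'", full))
      next
    }
    if (is.list(defaults[[key]]) && !is.list(override[[key]])) {
      errs <- c(errs, sprintf("'%s' must be a section", full))
    } else if (is.list(defaults[[key]])) {
      res <- merge_config(defaults[[key]], override[[key]], full)
      defaults[[key]] <- res$config
      errs <- c(errs, res$errors)
    } else {
      defaults[[key]] <- override[[key]]
    }
  }
  list(config = defaults, errors = errs)
}

#' Validate a raw configuration against the pipeline schema
#'
#' Accepts a YAML file path or a nested list, fills every default, rejects
#' unknown keys (typo safety), and reports all out-of-range values in a
#' single error.
#'
#' @param raw A file path to a YAML config, a nested list, or `NULL` for
#'   pure defaults.
#' @return A validated `pipeline_config`.
#' @export
validate_config <- function(raw = NULL) {
  defaults <- unclass(pipeline_config())
  override <- if (is.null(raw)) list()
    else if (is.character(raw)) yaml::read_yaml(raw)
    else if (is.list(raw)) raw
    else stop("config must be a file path or a list", call. = FALSE)
  res <- merge_config(defaults, override)
  cfg <- res$config
  errs <- res$errors

  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(cfg$model$dropout_rate >= 0 && cfg$model$dropout_rate < 1,
      sprintf("model.dropout_rate = %g out of range [0, 1)",
              cfg$model$dropout_rate))
  chk(cfg$model$learning_rate > 0, "model.learning_rate must be positive")
  chk(cfg$model$max_epochs >= 0, "model.max_epochs must be non-negative")
  chk(cfg$model$hidden_units >= 1, "model.hidden_units must be positive")
  chk(cfg$model$train_window >= 0, "model.train_window must be non-negative")
  chk(cfg$preprocess$low_hz > 0 &&
        cfg$preprocess$low_hz < cfg$preprocess$high_hz,
      "preprocess band edges must satisfy 0 < low_hz < high_hz")
  chk(cfg$preprocess$max_lag_s > 0, "preprocess.max_lag_s must be positive")
  chk(cfg$qc$sbp_min < cfg$qc$sbp_max && cfg$qc$dbp_min < cfg$qc$dbp_max,
      "qc bounds must be ordered")
  chk(cfg$synth$noise_sd >= 0, "synth.noise_sd must be non-negative")
  chk(cfg$synth$corrupt_frac >= 0 && cfg$synth$corrupt_frac <= 1,
      "synth.corrupt_frac must be in [0, 1]")
  chk(abs(cfg$split$train + cfg$split$val + cfg$split$test - 1) < 1e-9,
      "split fractions must sum to 1")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

# filter -> align -> crop to the uniform post-alignment length
preprocess_segment <- function(seg, pp, target_len, fs) {
  ppg_f <- bandpass_filter(seg$ppg, fs, pp$low_hz, pp$high_hz, pp$order)
  al <- suppressWarnings(
    align_signals(ppg_f, seg$abp, max_lag = round(pp$max_lag_s * fs),
                  fs = fs))
  ppg_al <- al$shifted_ppg
  abp_al <- al$abp
  list(ppg = ppg_al[seq_len(target_len)], abp = abp_al[seq_len(target_len)],
       delta_t = al$delta_t)
}

#' Run the full synthetic-to-evaluation pipeline
#'
#' Executes every stage in order — synthetic generation, preprocessing
#' (filter, align, crop), quality control, the two-stage training
#' (PPG-to-PPG reconstruction, then frozen-encoder PPG-to-ABP translation),
#' test-set translation, and evaluation — and returns a run manifest with
#' per-stage counts, per-rule elimination tallies, digests, training
#' reports, and the evaluation report.
#'
#' @param config A `pipeline_config` (see [validate_config()]).
#' @param verbose Print stage-by-stage progress.
#' @return A `pipeline_manifest` list.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  config <- validate_config(unclass(config))
  say <- function(...) if (verbose) message(sprintf(...))
  fs <- 125
  sy <- config$synth
  pp <- config$preprocess

  say("[synth] generating %d subjects x %d segments", sy$n_subjects,
      sy$segments_per_subject)
  base <- synth_config(segment_len = sy$segment_len,
                       heart_rate_bpm = sy$heart_rate_bpm,
                       hr_jitter = sy$hr_jitter,
                       dicrotic_rel_amp = sy$dicrotic_rel_amp,
                       lag_samples = sy$lag_samples, noise_sd = sy$noise_sd,
                       baseline_wander_amp = sy$baseline_wander_amp,
                       seed = config$seed)
  ds <- generate_dataset(base, sy$n_subjects, sy$segments_per_subject,
                         sbp_range = sy$sbp_range, dbp_range = sy$dbp_range,
                         hr_range = sy$hr_range,
                         corrupt_frac = sy$corrupt_frac,
                         corrupt_mode = sy$corrupt_mode)
  ds_digest <- dataset_digest(ds)

  say("[preprocess+qc] filtering, aligning, screening %d segments",
      length(ds$segments))
  max_lag <- round(pp$max_lag_s * fs)
  target_len <- sy$segment_len - max_lag
  thresholds <- list(sbp_min = config$qc$sbp_min, sbp_max = config$qc$sbp_max,
                     dbp_min = config$qc$dbp_min, dbp_max = config$qc$dbp_max,
                     r_min = config$qc$r_min)
  prepped <- vector("list", length(ds$segments))
  reports <- vector("list", length(ds$segments))
  for (i in seq_along(ds$segments)) {
    seg <- ds$segments[[i]]
    pr <- preprocess_segment(seg, pp, target_len, fs)
    reports[[i]] <- qc_filter(pr$ppg, pr$abp, seg$segment_id, fs,
                              thresholds)
    prepped[[i]] <- pr
  }
  qc_tab <- qc_table(reports)
  reason_counts <- table(unlist(lapply(reports, `[[`, "failure_reasons")))
  passed <- which(qc_tab$passed)
  say("[qc] %d/%d segments pass", length(passed), nrow(qc_tab))

  # subject-level split, seeded, before looking at QC outcomes
  subjects <- unique(ds$manifest$subject_id)
  split <- with_local_seed(config$seed + 17L, {
    shuffled <- sample(subjects)
    n <- length(shuffled)
    n_tr <- max(1, floor(config$split$train * n))
    n_va <- floor(config$split$val * n)
    list(train = shuffled[seq_len(n_tr)],
         val = if (n_va > 0) shuffled[n_tr + seq_len(n_va)] else character(),
         test = shuffled[-seq_len(n_tr + n_va)])
  })
  seg_subj <- ds$manifest$subject_id
  idx_train <- intersect(passed, which(seg_subj %in% split$train))
  idx_val <- intersect(passed, which(seg_subj %in% split$val))
  idx_test <- intersect(passed, which(seg_subj %in% split$test))
  if (!length(idx_train))
    stop("empty training set: every training segment was eliminated by QC",
         call. = FALSE)
  if (!length(idx_test))
    stop("empty test set: every test segment was eliminated by QC",
         call. = FALSE)
  say("[split] train %d / val %d / test %d segments (subject-level)",
      length(idx_train), length(idx_val), length(idx_test))

  # per-signal z-score for training; averaged parameters for testing
  h <- 1 / fs
  norm_train <- lapply(idx_train, function(i) {
    zp <- zscore(prepped[[i]]$ppg)
    za <- zscore(prepped[[i]]$abp)
    list(ppg = zp, abp_params = za$params)
  })
  g_ppg <- fit_global_norm(lapply(norm_train, function(x) x$ppg$params))
  g_abp <- fit_global_norm(lapply(norm_train, function(x) x$abp_params))
  norm <- list(ppg = g_ppg, abp = g_abp, step_h = h)

  # training window: stacks/targets may be cropped to a fixed shorter window
  # for training throughput; QC, translation and evaluation always use the
  # full aligned segment (the network handles any input length)
  tw <- config$model$train_window
  crop <- if (tw > 0 && tw < target_len) function(x) {
    if (is.matrix(x)) x[seq_len(tw), , drop = FALSE] else x[seq_len(tw)]
  } else identity
  stack_of <- function(x) make_feature_stack(x, h)
  train_stacks <- lapply(norm_train, function(x) crop(stack_of(x$ppg$x)))
  train_targets <- lapply(idx_train, function(i)
    crop((prepped[[i]]$abp - g_abp$mu_bar) / g_abp$sigma_bar))
  val_stacks <- if (length(idx_val)) lapply(idx_val, function(i)
    crop(stack_of(zscore(prepped[[i]]$ppg)$x))) else NULL
  val_targets <- if (length(idx_val)) lapply(idx_val, function(i)
    crop((prepped[[i]]$abp - g_abp$mu_bar) / g_abp$sigma_bar)) else NULL

  mcfg <- config$model
  mcfg$train_window <- NULL
  mcfg$compare_random <- NULL
  mc <- do.call(model_config, c(mcfg, list(seed = config$seed)))
  model <- build_model(mc)
  say("[train] stage 1: PPG reconstruction (%d segments, <=%d epochs)",
      length(train_stacks), mc$max_epochs)
  s1 <- train_reconstruction(model, train_stacks, val_stacks)
  model <- freeze_encoder(s1$model)
  say("[train] stage 2: frozen-encoder ABP translation")
  s2 <- train_translation(model, train_stacks, train_targets, val_stacks,
                          val_targets)
  model <- s2$model
  model$norm <- norm

  # optional control arm: a never-pretrained, randomly initialized encoder,
  # frozen and given the same translation budget — quantifies the benefit
  # of transferring the reconstruction-trained encoder
  scratch_report <- NULL
  if (isTRUE(config$model$compare_random)) {
    say("[train] control: frozen random-init encoder, same budget")
    rnd <- build_model(do.call(model_config,
                               c(mcfg, list(seed = config$seed + 9001L))))
    rnd <- freeze_encoder(rnd)
    scratch_report <- train_translation(rnd, train_stacks, train_targets,
                                        val_stacks, val_targets)$report
  }

  say("[translate+evaluate] %d held-out segments", length(idx_test))
  predicted <- lapply(idx_test, function(i) translate(model,
                                                      prepped[[i]]$ppg))
  observed <- lapply(idx_test, function(i) prepped[[i]]$abp)
  ids <- qc_tab$segment_id[idx_test]
  names(predicted) <- ids
  names(observed) <- ids
  evaluation <- evaluate_run(predicted, observed, ids,
                             subject_ids = seg_subj[idx_test])

  structure(list(
    config = unclass(config),
    seed = config$seed,
    counts = list(segments_generated = nrow(qc_tab),
                  qc_passed = length(passed),
                  qc_eliminated = nrow(qc_tab) - length(passed),
                  eliminated_by_reason = as.list(reason_counts),
                  train = length(idx_train), val = length(idx_val),
                  test = length(idx_test)),
    digests = list(dataset = ds_digest,
                   encoder = encoder_digest(model),
                   model = digest::digest(model$params)),
    norm = norm,
    qc = qc_tab,
    reports = list(reconstruction = s1$report, translation = s2$report,
                   translation_scratch = scratch_report),
    evaluation = evaluation,
    model = model), class = "pipeline_manifest")
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("<pipeline_manifest> seed %d\n", x$seed))
  cat(sprintf("  segments: %d generated, %d passed QC (train/val/test %d/%d/%d)\n",
              x$counts$segments_generated, x$counts$qc_passed,
              x$counts$train, x$counts$val, x$counts$test))
  print(x$evaluation)
  invisible(x)
}
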