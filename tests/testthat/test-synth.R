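test_that("noise-free generation hits the configured extrema exactly and is seed-deterministic", {
  cfg <- clean_config(sbp_mmHg = 120, dbp_mmHg = 80)
  s1 <- generate_segment(cfg)
  expect_identical(max(s1$abp), 120)
  expect_identical(min(s1$abp), 80)
  expect_identical(generate_segment(cfg), s1)

  cfg2 <- clean_config(sbp_mmHg = 150, dbp_mmHg = 65)
  s2 <- generate_segment(cfg2)
  expect_equal(max(s2$abp), 150)
  expect_equal(min(s2$abp), 65)
})

test_that("clean PPG and ABP templates are morphologically correlated (r >= 0.8)", {
  for (bp in list(c(120, 80), c(175, 105), c(90, 60), c(175, 60))) {
    s <- generate_segment(clean_config(sbp_mmHg = bp[1], dbp_mmHg = bp[2]))
    expect_gte(pearson_r(s$abp, s$ppg), 0.8)
  }
})

test_that("invalid configurations are rejected with descriptive errors", {
  expect_error(synth_config(sbp_mmHg = 80, dbp_mmHg = 90), "smaller than")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
  expect_error(synth_config(lag_samples = 200), "pulse period")
  expect_error(synth_config(segment_len = 150), "2 pulse periods")
})

test_that("jitter-free generation is periodic: autocorrelation peaks at the pulse period", {
  cfg <- clean_config(heart_rate_bpm = 75)  # period = 100 samples
  s <- generate_segment(cfg)
  ac <- stats::acf(s$ppg, lag.max = 150, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac[50:150]) + 49, 100)
})

test_that("the recorded lag is the circular shift applied to the PPG channel", {
  for (L in c(0L, 10L, 35L, 60L)) {
    base <- generate_segment(clean_config(lag_samples = 0))
    lagged <- generate_segment(clean_config(lag_samples = L))
    n <- length(base$ppg)
    expect_equal(lagged$ppg, base$ppg[((seq_len(n) - 1 - L) %% n) + 1])
    expect_equal(lagged$meta$config$lag_samples, L)
  }
})

test_that("cross-correlation of clean pairs is maximized exactly at the injected lag", {
  for (L in c(0L, 10L, 35L, 60L)) {
    s <- generate_segment(clean_config(lag_samples = L))
    al <- align_signals(s$ppg, s$abp, max_lag = 100)
    expect_identical(al$delta_t, L)
  }
})

test_that("datasets have the requested shape, distinct subjects, and reproducible digests", {
  cfg <- synth_config(seed = 3)
  ds <- generate_dataset(cfg, n_subjects = 3, segments_per_subject = 2)
  expect_length(ds$segments, 6)
  expect_length(unique(ds$manifest$subject_id), 3)
  expect_identical(dataset_digest(ds),
                   dataset_digest(generate_dataset(cfg, 3, 2)))
  ds2 <- generate_dataset(synth_config(seed = 4), 3, 2)
  expect_false(dataset_digest(ds) == dataset_digest(ds2))
})

test_that("per-subject draws respect the configured ranges with 20 mmHg pulse pressure", {
  ds <- generate_dataset(synth_config(seed = 9), n_subjects = 25,
                         segments_per_subject = 1,
                         sbp_range = c(90, 175), dbp_range = c(60, 110))
  m <- ds$manifest
  expect_true(all(m$sbp_mmHg >= 90 & m$sbp_mmHg <= 175))
  expect_true(all(m$dbp_mmHg >= 60 & m$dbp_mmHg <= 110))
  expect_true(all(m$sbp_mmHg - m$dbp_mmHg >= 20))
})

test_that("corrupted segments are flagged in the manifest and only those fail QC downstream", {
  ds <- generate_dataset(synth_config(seed = 42), n_subjects = 10,
                         segments_per_subject = 6, corrupt_frac = 0.1,
                         corrupt_mode = "flatline")
  expect_equal(sum(ds$manifest$corrupted), 6)
  reports <- lapply(ds$segments, function(s) {
    pr <- prep_pair(s)
    qc_filter(pr$ppg, pr$abp, s$segment_id)
  })
  tab <- qc_table(reports)
  expect_identical(tab$segment_id[!tab$passed],
                   ds$manifest$segment_id[ds$manifest$corrupted])
  no_peak <- vapply(reports, function(r) "no_peak" %in% r$failure_reasons,
                    TRUE)
  expect_identical(which(no_peak), which(ds$manifest$corrupted))
})
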