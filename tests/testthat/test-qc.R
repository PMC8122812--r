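test_that("SBP/DBP extraction is max/min of the waveform", {
  expect_identical(extract_sbp(c(80, 120, 95)), 120)
  expect_identical(extract_dbp(c(80, 120, 95)), 80)
  expect_identical(extract_sbp(rep(100, 5)), 100)
  expect_identical(extract_dbp(rep(100, 5)), 100)
  expect_error(extract_sbp(numeric(0)), "empty")
  expect_error(extract_dbp(numeric(0)), "empty")

  s <- generate_segment(clean_config(sbp_mmHg = 150, dbp_mmHg = 65))
  expect_equal(extract_sbp(s$abp), 150)
  expect_equal(extract_dbp(s$abp), 65)
})

test_that("pearson_r matches the product-moment formula and its invariances", {
  a <- c(1, 2, 3)
  expect_equal(pearson_r(a, 2 * a + 1), 1)
  expect_equal(pearson_r(a, -a), -1)
  expect_equal(pearson_r(a, c(1, 2, 2)), 0.8660, tolerance = 1e-4)
  set.seed(8)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(pearson_r(x, y), pearson_r(y, x))
  expect_equal(pearson_r(x, y), pearson_r(2 * x + 3, y), tolerance = 1e-12)
  expect_warning(r <- pearson_r(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(r))
  expect_error(pearson_r(1:3, 1:4), "equal lengths")
})

test_that("systolic peaks are found at the template lobe centres on clean signals", {
  s <- generate_segment(clean_config(heart_rate_bpm = 75))
  pk <- detect_systolic_peaks(bandpass_filter(s$ppg))
  expect_true(abs(length(pk) - 10) <= 1)
  offsets <- vapply(pk, function(p) min(abs(p - s$meta$true_peaks)), 0)
  expect_lte(max(offsets), 3)
})

test_that("flatline and noise-only signals yield no usable peaks", {
  expect_length(detect_systolic_peaks(rep(1, 1024)), 0)
  set.seed(11)
  expect_length(detect_systolic_peaks(rnorm(1024)), 0)
  for (sd_ in 1:5) {
    set.seed(sd_)
    expect_length(detect_systolic_peaks(rnorm(1024)), 0)
  }
})

test_that("qc_filter evaluates all four rules and attributes planted violations", {
  mk <- function(...) {
    s <- generate_segment(synth_config(..., seed = 31))
    pr <- prep_pair(s)
    qc_filter(pr$ppg, pr$abp, "seg")
  }
  clean <- mk(sbp_mmHg = 120, dbp_mmHg = 80)
  expect_true(clean$passed)
  expect_length(clean$failure_reasons, 0)

  high <- mk(sbp_mmHg = 190, dbp_mmHg = 80)
  expect_false(high$passed)
  expect_identical(high$failure_reasons, "sbp_range")

  low <- mk(sbp_mmHg = 120, dbp_mmHg = 55)
  expect_false(low$passed)
  expect_identical(low$failure_reasons, "dbp_range")

  burst <- mk(corruption = "dropout_burst")
  expect_true("low_correlation" %in% burst$failure_reasons)

  flat <- mk(corruption = "flatline")
  expect_true("no_peak" %in% flat$failure_reasons)
  expect_identical(flat$peaks_found, 0L)
})

test_that("pressure bounds are strict on the outside: exact limits pass", {
  # rescale a clean waveform to sit exactly on the limits
  s <- generate_segment(clean_config(sbp_mmHg = 180, dbp_mmHg = 60))
  pr <- prep_pair(s)
  at_limit <- qc_filter(pr$ppg, pr$abp, "limits")
  expect_true(at_limit$passed)

  eps <- 0.01
  over <- pr$abp * (180 + eps - 60) / (max(pr$abp) - 60) +
    60 * (1 - (180 + eps - 60) / (max(pr$abp) - 60))
  expect_true("sbp_range" %in% qc_filter(pr$ppg, over, "over")$failure_reasons)

  under <- pr$abp - (min(pr$abp) - (60 - eps))
  expect_true("dbp_range" %in%
                qc_filter(pr$ppg, under, "under")$failure_reasons)
})

test_that("QC pass rate equals one minus the planted corruption fraction", {
  ds <- generate_dataset(synth_config(seed = 77), n_subjects = 10,
                         segments_per_subject = 5, corrupt_frac = 0.2,
                         corrupt_mode = "saturation")
  tab <- qc_table(lapply(ds$segments, function(s) {
    pr <- prep_pair(s)
    qc_filter(pr$ppg, pr$abp, s$segment_id)
  }))
  expect_equal(mean(tab$passed), 0.8)
  expect_setequal(tab$segment_id[!tab$passed],
                  ds$manifest$segment_id[ds$manifest$corrupted])
})
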