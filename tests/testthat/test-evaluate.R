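test_that("mae and rmse match hand arithmetic and brute-force accumulation", {
  expect_equal(mae(c(0, 0, 0)), 0)
  expect_equal(mae(c(3, -4)), 3.5)
  expect_equal(rmse(c(0, 0)), 0)
  expect_equal(rmse(c(3, 4)), sqrt(12.5))
  expect_error(mae(numeric(0)), "empty")
  expect_error(rmse(numeric(0)), "empty")

  set.seed(2)
  e <- rnorm(1e4, 0, 5)
  brute_mae <- 0
  brute_sq <- 0
  for (v in e) {
    brute_mae <- brute_mae + abs(v)
    brute_sq <- brute_sq + v^2
  }
  expect_equal(mae(e), brute_mae / length(e), tolerance = 1e-10)
  expect_equal(rmse(e), sqrt(brute_sq / length(e)), tolerance = 1e-10)
})

test_that("rmse dominates mae on random error sets", {
  set.seed(6)
  for (i in 1:200) {
    e <- rnorm(sample(2:50, 1), sd = runif(1, 0.1, 10))
    expect_gte(rmse(e), mae(e))
  }
})

test_that("published cumulative percentages grade A and constructed sets grade as counted", {
  expect_identical(bhs_grade_from_pct(70.6, 94.1, 98.6), "A")
  expect_identical(bhs_grade_from_pct(91.1, 99.1, 99.8), "A")
  expect_identical(bhs_grade_from_pct(60, 85, 95), "A")    # inclusive
  expect_identical(bhs_grade_from_pct(59.9, 85, 95), "B")
  expect_identical(bhs_grade_from_pct(39, 65, 85), "fail")

  # 20 errors: 11 within 5, 16 within 10, 18 within 15 -> 55/80/90 -> B
  e <- c(rep(2, 11), rep(8, 5), rep(12, 2), rep(20, 2))
  b <- bhs_grade(e)
  expect_equal(b$pct_le_5, 55)
  expect_equal(b$pct_le_10, 80)
  expect_equal(b$pct_le_15, 90)
  expect_identical(b$grade, "B")

  # exact-threshold errors count as within (|e| <= 5)
  exact <- bhs_grade(c(rep(5, 6), rep(10, 3), rep(15, 1)))
  expect_equal(exact$pct_le_5, 60)
  expect_identical(exact$grade, "A")
  expect_error(bhs_grade(numeric(0)), "empty")
})

test_that("bhs grading is monotone under error inflation", {
  set.seed(14)
  e <- abs(rnorm(400, 0, 4))
  g0 <- bhs_grade(e)$grade
  g_shrunk <- bhs_grade(c(e, 0))$grade  # adding a zero error never hurts
  g_scaled <- bhs_grade(3 * e)$grade
  order <- c(A = 3, B = 2, C = 1, fail = 0)
  expect_gte(order[g_shrunk], order[g0])
  expect_lte(order[g_scaled], order[g0])
})

test_that("AAMI verdicts reproduce the published rows and boundary semantics", {
  # error sets engineered to the published MAE/STD summaries
  expect_true(aami_check(c(-4.05, 4.05), 5289)$pass)
  ok <- aami_check(rnorm(1000, 0, 3), 100)
  expect_true(ok$pass)

  # engineer an error set with exact MAE m and population SD s
  mk <- function(m, s, n) {
    e <- if (m >= s) c(m - s, m + s)
    else {
      d <- sqrt(s^2 - m^2)
      c(m + d, -(m + d), m - d, -(m - d))
    }
    aami_check(e, n)
  }
  expect_false(mk(5.0, 4.0, 100)$pass)  # mae not < 5
  expect_false(mk(4.0, 8.0, 100)$pass)  # std not < 8
  expect_false(mk(4.0, 4.0, 85)$pass)   # needs > 85 subjects
  expect_true(mk(4.0, 4.0, 86)$pass)
  expect_equal(mk(4.05, 4.60, 5289)$mae, 4.05)
  expect_equal(mk(4.05, 4.60, 5289)$std, 4.60)
  expect_true(mk(4.05, 4.60, 5289)$pass)
  expect_true(mk(2.41, 3.11, 5289)$pass)
})

test_that("SBP/DBP correlations behave at the identity and permutation null", {
  set.seed(9)
  sbp <- runif(100, 90, 180)
  dbp <- runif(100, 60, 110)
  r <- bp_correlation(sbp, sbp, dbp, dbp)
  expect_equal(r$r_sbp, 1)
  expect_equal(r$r_dbp, 1)
  big <- runif(1e4, 90, 180)
  expect_lt(abs(pearson_r(big, sample(big))), 0.05)
})

test_that("evaluate_run handles the perfect and constant-offset limits", {
  ds <- generate_dataset(synth_config(seed = 15), 5, 2)
  obs <- lapply(ds$segments, `[[`, "abp")
  names(obs) <- ds$manifest$segment_id
  perfect <- evaluate_run(obs, obs, subject_ids = ds$manifest$subject_id)
  expect_equal(perfect$sbp$mae, 0)
  expect_equal(perfect$dbp$rmse, 0)
  expect_identical(perfect$sbp$bhs$grade, "A")
  expect_false(perfect$sbp$aami$pass)  # only 5 subjects, needs > 85

  shifted <- lapply(obs, function(x) x + 6)
  off <- evaluate_run(shifted, obs, subject_ids = ds$manifest$subject_id)
  expect_equal(off$sbp$mae, 6)
  expect_equal(off$sbp$bhs$pct_le_5, 0)
  expect_identical(off$sbp$bhs$grade, "fail")

  bad_names <- obs
  names(bad_names) <- rev(names(obs))
  expect_error(evaluate_run(bad_names, obs), "mismatch")
  expect_error(evaluate_run(obs[1:3], obs), "differ")
})

test_that("planted half-normal errors reproduce the analytic CDF at 5 mmHg", {
  set.seed(33)
  n <- 100
  scale <- 3
  e <- abs(rnorm(n, 0, scale))
  obs <- lapply(seq_len(n), function(i) c(100, 100 + 40))  # dbp 100, sbp 140
  pred <- lapply(seq_len(n), function(i) c(100, 140 + e[i]))
  names(obs) <- names(pred) <- sprintf("s%03d", seq_len(n))
  # observed pressures are deliberately constant, so the correlation is
  # undefined (and warned about); the check targets the BHS percentage
  rep <- suppressWarnings(evaluate_run(pred, obs))
  analytic <- 100 * (2 * pnorm(5 / scale) - 1)
  expect_lt(abs(rep$sbp$bhs$pct_le_5 - analytic), 5)
})
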