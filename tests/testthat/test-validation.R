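# Screening-validation statistics: T, Fm, cc-beta, Horwitz, specificity,
# stability, ruggedness, full-study pipeline.

test_that("threshold value is mean plus 1.64 sample SDs", {
  expect_equal(threshold_value(c(1, 2, 3)), 3.64)
  expect_equal(threshold_value(c(5, 5, 5, 5)), 5)
  expect_equal(threshold_value(rep(0, 25)), 0)
  expect_error(threshold_value(3), "at least 2")
})

test_that("cut-off factor is mean minus 1.64 sample SDs", {
  expect_equal(cutoff_factor(c(48, 50, 52)), 46.72)
  expect_equal(cutoff_factor(rep(50, 10)), 50)
  expect_warning(fm <- cutoff_factor(c(0.1, 10)), "negative")
  expect_lt(fm, 0)
  expect_error(cutoff_factor(50), "at least 2")
})

test_that("detection-capability verdict requires Fm strictly above T", {
  expect_true(assess_ccbeta(3.64, 46.72, 50)$pass)
  expect_false(assess_ccbeta(50, 46.72, 50)$pass)
  expect_false(assess_ccbeta(46.72, 46.72, 50)$pass)
  expect_match(assess_ccbeta(50, 46.72, 50)$message, "new experiments")
  # monotone in Fm: raising Fm never flips pass to fail
  fms <- seq(0, 10, by = 0.5)
  passes <- vapply(fms, function(f) assess_ccbeta(5, f, 50)$pass, logical(1))
  expect_true(all(diff(passes) >= 0))
})

test_that("within-lab CV and its guide limits follow the printed rules", {
  expect_equal(cv_within_lab(c(50, 50, 50)), 0)
  x <- c(4 - 0.648, 4, 4 + 0.648)
  expect_equal(cv_within_lab(x), 100 * sd(x) / 4, tolerance = 1e-12)
  expect_error(cv_within_lab(c(-1, 1)), "must be > 0")

  expect_equal(max_allowed_cv(50), 25)
  expect_equal(max_allowed_cv(4), 30)
  expect_equal(max_allowed_cv(10), 25)   # "below 10" is exclusive
  expect_equal(max_allowed_cv(119.9), 25)
  # above 120 ug/kg the Horwitz function takes over: 2^(1 - 0.5 log10(2e-7))
  expect_equal(max_allowed_cv(200), 20.3866, tolerance = 1e-4)
})

test_that("Horwitz function and its four-decade halving property", {
  expect_equal(horwitz_cv(1), 2)
  expect_equal(horwitz_cv(0.01), 4)
  expect_equal(horwitz_cv(1e-7), 2^4.5, tolerance = 1e-12)
  expect_error(horwitz_cv(0), "must be > 0")
  for (C in c(1e-9, 1e-7, 1e-4)) {
    expect_equal(horwitz_cv(C * 1e4), horwitz_cv(C) / 4, tolerance = 1e-12)
  }
})

test_that("T and Fm agree with direct mean/SD arithmetic on random vectors", {
  # independent oracle: explicit sum-based mean and (n-1) SD
  set.seed(99)
  for (k in 1:1000) {
    n <- sample(2:50, 1)
    x <- runif(n, 0, 100)
    m <- sum(x) / n
    s <- sqrt(sum((x - m)^2) / (n - 1))
    expect_equal(threshold_value(x), m + 1.64 * s, tolerance = 1e-12)
    expect_equal(suppressWarnings(cutoff_factor(x)), m - 1.64 * s,
                 tolerance = 1e-12)
  }
})

test_that("specificity counts interference in the m/z x RT window", {
  db <- small_db()
  blanks <- lapply(1:5, function(i)
    gen_blank_run(db, noise = zero_noise(), seed = i))
  spec <- specificity_check(blanks, db)
  expect_true(all(spec$pass))
  expect_true(all(spec$interference_runs == 0))

  # inject a co-eluting ion into the amoxicillin window of one blank
  amox <- db$compounds[db$compounds$name == "Amoxicillin", ]
  blanks[[1]]$features <- rbind(blanks[[1]]$features, data.frame(
    mz = amox$mz_theoretical * (1 + 2e-6), rt_min = amox$rt_min * 1.01,
    response = 50, fragment_mzs = "", stringsAsFactors = FALSE))
  spec2 <- specificity_check(blanks, db)
  expect_equal(spec2$interference_runs[spec2$name == "Amoxicillin"], 1)
  expect_false(spec2$pass[spec2$name == "Amoxicillin"])

  # the same ion outside the RT window does not count
  blanks[[1]]$features$rt_min[nrow(blanks[[1]]$features)] <- amox$rt_min * 1.10
  spec3 <- specificity_check(blanks, db)
  expect_equal(spec3$interference_runs[spec3$name == "Amoxicillin"], 0)
})

test_that("stability passes identical curves and fails drift or curvature", {
  mk <- function(slope, intercept, r2) structure(
    list(name = "x", slope = slope, intercept = intercept, r_squared = r2),
    class = "calibration_curve")
  same <- stability_assess(list(mk(100, 5, 1), mk(100, 5, 1), mk(100, 5, 1)))
  expect_true(all(same$pass))
  expect_true(all(same$yx_rel_change == 0))

  drifted <- stability_assess(list(mk(100, 5, 1), mk(100, 5 * 1.25, 1)))
  expect_false(drifted$pass[2])
  expect_equal(drifted$yx_rel_change[2], 0.25)
  ok_drift <- stability_assess(list(mk(100, 5, 1), mk(100, 5 * 1.19, 1)))
  expect_true(ok_drift$pass[2])

  curved <- stability_assess(list(mk(100, 5, 1), mk(100, 5, 0.995)))
  expect_false(curved$pass[2])
  expect_true(curved$yx_pass[2])
  expect_error(stability_assess(list(mk(0, 5, 1))), "slope is zero")
})

test_that("ruggedness t-test: degenerate, significant, and alpha monotone", {
  same <- suppressWarnings(ruggedness_ttest(c(50, 50), c(50, 50)))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  f <- c(49, 50, 51, 50, 50)
  F <- c(54, 55, 56, 55, 55)
  rt <- ruggedness_ttest(f, F)
  # Welch statistic by hand: (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)
  t_hand <- (mean(f) - mean(F)) / sqrt(var(f) / 5 + var(F) / 5)
  expect_equal(rt$t, t_hand, tolerance = 1e-12)
  expect_equal(rt$t, -11.18, tolerance = 1e-2)
  expect_true(rt$significant)
  expect_false(ruggedness_ttest(f, F, alpha = 1e-9)$significant)
  expect_warning(ruggedness_ttest(c(1, 1), c(1, 2)), "zero variance")
})

test_that("the default synthetic validation study passes for every analyte", {
  db <- panel_db()
  study <- gen_validation_study(db, seed = 314)
  report <- run_validation(study, db)
  expect_equal(nrow(report), 57)
  expect_true(all(report$ccbeta_pass))
  expect_true(all(report$fm > report$t_value))
  # determinism: regenerating the study reproduces the report
  report2 <- run_validation(gen_validation_study(db, seed = 314), db)
  expect_equal(as.data.frame(report), as.data.frame(report2))
})

test_that("generated dispersion stays below the precision guide values", {
  # interference-free study: CV_R reflects the Table-like generating CVs
  # (max 18.5%), all under their 25/30% guide limits
  db <- panel_db()
  noise <- noise_model(blank_feature_rate = 0)
  study <- gen_validation_study(db, noise = noise, seed = 271)
  report <- run_validation(study, db)
  expect_true(all(report$precision_pass))
  expect_true(all(report$cv_r_pct < report$cv_limit_pct))
})

test_that("a zero-spike study fails detection capability everywhere", {
  db <- small_db()
  study <- gen_validation_study(db, level = 0, seed = 5)
  report <- run_validation(study, db)
  expect_false(any(report$ccbeta_pass))
})

test_that("false-negative rate below the true-parameter cut-off is ~5%", {
  # Fm from the true normal parameters; the simulated exceedance fraction
  # reads the same 1.64-sigma quantile the cut-off formula encodes
  level <- 50
  cv <- 0.10
  fm <- level - 1.64 * cv * level
  x <- withr::with_seed(2718, milkscreen:::draw_spike_concentrations(
    level, cv, 1e5, trunc_sd = 4))
  fn <- mean(x < fm)
  expect_gt(fn, 0.045)
  expect_lt(fn, 0.056)
})

test_that("study-level CV_R recovers the generating dispersion end to end", {
  db <- db_subset(panel_db(), "Penicillin V")
  cvs <- vapply(1:20, function(s) {
    study <- gen_validation_study(db, seed = 4000 + s)
    run_validation(study, db)$cv_r_pct
  }, numeric(1))
  # n = 25 sampling band around the generating 16.2%; individual studies can
  # be inflated by a rare background-feature collision
  expect_lt(abs(mean(cvs) - 16.2) / 16.2, 0.15)
  expect_true(all(cvs > 16.2 * 0.4 & cvs < 16.2 * 2.0))
})
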