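# Calibration fitting, back-calculation, screening verdicts, batch QC.

test_that("calibration fit recovers an exact line and flags noise", {
  lv <- c(0.1, 0.5, 1, 5, 10)
  cv <- fit_calibration(lv, 2 * lv + 1)
  expect_equal(cv$slope, 2, tolerance = 1e-12)
  expect_equal(cv$intercept, 1, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)

  cv2 <- fit_calibration(lv, c(1.1, 2.9, 5.2, 24.8, 50.1))
  expect_equal(cv2$slope, 4.95, tolerance = 0.01)
  expect_gt(cv2$r_squared, 0.999)

  set.seed(7)
  noise_fit <- fit_calibration(lv, rnorm(5))
  expect_lt(noise_fit$r_squared, 0.999)

  expect_error(fit_calibration(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(fit_calibration(1, 1), "length")
})

test_that("back-calculation inverts the curve and applies the 41x dilution", {
  cv <- fit_calibration(c(0.1, 0.5, 1, 5, 10),
                        100 * c(0.1, 0.5, 1, 5, 10) + 3)
  expect_equal(back_calculate(cv, 3), 0)
  expect_equal(back_calculate(cv, 100 * 1.22 + 3), 1.22 * 41,
               tolerance = 1e-9)
  expect_equal(back_calculate(cv, 100 * 0.0976 + 3), 4.0016,
               tolerance = 1e-6)
  # readings below the curve clamp to zero, not negative
  expect_equal(back_calculate(cv, 0), 0)
  zero <- structure(list(name = "z", slope = 0, intercept = 5,
                         r_squared = 1), class = "calibration_curve")
  expect_error(back_calculate(zero, 5), "slope is zero")
})

test_that("round trip through fit and back-calculation is exact", {
  lv <- c(0.1, 0.5, 1, 5, 10)
  cv <- fit_calibration(lv, 250 * lv + 7)
  dil <- dilution_model()
  for (c0 in c(0.1, 0.33, 1, 4.7, 10)) {
    got <- back_calculate(cv, 250 * c0 + 7, dil) / dilution_factor(dil)
    expect_equal(got, c0, tolerance = 1e-10)
  }
})

test_that("the dilution model maps STC levels into the calibration range", {
  dfac <- dilution_factor(dilution_model())
  expect_equal(dfac, 41)
  stc <- panel_db()$compounds$stc_ug_kg
  vial <- stc / dfac
  expect_equal(min(vial), 4 / 41, tolerance = 1e-12)   # ~0.098 ug/L
  expect_equal(max(vial), 75 / 41, tolerance = 1e-12)  # ~1.83 ug/L
  expect_true(all(vial >= 0.09 & vial <= 10))
})

test_that("screening verdicts: blank compliant, 2x STC suspect, boundary compliant", {
  db <- small_db()
  cal <- gen_calibration_series(db, noise = zero_noise(), seed = 1)
  curves <- fit_calibration_series(cal)
  cutoffs <- default_cutoffs(db)

  blank <- gen_blank_run(db, noise = zero_noise(), seed = 2)
  dec <- screen_sample(blank, db, curves, cutoffs)
  expect_true(all(dec$verdict == "compliant"))
  expect_equal(sample_verdict(dec), "compliant")

  hot <- gen_spiked_run(db, 2 * stc_levels(db), noise = zero_noise(), seed = 3)
  dec2 <- screen_sample(hot, db, curves, cutoffs)
  expect_true(all(dec2$verdict == "suspect"))
  expect_equal(dec2$conc_ug_kg, unname(2 * stc_levels(db)), tolerance = 1e-6)

  # concentration exactly at the cut-off stays compliant (strict inequality);
  # exact-arithmetic construction: slope 2, intercept 0, response 2 -> vial 1
  # -> sample 41 ug/kg against a cut-off of exactly 41
  amox <- db$compounds[1, ]
  exact_curve <- list(Amoxicillin = structure(
    list(name = "Amoxicillin", levels = c(0, 1, 2), responses = c(0, 2, 4),
         slope = 2, intercept = 0, r_squared = 1),
    class = "calibration_curve"))
  feat <- data.frame(mz = amox$mz_theoretical, rt_min = amox$rt_min,
                     response = 2,
                     fragment_mzs = sprintf("%.1f;%.1f", amox$fragment1_mz,
                                            amox$fragment2_mz),
                     stringsAsFactors = FALSE)
  dec3 <- screen_sample(feat, db_subset(db, "Amoxicillin"), exact_curve,
                        c(Amoxicillin = 41))
  expect_identical(dec3$conc_ug_kg, 41)
  expect_equal(dec3$verdict, "compliant")
  dec4 <- screen_sample(feat, db_subset(db, "Amoxicillin"), exact_curve,
                        c(Amoxicillin = 40.9))
  expect_equal(dec4$verdict, "suspect")
})

test_that("screening demands a curve and cut-off for every identified analyte", {
  db <- small_db()
  cal <- gen_calibration_series(db, noise = zero_noise(), seed = 1)
  curves <- fit_calibration_series(cal)
  run <- gen_spiked_run(db, stc_levels(db), noise = zero_noise(), seed = 5)
  expect_error(screen_sample(run, db, curves[-1], default_cutoffs(db)),
               "no calibration curve for identified compound 'Amoxicillin'")
  expect_error(screen_sample(run, db, curves, default_cutoffs(db)[-1]),
               "no cut-off configured for identified compound 'Amoxicillin'")
})

test_that("a well-formed batch passes QC; broken controls fail with reasons", {
  db <- small_db()
  b <- gen_batch(db, n_unknowns = 1, seed = 10)
  qc <- qc_batch(b, db)
  expect_true(qc$pass)
  expect_equal(qc$negative_verdict, "compliant")
  expect_equal(qc$positive_verdict, "suspect")
  expect_true(all(qc$is_checks$present))

  # positive control generated at zero concentration
  broken <- b
  broken$runs$positive_control <- gen_blank_run(db, seed = 77,
                                                run_id = "positive-control")
  broken$runs$positive_control$role <- "positive_control"
  qc2 <- qc_batch(broken, db)
  expect_false(qc2$pass)
  expect_true(any(grepl("positive control not suspect", qc2$failures)))

  # internal standard drifted by +5% in RT (> 2.5% tolerance)
  drift <- b
  is_mz <- internal_standards()$mz_theoretical[1]
  feats <- drift$runs$negative_control$features
  hit <- which.min(abs(feats$mz - is_mz))
  feats$rt_min[hit] <- feats$rt_min[hit] * 1.05
  drift$runs$negative_control$features <- feats
  qc3 <- qc_batch(drift, db)
  expect_false(qc3$pass)
  expect_true(any(grepl("RT-drifted", qc3$failures)))

  no_controls <- b
  no_controls$runs$negative_control <- NULL
  expect_error(qc_batch(no_controls, db), "missing its control")
})
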