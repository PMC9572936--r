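# Feature-to-compound matching and identification-point scoring.

test_that("precursor matching is inclusive at the 5 ppm boundary", {
  expect_true(match_precursor(366.1118, 366.1118)$matched)
  expect_equal(match_precursor(366.1118, 366.1118)$ppm, 0)
  hit <- match_precursor(366.1118 * (1 + 5e-6), 366.1118)
  expect_true(hit$matched)
  expect_equal(hit$ppm, 5, tolerance = 1e-9)
  miss <- match_precursor(366.1155, 366.1118)
  expect_false(miss$matched)
  expect_equal(miss$ppm, 10.1, tolerance = 0.05)
})

test_that("retention-time matching uses relative tolerance", {
  expect_true(match_rt(7.22, 7.22)$matched)
  near <- match_rt(7.40, 7.22)
  expect_true(near$matched)
  expect_equal(near$rel_dev, 0.18 / 7.22, tolerance = 1e-9)
  expect_false(match_rt(7.45, 7.22)$matched)
  expect_error(match_rt(7.22, 0), "must be > 0")
})

test_that("fragment matching counts tabulated fragments, consuming observations once", {
  expect_equal(match_fragments(c(208.0, 349.1), c(208.0, 349.1)), 2)
  expect_equal(match_fragments(numeric(0), c(208.0, 349.1)), 0)
  expect_equal(match_fragments(208.04, c(208.0, 349.1)), 1)
  expect_equal(match_fragments(208.06, c(208.0, 349.1)), 0)
  # a single observation cannot satisfy two tabulated fragments
  expect_equal(match_fragments(208.0, c(208.0, 208.0)), 1)
  expect_equal(match_fragments(c(208.0, 208.01), c(208.0, 208.0)), 2)
})

test_that("identification points follow the per-technique scheme", {
  expect_equal(identification_points(TRUE, TRUE, 2), 7.5)
  expect_equal(identification_points(TRUE, TRUE, 1), 5.0)
  expect_equal(identification_points(TRUE, FALSE, 0), 1.0)
  expect_equal(identification_points(FALSE, TRUE, 0), 1.5)
  expect_equal(identification_points(FALSE, FALSE, 0), 0)
  expect_error(identification_points(TRUE, TRUE, -1))
})

test_that("a noiseless STC-spiked run identifies every analyte at 7.5 points", {
  db <- panel_db()
  r <- gen_spiked_run(db, stc_levels(db), noise = zero_noise(), seed = 1)
  id <- identify_run(r, db)
  expect_true(all(id$identified))
  expect_true(all(id$points == 7.5))
  expect_true(all(abs(id$ppm) < 1e-9))
})

test_that("a clean blank yields zero identifications", {
  db <- panel_db()
  r <- gen_blank_run(db, noise = zero_noise(), seed = 1)
  id <- identify_run(r, db)
  expect_false(any(id$identified))
  expect_true(all(id$points == 0))
})

test_that("losing one product ion leaves 5.0 points, still above both thresholds", {
  db <- db_subset(panel_db(), c("Amoxicillin", "Lincomycin"))  # MRL / no MRL
  r <- gen_spiked_run(db, stc_levels(db), noise = zero_noise(), seed = 1)
  # drop the second fragment of each spike feature
  r$features$fragment_mzs[1:2] <-
    vapply(strsplit(r$features$fragment_mzs[1:2], ";"), `[`, "", 1)
  id <- identify_run(r, db)
  expect_equal(id$points, c(5, 5))
  expect_equal(id$required_points, c(4, 5))
  expect_true(all(id$identified))
  # losing both fragments drops below both thresholds
  r$features$fragment_mzs[1:2] <- ""
  id2 <- identify_run(r, db)
  expect_equal(id2$points, c(2.5, 2.5))
  expect_false(any(id2$identified))
})

test_that("isobaric epimers resolve to their own retention-time windows", {
  db <- db_subset(panel_db(), c("Tetracycline", "Epi-Tetracycline",
                                "Doxycycline", "Epi-Doxycycline"))
  r <- gen_spiked_run(db, stc_levels(db), noise = zero_noise(), seed = 1)
  id <- identify_run(r, db)
  expect_true(all(id$identified))
  expect_equal(id$feature_rt, db$compounds$rt_min, tolerance = 1e-9)
})

test_that("identify_run matches a brute-force all-pairs matcher on small instances", {
  db <- db_subset(panel_db(), c("Amoxicillin", "Tetracycline", "Sulfadiazine",
                                "Enrofloxacin", "Tylosin"))
  for (s in 1:10) {
    r <- gen_spiked_run(db, stc_levels(db) * (s %% 3), seed = 100 + s)
    id <- identify_run(r, db)
    bf <- brute_identify(r$features, db)
    expect_equal(as.logical(bf[, "identified"]), id$identified,
                 info = sprintf("seed %d", s))
    expect_equal(unname(bf[, "points"]), id$points,
                 info = sprintf("seed %d", s))
  }
})

test_that("widening tolerances never shrinks the identified set", {
  # interference-free runs: with background features, a wider m/z window can
  # admit a closer fragment-less interferent and change the candidate choice
  db <- panel_db()
  noise <- noise_model(blank_feature_rate = 0)
  for (s in 1:5) {
    r <- gen_spiked_run(db, stc_levels(db), noise = noise, seed = 200 + s)
    narrow <- identify_run(r, db, run_config(ppm_tol = 2, rt_tol_frac = 0.01,
                                             frag_tol = 0.02))
    wide <- identify_run(r, db, run_config(ppm_tol = 5, rt_tol_frac = 0.025,
                                           frag_tol = 0.05))
    expect_true(all(wide$identified[narrow$identified]))
    expect_true(all(wide$points >= narrow$points))
  }
})
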