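# Shared fixtures: the packaged panel, small sub-panels, and a noiseless
# noise model for exact-contract tests.

panel_db <- function() load_compound_db()

small_db <- function(names = c("Amoxicillin", "Tetracycline", "Lincomycin")) {
  db_subset(load_compound_db(), names)
}

# Every stochastic component switched off: spikes land exactly on theoretical
# m/z, expected RT, nominal response; no background features.
zero_noise <- function(...) {
  noise_model(mass_error_ppm_sd = 0, rt_jitter_sd = 0,
              response_cv = c(none = 0), default_cv = 0,
              blank_feature_rate = 0, frag_mz_sd = 0,
              calibration_cv = 0, is_cv = 0, ...)
}

stc_levels <- function(db) {
  stats::setNames(db$compounds$stc_ug_kg, db$compounds$name)
}

# All-pairs brute-force matcher used as the independent oracle: scalar loops,
# explicit lexicographic preference (RT window first, then |ppm|, |RT dev|, m/z).
brute_identify <- function(features, db, config = run_config()) {
  lex_less <- function(a, b) {
    for (k in seq_along(a)) {
      if (a[k] < b[k]) return(TRUE)
      if (a[k] > b[k]) return(FALSE)
    }
    FALSE
  }
  cmp <- db$compounds
  out <- list()
  for (i in seq_len(nrow(cmp))) {
    best <- NULL
    for (j in seq_len(nrow(features))) {
      p <- ppm_error(features$mz[j], cmp$mz_theoretical[i])
      if (abs(p) > config$ppm_tol) next
      rel <- (features$rt_min[j] - cmp$rt_min[i]) / cmp$rt_min[i]
      key <- c(as.numeric(abs(rel) > config$rt_tol_frac), abs(p), abs(rel),
               features$mz[j])
      if (is.null(best) || lex_less(key, best$key))
        best <- list(j = j, key = key, ppm = p, rel = rel)
    }
    if (is.null(best)) {
      out[[i]] <- c(identified = FALSE, points = 0)
    } else {
      frags <- match_fragments(
        milkscreen:::split_fragments(features$fragment_mzs[best$j]),
        c(cmp$fragment1_mz[i], cmp$fragment2_mz[i]), config$frag_tol)
      rt_ok <- abs(best$rel) <= config$rt_tol_frac
      pts <- identification_points(rt_ok, TRUE, frags)
      req <- if (cmp$authorized[i]) config$ip_required_authorized else
        config$ip_required_unauthorized
      out[[i]] <- c(identified = rt_ok && pts >= req, points = pts)
    }
  }
  do.call(rbind, out)
}

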