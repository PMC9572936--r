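#' Instrument noise model for the synthetic-data generator
#'
#' Describes the statistical structure of generated feature tables: mass
#' error (normal in ppm, truncated at the matching tolerance so a true spike
#' can never be lost on tolerance grounds), retention-time jitter (relative,
#' truncated likewise), per-analyte response dispersion (normal, truncated at
#' `trunc_sd` standard deviations to keep responses positive), and a sparse
#' Poisson background of false features in blank matrix.
#'
#' @param mass_error_ppm_sd SD of the ppm mass error (default 1.5).
#' @param mass_error_ppm_max Truncation bound of the ppm error (default 5).
#' @param rt_jitter_sd SD of the relative RT jitter (default 0.008).
#' @param rt_jitter_max Truncation bound of the relative RT jitter (0.025).
#' @param response_cv Named numeric vector of fractional within-lab CVs per
#'   analyte; `NULL` (default) uses the packaged [cv_reference()] values.
#' @param default_cv Fractional CV for analytes absent from `response_cv`.
#' @param blank_feature_rate Expected false features per analyte window per
#'   blank run (Poisson rate, default 0.02).
#' @param blank_response_frac Mean false-feature response, as a fraction of
#'   the analyte's response at STC (exponential distribution, default 0.05).
#' @param frag_mz_sd,frag_mz_max SD / truncation (Th) of fragment m/z jitter.
#' @param trunc_sd Truncation, in SD units, of the response noise (default 4).
#' @param calibration_cv Fractional response CV of calibration standards
#'   (solvent standards are far less dispersed than milk extracts).
#' @param is_cv Fractional response CV of internal-standard features.
#' @param species_scale Named multiplicative response scale per species; all
#'   ones by default (the procedure applies identically to bovine, ovine and
#'   goat milk), available for ruggedness-style experiments.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(mass_error_ppm_sd = 1.5, mass_error_ppm_max = 5,
                        rt_jitter_sd = 0.008, rt_jitter_max = 0.025,
                        response_cv = NULL, default_cv = 0.05,
                        blank_feature_rate = 0.02, blank_response_frac = 0.05,
                        frag_mz_sd = 0.005, frag_mz_max = 0.02,
                        trunc_sd = 4, calibration_cv = 0.005, is_cv = 0.05,
                        species_scale = c(bovine = 1, ovine = 1, goat = 1)) {
  stopifnot(mass_error_ppm_sd >= 0, mass_error_ppm_max >= 0,
            rt_jitter_sd >= 0, rt_jitter_max >= 0,
            blank_feature_rate >= 0, blank_response_frac >= 0,
            trunc_sd > 0, calibration_cv >= 0, is_cv >= 0,
            default_cv >= 0)
  structure(
    list(mass_error_ppm_sd = mass_error_ppm_sd,
         mass_error_ppm_max = mass_error_ppm_max,
         rt_jitter_sd = rt_jitter_sd, rt_jitter_max = rt_jitter_max,
         response_cv = response_cv, default_cv = default_cv,
         blank_feature_rate = blank_feature_rate,
         blank_response_frac = blank_response_frac,
         frag_mz_sd = frag_mz_sd, frag_mz_max = frag_mz_max,
         trunc_sd = trunc_sd, calibration_cv = calibration_cv, is_cv = is_cv,
         species_scale = species_scale),
    class = "noise_model"
  )
}

# Fractional CV per analyte name under a noise model.
noise_cv <- function(noise, names) {
  cv <- rep(noise$default_cv, length(names))
  names(cv) <- names
  if (is.null(noise$response_cv)) {
    ref <- cv_reference()
    hit <- match(names, ref$name)
    cv[!is.na(hit)] <- ref$cv_r_pct[hit[!is.na(hit)]] / 100
  } else {
    hit <- match(names, names(noise$response_cv))
    cv[!is.na(hit)] <- noise$response_cv[hit[!is.na(hit)]]
  }
  cv
}

# Truncated normal draws by rejection; truncation bounds are absolute
# deviations from the mean, in the same units as sd.
rtrunc_norm <- function(n, mean = 0, sd = 1, max_dev = Inf) {
  if (n == 0) return(numeric(0))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(abs(x - mean) > max_dev)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), if (length(mean) > 1) mean[bad] else mean,
                           if (length(sd) > 1) sd[bad] else sd)
    bad <- bad[abs(x[bad] - (if (length(mean) > 1) mean[bad] else mean)) >
                 (if (length(max_dev) > 1) max_dev[bad] else max_dev)]
  }
  x
}

# Concentration readings for a spiked analyte: normal around the nominal
# level with the configured fractional CV, truncated at trunc_sd SDs so the
# reading stays positive. This single primitive is shared by the run
# generator and by the vectorized CV-recovery simulator, so both draw from
# the identical distribution.
draw_spike_concentrations <- function(level, cv, n, trunc_sd = 4) {
  if (cv == 0) return(rep(level, n))
  rtrunc_norm(n, mean = level, sd = cv * level, max_dev = trunc_sd * cv * level)
}

#' Ground-truth detector response parameters
#'
#' Draws a per-compound linear response model (slope in area units per µg/L
#' of vial concentration, small intercept) that plays the role of the
#' instrument's true response function: the same parameters generate both
#' calibration series and milk-run features, so back-calculation through a
#' fitted curve recovers the generated concentrations.
#'
#' @param db A `compound_db`.
#' @param seed Integer seed.
#' @param slope_meanlog,slope_sdlog Log-normal slope parameters.
#' @param intercept_sd_frac SD of the intercept as a fraction of the slope.
#' @return Data frame `name`, `slope`, `intercept` of class `response_params`.
#' @export
response_params <- function(db, seed = 1L, slope_meanlog = log(5000),
                            slope_sdlog = 0.3, intercept_sd_frac = 0.002) {
  stopifnot(inherits(db, "compound_db"))
  nm <- db$compounds$name
  withr::with_seed(seed, {
    slope <- stats::rlnorm(length(nm), slope_meanlog, slope_sdlog)
    intercept <- stats::rnorm(length(nm), 0, intercept_sd_frac * slope)
  })
  structure(data.frame(name = nm, slope = slope, intercept = intercept,
                       stringsAsFactors = FALSE),
            class = c("response_params", "data.frame"))
}

empty_features <- function() {
  data.frame(mz = numeric(0), rt_min = numeric(0), response = numeric(0),
             fragment_mzs = character(0), stringsAsFactors = FALSE)
}

new_run <- function(run_id, species, truth, features, seed, role = "sample") {
  structure(list(run_id = run_id, species = species, truth = truth,
                 features = features, seed = seed, role = role),
            class = "synthetic_run")
}

#' @export
print.synthetic_run <- function(x, ...) {
  cat(sprintf("<synthetic_run> %s (%s, %s): %d features, %d analytes spiked\n",
              x$run_id, x$species, x$role, nrow(x$features),
              sum(x$truth > 0)))
  invisible(x)
}

#' Generate a spiked (or blank) milk run
#'
#' Simulates the feature table of one milk sample: for every analyte spiked
#' at a positive level, one chromatographic feature with mass error, RT
#' jitter and response noise per the noise model, both tabulated fragments
#' present; plus rare Poisson false features in every analyte window and the
#' four internal-standard features (always present in milk runs).
#'
#' @param db A `compound_db`.
#' @param level Named numeric vector of true concentrations (µg/kg); names
#'   must be analytes of `db`. Analytes not named are at concentration 0.
#'   A single unnamed value spikes the whole panel at that level.
#' @param noise A [noise_model()].
#' @param resp A [response_params()] ground truth (default: seed-1 draw).
#' @param seed Integer seed; the run is a pure function of its arguments.
#' @param run_id,species Run metadata.
#' @param dilution A [dilution_model()] mapping sample µg/kg to vial µg/L.
#' @param include_is Add internal-standard features (TRUE for milk runs).
#' @return A `synthetic_run`.
#' @export
gen_spiked_run <- function(db, level, noise = noise_model(),
                           resp = response_params(db), seed = 1L,
                           run_id = sprintf("run-%d", seed),
                           species = "bovine",
                           dilution = dilution_model(), include_is = TRUE) {
  stopifnot(inherits(db, "compound_db"))
  cmp <- db$compounds
  lev <- rep(0, nrow(cmp))
  names(lev) <- cmp$name
  if (length(level) == 1 && is.null(names(level))) {
    lev[] <- level
  } else if (length(level) > 0) {
    unknown <- setdiff(names(level), cmp$name)
    if (length(unknown) > 0)
      stop(sprintf("compound(s) not in database: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    lev[names(level)] <- level
  }
  if (any(lev < 0)) stop("spike levels must be >= 0", call. = FALSE)

  ri <- match(cmp$name, resp$name)
  if (anyNA(ri)) stop("response parameters missing for some analytes",
                      call. = FALSE)
  slope <- resp$slope[ri]
  intercept <- resp$intercept[ri]
  cv <- noise_cv(noise, cmp$name)
  dfac <- dilution_factor(dilution)
  scale <- if (species %in% names(noise$species_scale))
    noise$species_scale[[species]] else 1

  withr::with_seed(seed, {
    feats <- list()
    spiked <- which(lev > 0)
    if (length(spiked) > 0) {
      conc <- vapply(spiked, function(i)
        draw_spike_concentrations(lev[i], cv[i], 1, noise$trunc_sd), numeric(1))
      vial <- conc / dfac
      response <- pmax(0, (slope[spiked] * vial + intercept[spiked]) * scale)
      dppm <- rtrunc_norm(length(spiked), 0, noise$mass_error_ppm_sd,
                          noise$mass_error_ppm_max)
      drt <- rtrunc_norm(length(spiked), 0, noise$rt_jitter_sd,
                         noise$rt_jitter_max)
      f1 <- cmp$fragment1_mz[spiked] +
        rtrunc_norm(length(spiked), 0, noise$frag_mz_sd, noise$frag_mz_max)
      f2 <- cmp$fragment2_mz[spiked] +
        rtrunc_norm(length(spiked), 0, noise$frag_mz_sd, noise$frag_mz_max)
      feats$spike <- data.frame(
        mz = cmp$mz_theoretical[spiked] * (1 + dppm * 1e-6),
        rt_min = cmp$rt_min[spiked] * (1 + drt),
        response = response,
        fragment_mzs = sprintf("%.4f;%.4f", f1, f2),
        stringsAsFactors = FALSE
      )
    }
    if (noise$blank_feature_rate > 0) {
      k <- stats::rpois(nrow(cmp), noise$blank_feature_rate)
      idx <- rep(seq_len(nrow(cmp)), k)
      if (length(idx) > 0) {
        half_ppm <- db$ppm_tol
        stc_vial <- cmp$stc_ug_kg[idx] / dfac
        mean_resp <- noise$blank_response_frac *
          pmax(1e-9, slope[idx] * stc_vial + intercept[idx])
        feats$false <- data.frame(
          mz = cmp$mz_theoretical[idx] *
            (1 + stats::runif(length(idx), -half_ppm, half_ppm) * 1e-6),
          rt_min = cmp$rt_min[idx] *
            (1 + stats::runif(length(idx), -db$rt_tol_frac, db$rt_tol_frac)),
          response = stats::rexp(length(idx), rate = 1 / mean_resp),
          fragment_mzs = rep("", length(idx)),
          stringsAsFactors = FALSE
        )
      }
    }
    if (include_is) {
      is_tab <- internal_standards()
      n_is <- nrow(is_tab)
      dppm <- rtrunc_norm(n_is, 0, noise$mass_error_ppm_sd,
                          noise$mass_error_ppm_max)
      drt <- rtrunc_norm(n_is, 0, noise$rt_jitter_sd, noise$rt_jitter_max)
      feats$is <- data.frame(
        mz = is_tab$mz_theoretical * (1 + dppm * 1e-6),
        rt_min = is_tab$rt_min * (1 + drt),
        response = pmax(0, 5000 * (1 + rtrunc_norm(n_is, 0, noise$is_cv,
                                                   noise$trunc_sd * noise$is_cv))),
        fragment_mzs = rep("", n_is),
        stringsAsFactors = FALSE
      )
    }
  })
  features <- if (length(feats) > 0) do.call(rbind, feats) else empty_features()
  rownames(features) <- NULL
  new_run(run_id, species, lev, features, seed)
}

#' Generate a blank milk run
#'
#' Equivalent to [gen_spiked_run()] with every analyte at concentration 0:
#' only rare Poisson false features and the internal standards appear.
#'
#' @inheritParams gen_spiked_run
#' @return A `synthetic_run`.
#' @export
gen_blank_run <- function(db, noise = noise_model(),
                          resp = response_params(db), seed = 1L,
                          run_id = sprintf("blank-%d", seed),
                          species = "bovine",
                          dilution = dilution_model(), include_is = TRUE) {
  gen_spiked_run(db, level = numeric(0), noise = noise, resp = resp,
                 seed = seed, run_id = run_id, species = species,
                 dilution = dilution, include_is = include_is)
}

#' Generate a calibration series
#'
#' Per-compound responses at the standard levels, `slope * level + intercept`
#' with small multiplicative noise (`calibration_cv`); the generating slope
#' and intercept are attached as ground truth.
#'
#' @inheritParams gen_spiked_run
#' @param levels Calibration levels in µg/L (default 0.1, 0.5, 1, 5, 10).
#' @return Data frame `name`, `level_ug_l`, `response` of class
#'   `calibration_series`, with attribute `truth` (the `response_params`).
#' @export
gen_calibration_series <- function(db, levels = c(0.1, 0.5, 1, 5, 10),
                                   noise = noise_model(),
                                   resp = response_params(db), seed = 1L) {
  stopifnot(inherits(db, "compound_db"), length(unique(levels)) >= 2)
  cmp <- db$compounds
  ri <- match(cmp$name, resp$name)
  out <- expand.grid(name = cmp$name, level_ug_l = levels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(match(out$name, cmp$name), out$level_ug_l), ]
  rownames(out) <- NULL
  slope <- resp$slope[ri][match(out$name, cmp$name)]
  intercept <- resp$intercept[ri][match(out$name, cmp$name)]
  nominal <- slope * out$level_ug_l + intercept
  withr::with_seed(seed, {
    eps <- rtrunc_norm(nrow(out), 0, noise$calibration_cv,
                       4 * noise$calibration_cv)
  })
  out$response <- pmax(0, nominal * (1 + eps))
  structure(out, truth = resp, class = c("calibration_series", "data.frame"))
}

#' Generate a complete validation study
#'
#' Paired blank and STC-spiked runs over the three milk species (default 10
#' sheep + 10 cow + 5 goat of each kind, i.e. 25 + 25 runs), plus a
#' calibration series drawn from the same ground-truth response parameters.
#' Run seeds are derived deterministically from the master seed.
#'
#' @inheritParams gen_spiked_run
#' @param n_sheep,n_cow,n_goat Replicates per species.
#' @param level Spike level: `NULL` (default) uses each analyte's STC; a
#'   named vector or single value overrides it.
#' @return Object of class `validation_study`: list with `blank_runs`,
#'   `spiked_runs`, `calibration`, `resp`, `seed`.
#' @export
gen_validation_study <- function(db, n_sheep = 10, n_cow = 10, n_goat = 5,
                                 level = NULL, noise = noise_model(),
                                 resp = NULL, seed = 1L,
                                 dilution = dilution_model()) {
  stopifnot(inherits(db, "compound_db"), n_sheep + n_cow + n_goat >= 2)
  n <- n_sheep + n_cow + n_goat
  species <- c(rep("ovine", n_sheep), rep("bovine", n_cow), rep("goat", n_goat))
  if (is.null(level)) {
    level <- db$compounds$stc_ug_kg
    names(level) <- db$compounds$name
  }
  sub <- withr::with_seed(seed,
                          sample.int(.Machine$integer.max, 2 * n + 1))
  if (is.null(resp)) resp <- response_params(db, seed = sub[2 * n + 1])
  blank_runs <- lapply(seq_len(n), function(i)
    gen_blank_run(db, noise = noise, resp = resp, seed = sub[i],
                  run_id = sprintf("blank-%02d", i), species = species[i],
                  dilution = dilution))
  spiked_runs <- lapply(seq_len(n), function(i)
    gen_spiked_run(db, level = level, noise = noise, resp = resp,
                   seed = sub[n + i], run_id = sprintf("spiked-%02d", i),
                   species = species[i], dilution = dilution))
  calibration <- gen_calibration_series(db, noise = noise, resp = resp,
                                        seed = sub[2 * n + 1])
  structure(list(blank_runs = blank_runs, spiked_runs = spiked_runs,
                 calibration = calibration, resp = resp, seed = seed),
            class = "validation_study")
}

#' @export
print.validation_study <- function(x, ...) {
  cat(sprintf("<validation_study> %d blank + %d spiked runs, seed %d\n",
              length(x$blank_runs), length(x$spiked_runs), x$seed))
  invisible(x)
}

#' Generate an ordered analytical batch
#'
#' Reproduces the routine injection sequence: solvent blank, the five
#' calibration standards, solvent blank, negative control (blank milk),
#' screen positive control (milk spiked at STC), solvent blank, the unknown
#' samples, and a final solvent blank.
#'
#' @inheritParams gen_spiked_run
#' @param n_unknowns Number of unknown milk samples.
#' @param contamination List of named concentration vectors (µg/kg), one per
#'   unknown; `NULL` entries (or a `NULL` list) mean uncontaminated.
#' @param levels Calibration levels in µg/L.
#' @return Object of class `analysis_batch`: list with `calibration`,
#'   `runs` (each tagged with a `role`), `manifest` (data frame of the
#'   injection order), `resp`, `seed`.
#' @export
gen_batch <- function(db, n_unknowns = 0, contamination = NULL,
                      noise = noise_model(), resp = NULL, seed = 1L,
                      levels = c(0.1, 0.5, 1, 5, 10),
                      dilution = dilution_model()) {
  stopifnot(inherits(db, "compound_db"), n_unknowns >= 0)
  if (!is.null(contamination) && length(contamination) != n_unknowns)
    stop("contamination must have one entry per unknown", call. = FALSE)
  sub <- withr::with_seed(seed,
                          sample.int(.Machine$integer.max, n_unknowns + 4))
  if (is.null(resp)) resp <- response_params(db, seed = sub[1])
  stc <- db$compounds$stc_ug_kg
  names(stc) <- db$compounds$name

  calibration <- gen_calibration_series(db, levels = levels, noise = noise,
                                        resp = resp, seed = sub[2])
  runs <- list()
  runs$negative_control <- gen_blank_run(
    db, noise = noise, resp = resp, seed = sub[3],
    run_id = "negative-control", dilution = dilution)
  runs$negative_control$role <- "negative_control"
  runs$positive_control <- gen_spiked_run(
    db, level = stc, noise = noise, resp = resp, seed = sub[4],
    run_id = "positive-control", dilution = dilution)
  runs$positive_control$role <- "positive_control"
  for (k in seq_len(n_unknowns)) {
    lv <- contamination[[k]] %||% numeric(0)
    r <- gen_spiked_run(db, level = lv, noise = noise, resp = resp,
                        seed = sub[4 + k],
                        run_id = sprintf("unknown-%02d", k),
                        dilution = dilution)
    r$role <- "unknown"
    runs[[sprintf("unknown_%02d", k)]] <- r
  }

  solvent <- function(i) sprintf("solvent-blank-%d", i)
  manifest <- data.frame(
    position = seq_len(length(levels) + n_unknowns + 6),
    run_id = c(solvent(1), sprintf("cal-%d", seq_along(levels)), solvent(2),
               "negative-control", "positive-control", solvent(3),
               sprintf("unknown-%02d", seq_len(n_unknowns)), solvent(4)),
    role = c("solvent_blank", rep("calibration", length(levels)),
             "solvent_blank", "negative_control", "positive_control",
             "solvent_blank", rep("unknown", n_unknowns), "solvent_blank"),
    stringsAsFactors = FALSE
  )
  structure(list(calibration = calibration, runs = runs, manifest = manifest,
                 resp = resp, seed = seed),
            class = "analysis_batch")
}

#' @export
print.analysis_batch <- function(x, ...) {
  cat(sprintf("<analysis_batch> %d injections (%d unknowns), seed %d\n",
              nrow(x$manifest), sum(x$manifest$role == "unknown"), x$seed))
  invisible(x)
}

#' Simulate within-laboratory CV recovery
#'
#' For each analyte, generates many independent validation-style sets of
#' spiked concentration readings at STC (the same truncated-normal primitive
#' the run generator uses), computes each set's percent CV, and averages
#' across sets. Used to check that the generator's dispersion is recovered
#' at the n = 25 replicate scale.
#'
#' @param db A `compound_db`.
#' @param n_studies Number of independent simulated studies (default 200).
#' @param n_reps Spiked replicates per study (default 25).
#' @param noise A [noise_model()] supplying the per-analyte true CV.
#' @param seed Integer seed.
#' @return Data frame `name`, `true_cv_pct`, `mean_recovered_cv_pct`.
#' @export
estimate_cv_recovery <- function(db, n_studies = 200, n_reps = 25,
                                 noise = noise_model(), seed = 1L) {
  stopifnot(inherits(db, "compound_db"), n_studies >= 2, n_reps >= 2)
  cmp <- db$compounds
  cv <- noise_cv(noise, cmp$name)
  out <- data.frame(name = cmp$name, true_cv_pct = 100 * cv,
                    mean_recovered_cv_pct = NA_real_,
                    stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    for (i in seq_len(nrow(cmp))) {
      x <- draw_spike_concentrations(cmp$stc_ug_kg[i], cv[i],
                                     n_studies * n_reps, noise$trunc_sd)
      m <- matrix(x, nrow = n_reps)
      cvs <- 100 * apply(m, 2, stats::sd) / colMeans(m)
      out$mean_recovered_cv_pct[i] <- mean(cvs)
    }
  })
  out
}
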