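#' Fixed dilution model of the extraction procedure
#'
#' Maps a concentration in the vial (µg/L) to the concentration in the milk
#' sample (µg/kg): 1.0 g of milk is extracted into 4.1 mL (4.0 mL acidified
#' acetonitrile + 0.1 mL EDTA solution) and a 100 µL aliquot of the purified
#' extract is diluted tenfold before injection, so
#' sample µg/kg = vial µg/L x (4.1 / 1.0) x 10 = vial x 41. This places the
#' STC levels of the panel (4-75 µg/kg) at 0.098-1.83 µg/L, inside the
#' 0.1-10 µg/L calibration range.
#'
#' @param sample_g Sample mass (g).
#' @param extract_ml Extract volume (mL).
#' @param dilution_factor Aliquot dilution factor.
#' @return Object of class `dilution_model`.
#' @export
dilution_model <- function(sample_g = 1.0, extract_ml = 4.1,
                           dilution_factor = 10) {
  stopifnot(sample_g > 0, extract_ml > 0, dilution_factor > 0)
  structure(list(sample_g = sample_g, extract_ml = extract_ml,
                 dilution_factor = dilution_factor),
            class = "dilution_model")
}

#' Overall vial-to-sample conversion factor
#'
#' @param dilution A [dilution_model()].
#' @return Multiplier taking vial µg/L to sample µg/kg (41 by default).
#' @export
dilution_factor <- function(dilution = dilution_model()) {
  dilution$extract_ml / dilution$sample_g * dilution$dilution_factor
}

#' Fit a calibration curve
#'
#' Unweighted ordinary least-squares line through the calibration points.
#'
#' @param levels Concentrations (µg/L), at least two distinct values.
#' @param responses Instrument responses, same length.
#' @param name Optional analyte name carried in the result.
#' @return Object of class `calibration_curve`: list with `name`, `levels`,
#'   `responses`, `slope`, `intercept`, `r_squared`.
#' @examples
#' fit_calibration(c(0.1, 0.5, 1, 5, 10), 2 * c(0.1, 0.5, 1, 5, 10) + 1)
#' @export
fit_calibration <- function(levels, responses, name = NA_character_) {
  if (length(levels) != length(responses) || length(levels) < 2)
    stop("levels and responses must have equal length >= 2", call. = FALSE)
  if (length(unique(levels)) < 2)
    stop("degenerate design: all calibration levels identical", call. = FALSE)
  fit <- stats::lm(responses ~ levels)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((responses - mean(responses))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(name = name, levels = levels, responses = responses,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: slope %.4g, intercept %.4g, R2 %.6f\n",
              x$name, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Fit one calibration curve per analyte from a calibration series
#'
#' @param series A `calibration_series` data frame (`name`, `level_ug_l`,
#'   `response`).
#' @return Named list of `calibration_curve` objects.
#' @export
fit_calibration_series <- function(series) {
  stopifnot(all(c("name", "level_ug_l", "response") %in% names(series)))
  nm <- unique(series$name)
  curves <- lapply(nm, function(n) {
    s <- series[series$name == n, ]
    fit_calibration(s$level_ug_l, s$response, name = n)
  })
  names(curves) <- nm
  curves
}

#' Back-calculate a sample concentration from a response
#'
#' Inverts the calibration line to a vial concentration (negative values
#' clamp to zero: readings below the calibration range are reported as not
#' detected, not as negative amounts) and scales it to the milk sample by
#' the dilution model.
#'
#' @param curve A `calibration_curve`.
#' @param response Instrument response (vectorized).
#' @param dilution A [dilution_model()].
#' @return Sample concentration in µg/kg.
#' @export
back_calculate <- function(curve, response, dilution = dilution_model()) {
  if (curve$slope == 0) stop("calibration slope is zero", call. = FALSE)
  vial <- pmax(0, (response - curve$intercept) / curve$slope)
  vial * dilution_factor(dilution)
}

#' Measured concentration of every analyte in a run
#'
#' For each analyte, back-calculates the response of the best feature in its
#' precursor m/z window whose retention time also matches; analytes without
#' such a feature read 0 µg/kg. This mirrors reading an extracted-ion
#' chromatogram at the analyte's retention-time region, and is used both for
#' blank readings in validation and for screening quantification.
#'
#' @param run Run or feature table (see [identify_run()]).
#' @param db A `compound_db`.
#' @param curves Named list of `calibration_curve`s covering the analytes.
#' @param dilution A [dilution_model()].
#' @param config A [run_config()].
#' @return Named numeric vector of concentrations (µg/kg) per analyte.
#' @export
measure_concentration <- function(run, db, curves,
                                  dilution = dilution_model(),
                                  config = run_config()) {
  id <- identify_run(run, db, config)
  conc <- numeric(nrow(id))
  names(conc) <- id$name
  hit <- which(id$precursor_matched & id$rt_matched)
  for (i in hit) {
    cv <- curves[[id$name[i]]]
    if (is.null(cv))
      stop(sprintf("no calibration curve for '%s'", id$name[i]), call. = FALSE)
    conc[i] <- back_calculate(cv, id$response[i], dilution)
  }
  conc
}

#' Screen one sample against per-analyte cut-off concentrations
#'
#' Runs identification, back-calculates concentrations, and issues one
#' verdict per analyte: `"suspect"` when the analyte is identified and its
#' concentration strictly exceeds the cut-off factor Fm, `"compliant"`
#' otherwise. A concentration exactly at the cut-off remains compliant.
#'
#' @param run Run or feature table.
#' @param db A `compound_db`.
#' @param curves Named list of `calibration_curve`s.
#' @param cutoffs Named numeric vector of cut-off factors Fm (µg/kg).
#' @param dilution A [dilution_model()].
#' @param config A [run_config()].
#' @return Data frame of class `screening_report`, one row per analyte:
#'   identification fields plus `conc_ug_kg`, `cutoff_ug_kg`, `verdict`.
#' @export
screen_sample <- function(run, db, curves, cutoffs,
                          dilution = dilution_model(),
                          config = run_config()) {
  id <- identify_run(run, db, config)
  conc <- rep(0, nrow(id))
  fm <- rep(NA_real_, nrow(id))
  verdict <- rep("compliant", nrow(id))
  for (i in seq_len(nrow(id))) {
    nm <- id$name[i]
    if (id$precursor_matched[i] && id$rt_matched[i]) {
      cv <- curves[[nm]]
      if (is.null(cv))
        stop(sprintf("no calibration curve for identified compound '%s'", nm),
             call. = FALSE)
      conc[i] <- back_calculate(cv, id$response[i], dilution)
    }
    if (id$identified[i]) {
      if (!nm %in% names(cutoffs))
        stop(sprintf("no cut-off configured for identified compound '%s'", nm),
             call. = FALSE)
      fm[i] <- cutoffs[[nm]]
      if (conc[i] > fm[i]) verdict[i] <- "suspect"
    }
  }
  id$conc_ug_kg <- conc
  id$cutoff_ug_kg <- fm
  id$verdict <- verdict
  structure(id, class = c("screening_report", "data.frame"))
}

#' Sample-level verdict from per-analyte screening decisions
#'
#' A sample is suspect (must be sent to confirmation) when any analyte in it
#' screens suspect.
#'
#' @param decisions A `screening_report`.
#' @return `"suspect"` or `"compliant"`.
#' @export
sample_verdict <- function(decisions) {
  if (any(decisions$verdict == "suspect")) "suspect" else "compliant"
}

#' Nominal cut-off concentrations from reference dispersion
#'
#' Builds a per-analyte cut-off table `Fm = STC * (1 - z * CV)` from the
#' packaged within-laboratory CVs; a convenience for screening batches when
#' no in-house validation study has been run.
#'
#' @param db A `compound_db`.
#' @param z Quantile factor (default 1.64).
#' @return Named numeric vector of Fm values (µg/kg).
#' @export
default_cutoffs <- function(db, z = 1.64) {
  stopifnot(inherits(db, "compound_db"))
  cv <- noise_cv(noise_model(), db$compounds$name)
  fm <- db$compounds$stc_ug_kg * (1 - z * cv)
  names(fm) <- db$compounds$name
  fm
}

#' Batch quality control
#'
#' Checks the control samples of an analytical batch: the negative control
#' (blank milk) must screen compliant, the screen positive control (milk
#' spiked at STC) must screen suspect, and all four internal standards must
#' be present in both control runs within the mass and retention-time
#' tolerances. Calibration curves failing the R-squared minimum are
#' reported as unusable.
#'
#' @param batch An `analysis_batch`.
#' @param db A `compound_db`.
#' @param curves Named list of `calibration_curve`s (default: fit from the
#'   batch's own calibration series).
#' @param cutoffs Named numeric Fm vector (default: [default_cutoffs()]).
#' @param dilution A [dilution_model()].
#' @param config A [run_config()].
#' @return List of class `batch_qc_report`: `negative_verdict`,
#'   `positive_verdict`, `is_checks` (data frame), `unusable_curves`,
#'   `pass`, `failures` (character reasons).
#' @export
qc_batch <- function(batch, db, curves = NULL, cutoffs = default_cutoffs(db),
                     dilution = dilution_model(), config = run_config()) {
  stopifnot(inherits(batch, "analysis_batch"))
  if (is.null(batch$runs$negative_control) || is.null(batch$runs$positive_control))
    stop("batch is missing its control samples", call. = FALSE)
  if (is.null(curves)) curves <- fit_calibration_series(batch$calibration)

  failures <- character(0)
  unusable <- names(curves)[vapply(curves, function(cv)
    cv$r_squared < config$r2_min, logical(1))]
  if (length(unusable) > 0)
    failures <- c(failures, sprintf("calibration R2 below %.3f: %s",
                                    config$r2_min,
                                    paste(unusable, collapse = ", ")))

  neg <- screen_sample(batch$runs$negative_control, db, curves, cutoffs,
                       dilution, config)
  pos <- screen_sample(batch$runs$positive_control, db, curves, cutoffs,
                       dilution, config)
  negative_verdict <- sample_verdict(neg)
  positive_verdict <- sample_verdict(pos)
  if (negative_verdict != "compliant")
    failures <- c(failures, "negative control not compliant")
  if (positive_verdict != "suspect")
    failures <- c(failures, "positive control not suspect")

  is_tab <- internal_standards()
  checks <- list()
  for (role in c("negative_control", "positive_control")) {
    feats <- batch$runs[[role]]$features
    for (i in seq_len(nrow(is_tab))) {
      ppm <- if (nrow(feats) > 0)
        ppm_error(feats$mz, is_tab$mz_theoretical[i]) else numeric(0)
      cand <- which(abs(ppm) <= config$ppm_tol)
      present <- FALSE
      rt_dev <- NA_real_
      if (length(cand) > 0) {
        rel <- (feats$rt_min[cand] - is_tab$rt_min[i]) / is_tab$rt_min[i]
        best <- cand[which.min(abs(rel))]
        rt_dev <- (feats$rt_min[best] - is_tab$rt_min[i]) / is_tab$rt_min[i]
        present <- abs(rt_dev) <= config$rt_tol_frac
      }
      checks[[length(checks) + 1L]] <- data.frame(
        run = role, standard = is_tab$name[i], present = present,
        rt_rel_dev = rt_dev, stringsAsFactors = FALSE)
      if (!present)
        failures <- c(failures,
                      sprintf("internal standard %s missing or RT-drifted in %s",
                              is_tab$name[i], role))
    }
  }
  is_checks <- do.call(rbind, checks)
  structure(
    list(negative_verdict = negative_verdict,
         positive_verdict = positive_verdict,
         is_checks = is_checks, unusable_curves = unusable,
         pass = length(failures) == 0, failures = failures,
         negative_report = neg, positive_report = pos),
    class = "batch_qc_report"
  )
}

#' @export
print.batch_qc_report <- function(x, ...) {
  cat(sprintf("<batch_qc_report> %s\n", if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  negative control: %s; positive control: %s; IS present: %d/%d\n",
              x$negative_verdict, x$positive_verdict,
              sum(x$is_checks$present), nrow(x$is_checks)))
  for (f in x$failures) cat("  -", f, "\n")
  invisible(x)
}
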