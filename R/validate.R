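#' Threshold value T from blank readings
#'
#' `T = B + z * SB`, where B and SB are the mean and sample (n-1) standard
#' deviation of the blank concentration readings at the analyte's retention
#' time: the minimum concentration above which a sample is considered
#' positive.
#'
#' @param blanks Numeric vector of blank concentration readings (µg/kg),
#'   n >= 2.
#' @param z Quantile factor (default 1.64, as printed in the screening
#'   validation guidance).
#' @return Threshold value T (µg/kg).
#' @examples
#' threshold_value(c(1, 2, 3)) # 2 + 1.64 * 1 = 3.64
#' @export
threshold_value <- function(blanks, z = 1.64) {
  if (length(blanks) < 2)
    stop("at least 2 blank replicates are required", call. = FALSE)
  mean(blanks) + z * stats::sd(blanks)
}

#' Cut-off factor Fm from STC-spiked readings
#'
#' `Fm = M - z * SD`, the concentration above which 95% of samples fortified
#' at the screening target concentration fall; a sample reading above Fm is
#' screen-positive.
#'
#' @param spikes Numeric vector of spiked concentration readings (µg/kg),
#'   n >= 2.
#' @param z Quantile factor (default 1.64).
#' @return Cut-off factor Fm (µg/kg). A negative Fm (dispersion larger than
#'   `M/z`) is returned with a warning.
#' @examples
#' cutoff_factor(c(48, 50, 52)) # 50 - 1.64 * 2 = 46.72
#' @export
cutoff_factor <- function(spikes, z = 1.64) {
  if (length(spikes) < 2)
    stop("at least 2 spiked replicates are required", call. = FALSE)
  fm <- mean(spikes) - z * stats::sd(spikes)
  if (fm < 0)
    warning("cut-off factor is negative: spike dispersion exceeds mean/z")
  fm
}

#' Detection-capability verdict from T and Fm
#'
#' `Fm > T` (strict) is the optimal condition: the false-negative rate at
#' STC is below 5% and the detection capability is at or below the STC.
#' Otherwise the detection capability exceeds the STC and new experiments at
#' a higher level are needed; no numeric re-determination is attempted.
#'
#' @param t_value Threshold value T (µg/kg).
#' @param fm Cut-off factor Fm (µg/kg).
#' @param stc Screening target concentration (µg/kg).
#' @return List with `pass` (logical, `Fm > T`), `ccbeta_le_stc`, `message`.
#' @export
assess_ccbeta <- function(t_value, fm, stc) {
  stopifnot(is.finite(t_value), is.finite(fm))
  pass <- fm > t_value
  list(
    pass = pass,
    ccbeta_le_stc = pass,
    message = if (pass)
      sprintf("detection capability <= STC (%g ug/kg)", stc)
    else
      "detection capability > STC; new experiments required at a higher level"
  )
}

#' Within-laboratory reproducibility CV
#'
#' @param spikes Numeric vector of spiked concentration readings; the mean
#'   must be positive.
#' @return CV in percent, `100 * SD / M` with the sample (n-1) SD.
#' @export
cv_within_lab <- function(spikes) {
  m <- mean(spikes)
  if (!is.finite(m) || m <= 0)
    stop("mean spiked concentration must be > 0", call. = FALSE)
  100 * stats::sd(spikes) / m
}

#' Horwitz precision function
#'
#' Empirical interlaboratory CV expected at a mass fraction C:
#' `CV(%) = 2^(1 - 0.5 * log10(C))`.
#'
#' @param mass_fraction Dimensionless mass fraction (e.g. 1e-7 for
#'   100 µg/kg), > 0.
#' @return Expected CV in percent.
#' @examples
#' horwitz_cv(1e-7) # 22.63% at 100 ug/kg
#' @export
horwitz_cv <- function(mass_fraction) {
  if (any(mass_fraction <= 0))
    stop("mass fraction must be > 0", call. = FALSE)
  2^(1 - 0.5 * log10(mass_fraction))
}

#' Maximum allowed within-laboratory CV at a screening level
#'
#' Regulation guide values: 30% below 10 µg/kg, 25% from 10 µg/kg up to (but
#' not including) 120 µg/kg; above that the Horwitz value applies. The guide
#' values are applied exactly as printed even where the Horwitz function
#' evaluated at the same mass fraction differs.
#'
#' @param stc Screening target concentration in µg/kg, > 0.
#' @return CV limit in percent.
#' @examples
#' max_allowed_cv(4)  # 30
#' max_allowed_cv(50) # 25
#' @export
max_allowed_cv <- function(stc) {
  stopifnot(all(stc > 0))
  ifelse(stc < 10, 30,
         ifelse(stc < 120, 25, horwitz_cv(stc * 1e-9)))
}

#' Specificity check on blank runs
#'
#' Counts, per analyte, the blank runs containing at least one feature
#' inside its precursor m/z x retention-time window (signal interference in
#' the retention-time region of the target analyte). Specificity passes for
#' an analyte when no blank run shows interference.
#'
#' @param blank_runs List of runs or feature tables.
#' @param db A `compound_db`.
#' @param config A [run_config()].
#' @return Data frame `name`, `interference_runs`, `pass`.
#' @export
specificity_check <- function(blank_runs, db, config = run_config()) {
  stopifnot(length(blank_runs) >= 1, inherits(db, "compound_db"))
  cmp <- db$compounds
  counts <- integer(nrow(cmp))
  for (run in blank_runs) {
    feats <- if (is.data.frame(run)) run else run$features
    if (nrow(feats) == 0) next
    for (i in seq_len(nrow(cmp))) {
      ppm_ok <- abs(ppm_error(feats$mz, cmp$mz_theoretical[i])) <= config$ppm_tol
      rt_ok <- abs(feats$rt_min - cmp$rt_min[i]) / cmp$rt_min[i] <= config$rt_tol_frac
      if (any(ppm_ok & rt_ok)) counts[i] <- counts[i] + 1L
    }
  }
  data.frame(name = cmp$name, interference_runs = counts,
             pass = counts == 0L, stringsAsFactors = FALSE)
}

#' Calibration stability assessment
#'
#' Tracks a time-ordered sequence of calibration fits for one analyte:
#' linearity (`R^2 >= r2_min`) and constancy of the intercept/slope ratio
#' (y/x), whose relative change from the first curve's ratio must stay
#' within `yx_tol`. The first curve serves as the reference.
#'
#' @param curves List of `calibration_curve`s in time order, length >= 1.
#' @param r2_min Minimum R-squared (default 0.999).
#' @param yx_tol Tolerated relative y/x drift (default 0.20).
#' @return Data frame of class `stability_record`: `index`, `r_squared`,
#'   `yx_ratio`, `yx_rel_change`, `linearity_pass`, `yx_pass`, `pass`.
#' @export
stability_assess <- function(curves, r2_min = 0.999, yx_tol = 0.20) {
  stopifnot(length(curves) >= 1)
  if (any(vapply(curves, function(cv) cv$slope == 0, logical(1))))
    stop("calibration slope is zero", call. = FALSE)
  yx <- vapply(curves, function(cv) cv$intercept / cv$slope, numeric(1))
  r2 <- vapply(curves, function(cv) cv$r_squared, numeric(1))
  ref <- yx[1]
  rel <- if (ref == 0) ifelse(yx == 0, 0, Inf) else (yx - ref) / ref
  out <- data.frame(
    index = seq_along(curves), r_squared = r2, yx_ratio = yx,
    yx_rel_change = rel,
    linearity_pass = r2 >= r2_min,
    yx_pass = abs(rel) <= yx_tol
  )
  out$pass <- out$linearity_pass & out$yx_pass
  structure(out, reference_yx = ref, class = c("stability_record", "data.frame"))
}

#' Ruggedness two-level t-test
#'
#' Compares concentration readings obtained at the two discrete levels (f
#' and F) of a procedural factor with a two-sided two-sample t-test (Welch
#' by default). The factor is significant — i.e. the method is not rugged
#' against it — when p < alpha.
#'
#' @param level_f,level_F Numeric reading vectors, n >= 2 each.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @param factor_name Optional label carried in the result.
#' @return List of class `ruggedness_test`: `factor_name`, `t`, `p_value`,
#'   `significant`, `alpha`.
#' @export
ruggedness_ttest <- function(level_f, level_F, alpha = 0.05,
                             var_equal = FALSE, factor_name = NA_character_) {
  stopifnot(length(level_f) >= 2, length(level_F) >= 2, alpha > 0, alpha < 1)
  s_f <- stats::sd(level_f)
  s_F <- stats::sd(level_F)
  if ((s_f == 0 && length(level_f) < 3) || (s_F == 0 && length(level_F) < 3))
    warning("a group has zero variance with fewer than 3 replicates")
  if (s_f == 0 && s_F == 0) {
    # t.test rejects constant data; the comparison is still well defined
    equal <- isTRUE(all.equal(mean(level_f), mean(level_F)))
    t_stat <- if (equal) 0 else sign(mean(level_f) - mean(level_F)) * Inf
    p <- if (equal) 1 else 0
  } else {
    ht <- stats::t.test(level_f, level_F, var.equal = var_equal)
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(list(factor_name = factor_name, t = t_stat, p_value = p,
                 significant = p < alpha, alpha = alpha),
            class = "ruggedness_test")
}

#' @export
print.ruggedness_test <- function(x, ...) {
  cat(sprintf("<ruggedness_test> %s: t = %.3f, p = %.4g (%ssignificant at %.2g)\n",
              x$factor_name, x$t, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Run the full screening validation on a study
#'
#' For every analyte: back-calculates the blank and spiked concentration
#' readings of the study through the calibration curves, forms the blank
#' statistics (B, SB) and spike statistics (M, SD, CV), computes the
#' threshold value T and cut-off factor Fm, issues the detection-capability
#' verdict (`Fm > T`), and compares the within-laboratory CV with its guide
#' limit.
#'
#' @param study A `validation_study`.
#' @param db The `compound_db` the study was generated from.
#' @param curves Named list of `calibration_curve`s (default: fit from the
#'   study's own calibration series).
#' @param dilution A [dilution_model()].
#' @param config A [run_config()].
#' @return Data frame of class `validation_report`, one row per analyte:
#'   `name`, `stc_ug_kg`, `blank_mean`, `blank_sd`, `t_value`, `spike_mean`,
#'   `spike_sd`, `fm`, `ccbeta_pass`, `cv_r_pct`, `cv_limit_pct`,
#'   `precision_pass`; attribute `all_pass`.
#' @export
run_validation <- function(study, db, curves = NULL,
                           dilution = dilution_model(),
                           config = run_config()) {
  stopifnot(inherits(study, "validation_study"),
            length(study$blank_runs) >= 2, length(study$spiked_runs) >= 2)
  if (is.null(curves)) curves <- fit_calibration_series(study$calibration)
  missing <- setdiff(db$compounds$name, names(curves))
  if (length(missing) > 0)
    stop(sprintf("no calibration curve for: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)

  blank_mat <- matrix(vapply(study$blank_runs, measure_concentration,
                             numeric(nrow(db$compounds)),
                             db = db, curves = curves, dilution = dilution,
                             config = config),
                      nrow = nrow(db$compounds))
  spike_mat <- matrix(vapply(study$spiked_runs, measure_concentration,
                             numeric(nrow(db$compounds)),
                             db = db, curves = curves, dilution = dilution,
                             config = config),
                      nrow = nrow(db$compounds))
  cmp <- db$compounds
  n <- nrow(cmp)
  out <- data.frame(
    name = cmp$name, stc_ug_kg = cmp$stc_ug_kg,
    blank_mean = NA_real_, blank_sd = NA_real_, t_value = NA_real_,
    spike_mean = NA_real_, spike_sd = NA_real_, fm = NA_real_,
    ccbeta_pass = NA, cv_r_pct = NA_real_, cv_limit_pct = NA_real_,
    precision_pass = NA, stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    blanks <- blank_mat[i, ]
    spikes <- spike_mat[i, ]
    out$blank_mean[i] <- mean(blanks)
    out$blank_sd[i] <- stats::sd(blanks)
    out$t_value[i] <- threshold_value(blanks, z = config$z)
    out$spike_mean[i] <- mean(spikes)
    out$spike_sd[i] <- stats::sd(spikes)
    out$fm[i] <- suppressWarnings(cutoff_factor(spikes, z = config$z))
    out$ccbeta_pass[i] <- assess_ccbeta(out$t_value[i], out$fm[i],
                                        cmp$stc_ug_kg[i])$pass
    out$cv_r_pct[i] <- if (mean(spikes) > 0) cv_within_lab(spikes) else NA_real_
    out$cv_limit_pct[i] <- max_allowed_cv(cmp$stc_ug_kg[i])
    out$precision_pass[i] <- !is.na(out$cv_r_pct[i]) &&
      out$cv_r_pct[i] <= out$cv_limit_pct[i]
  }
  structure(out,
            all_pass = all(out$ccbeta_pass & out$precision_pass),
            config_hash = config_hash(config), seed = study$seed,
            class = c("validation_report", "data.frame"))
}
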