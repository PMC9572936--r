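#' Pipeline configuration
#'
#' One auditable place for every regulation-driven constant: matching
#' tolerances, identification-point thresholds, the 1.64 quantile factor of
#' the threshold-value / cut-off-factor formulas, calibration acceptance
#' limits, and the dilution and noise models.
#'
#' @param ppm_tol Mass-accuracy tolerance for precursor matching (ppm).
#' @param rt_tol_frac Relative retention-time tolerance (fraction).
#' @param frag_tol Fragment m/z match tolerance (Th, absolute).
#' @param min_fragments Minimum matching fragments for full detection.
#' @param ip_required_authorized,ip_required_unauthorized Identification
#'   points required for substances with / without an MRL.
#' @param z Quantile factor in `T = B + z*SB` and `Fm = M - z*SD`.
#' @param r2_min Minimum calibration coefficient of determination.
#' @param yx_tol Tolerated relative drift of the intercept/slope ratio.
#' @param alpha Significance level of the ruggedness t-test.
#' @param dilution A [dilution_model()].
#' @param noise A [noise_model()].
#' @param seed Master seed recorded in reports.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(ppm_tol = 5, rt_tol_frac = 0.025, frag_tol = 0.05,
                       min_fragments = 2,
                       ip_required_authorized = 4,
                       ip_required_unauthorized = 5,
                       z = 1.64, r2_min = 0.999, yx_tol = 0.20, alpha = 0.05,
                       dilution = dilution_model(), noise = noise_model(),
                       seed = 1L) {
  stopifnot(ppm_tol > 0, rt_tol_frac > 0, frag_tol > 0, min_fragments >= 0,
            z > 0, r2_min >= 0, yx_tol > 0, alpha > 0, alpha < 1)
  structure(
    list(ppm_tol = ppm_tol, rt_tol_frac = rt_tol_frac, frag_tol = frag_tol,
         min_fragments = min_fragments,
         ip_required_authorized = ip_required_authorized,
         ip_required_unauthorized = ip_required_unauthorized,
         z = z, r2_min = r2_min, yx_tol = yx_tol, alpha = alpha,
         dilution = dilution, noise = noise, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a configuration file
#'
#' Reads a YAML file of configuration overrides; anything not set in the file
#' keeps its [run_config()] default. Nested keys `dilution` and `noise`
#' override the corresponding model fields.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  dil <- do.call(dilution_model, as.list(y$dilution %||% list()))
  noi <- do.call(noise_model, as.list(y$noise %||% list()))
  y$dilution <- NULL
  y$noise <- NULL
  do.call(run_config, c(y, list(dilution = dil, noise = noi)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small polynomial content hash used to stamp reports with the configuration
# they were produced under; not cryptographic.
config_hash <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL, ascii = TRUE)[-(1:18)])
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}
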