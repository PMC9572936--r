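#' Match an observed precursor m/z against a theoretical value
#'
#' @param observed Observed m/z (vectorized).
#' @param theoretical Theoretical m/z (> 0).
#' @param ppm_tol Inclusive mass-accuracy tolerance in ppm (default 5).
#' @return List with `matched` (logical) and `ppm` (signed error).
#' @examples
#' match_precursor(366.1118, 366.1118)
#' @export
match_precursor <- function(observed, theoretical, ppm_tol = 5) {
  stopifnot(ppm_tol > 0)
  ppm <- ppm_error(observed, theoretical)
  list(matched = abs(ppm) <= ppm_tol, ppm = ppm)
}

#' Match an observed retention time against the expected value
#'
#' @param observed_rt Observed retention time (min, vectorized).
#' @param expected_rt Expected retention time (min, > 0).
#' @param tol_frac Inclusive relative tolerance (default 0.025, i.e. 2.5%).
#' @return List with `matched` (logical) and `rel_dev` (signed relative
#'   deviation).
#' @export
match_rt <- function(observed_rt, expected_rt, tol_frac = 0.025) {
  if (any(expected_rt <= 0))
    stop("expected retention time must be > 0", call. = FALSE)
  rel <- (observed_rt - expected_rt) / expected_rt
  list(matched = abs(rel) <= tol_frac, rel_dev = rel)
}

#' Count matched product ions
#'
#' Counts how many of a compound's tabulated fragment m/z values have at
#' least one observed fragment within `frag_tol` Th; each observation is
#' consumed by at most one tabulated fragment.
#'
#' @param observed Numeric vector of observed fragment m/z (may be empty).
#' @param fragments Numeric vector of tabulated fragment m/z.
#' @param frag_tol Inclusive absolute tolerance in Th (default 0.05; the
#'   panel tabulates fragments to one decimal).
#' @return Integer count of matched tabulated fragments.
#' @export
match_fragments <- function(observed, fragments, frag_tol = 0.05) {
  stopifnot(frag_tol > 0)
  used <- rep(FALSE, length(observed))
  n <- 0L
  for (f in fragments) {
    ok <- which(!used & abs(observed - f) <= frag_tol)
    if (length(ok) > 0) {
      used[ok[1]] <- TRUE
      n <- n + 1L
    }
  }
  n
}

#' Identification points for one analyte detection
#'
#' Additive evidence credit: chromatographic separation 1.0, high-resolution
#' precursor ion 1.5, each high-resolution product ion 2.5. Confirmation
#' requires at least 4 points for authorized substances (an MRL exists) and
#' 5 for unauthorized or prohibited ones.
#'
#' @param rt_matched,precursor_matched Logical flags.
#' @param fragments_matched Non-negative integer count of product ions.
#' @return Total identification points.
#' @examples
#' identification_points(TRUE, TRUE, 2) # 7.5
#' @export
identification_points <- function(rt_matched, precursor_matched,
                                  fragments_matched) {
  stopifnot(all(fragments_matched >= 0))
  1.0 * as.numeric(rt_matched) + 1.5 * as.numeric(precursor_matched) +
    2.5 * fragments_matched
}

# Split a semicolon-joined fragment string into a numeric vector.
split_fragments <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
}

#' Identify target compounds in a feature table
#'
#' For each analyte in the database, selects the candidate feature with the
#' smallest absolute precursor ppm error (ties broken by smallest relative
#' RT deviation, then by m/z for determinism), then scores retention-time
#' match, precursor match and product-ion matches into identification
#' points. An analyte is identified when precursor and retention time both
#' match and the point total reaches the class-dependent requirement. A
#' retention-time coincidence without a precursor match identifies nothing:
#' candidates are drawn from the precursor m/z window.
#'
#' @param run A `synthetic_run`, or any list with a `features` data frame
#'   (columns `mz`, `rt_min`, `response`, `fragment_mzs`), or such a data
#'   frame directly.
#' @param db A `compound_db`.
#' @param config A [run_config()] supplying tolerances and point thresholds.
#' @return Data frame of class `identification_report`, one row per analyte:
#'   `name`, `feature_mz`, `feature_rt`, `response`, `precursor_matched`,
#'   `ppm`, `rt_matched`, `rt_rel_dev`, `fragments_matched`, `points`,
#'   `required_points`, `identified`.
#' @export
identify_run <- function(run, db, config = run_config()) {
  stopifnot(inherits(db, "compound_db"))
  features <- if (is.data.frame(run)) run else run$features
  cmp <- db$compounds
  n <- nrow(cmp)
  out <- data.frame(
    name = cmp$name,
    feature_mz = NA_real_, feature_rt = NA_real_, response = NA_real_,
    precursor_matched = FALSE, ppm = NA_real_,
    rt_matched = FALSE, rt_rel_dev = NA_real_,
    fragments_matched = 0L, points = 0,
    required_points = ifelse(cmp$authorized,
                             config$ip_required_authorized,
                             config$ip_required_unauthorized),
    identified = FALSE,
    stringsAsFactors = FALSE
  )
  if (nrow(features) == 0) return(structure(out, class = c("identification_report", "data.frame")))
  for (i in seq_len(n)) {
    ppm <- ppm_error(features$mz, cmp$mz_theoretical[i])
    cand <- which(abs(ppm) <= config$ppm_tol)
    if (length(cand) == 0) next
    rel <- (features$rt_min[cand] - cmp$rt_min[i]) / cmp$rt_min[i]
    # isobaric analytes (e.g. the tetracycline epimers) put several true
    # features in one m/z window: restrict to the expected RT window first,
    # as when reading the extracted-ion chromatogram at the expected RT
    in_rt <- abs(rel) <= config$rt_tol_frac
    pool <- if (any(in_rt)) which(in_rt) else seq_along(cand)
    ord <- pool[order(abs(ppm[cand][pool]), abs(rel[pool]),
                      features$mz[cand][pool])]
    best <- cand[ord[1]]
    rt <- match_rt(features$rt_min[best], cmp$rt_min[i], config$rt_tol_frac)
    frags <- match_fragments(split_fragments(features$fragment_mzs[best]),
                             c(cmp$fragment1_mz[i], cmp$fragment2_mz[i]),
                             config$frag_tol)
    pts <- identification_points(rt$matched, TRUE, frags)
    out$feature_mz[i] <- features$mz[best]
    out$feature_rt[i] <- features$rt_min[best]
    out$response[i] <- features$response[best]
    out$precursor_matched[i] <- TRUE
    out$ppm[i] <- ppm[best]
    out$rt_matched[i] <- rt$matched
    out$rt_rel_dev[i] <- rt$rel_dev
    out$fragments_matched[i] <- frags
    out$points[i] <- pts
    out$identified[i] <- rt$matched && pts >= out$required_points[i]
  }
  structure(out, class = c("identification_report", "data.frame"))
}
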