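#' Load a compound target database
#'
#' Reads a comma-separated target panel (header row; columns `name`, `class`,
#' `formula`, `adduct`, `rt_min`, `precursor_mz`, `fragment1_mz`,
#' `fragment2_mz`, `nce`, `mrl_ug_kg` — empty for unauthorized substances —
#' and `stc_ug_kg`), recomputes every theoretical precursor m/z from formula
#' and adduct, and compares it with the tabulated value. Rows whose tabulated
#' m/z deviates from the recomputation by more than `ppm_flag_tol` are loaded
#' but flagged as discrepancies; the recomputed value is authoritative for
#' matching.
#'
#' @param path Path to the CSV file. Default: the packaged 57-compound panel.
#' @param ppm_flag_tol Flagging tolerance in ppm for tabulated-vs-recomputed
#'   precursor m/z (default 0.5, i.e. anything beyond 4-decimal rounding).
#' @param ppm_tol,rt_tol_frac Matching tolerance defaults stored with the
#'   database: mass accuracy (ppm, default 5) and relative retention-time
#'   tolerance (default 0.025).
#' @return Object of class `compound_db`: a list with `compounds` (data frame,
#'   one row per analyte, including `mz_theoretical`, `ppm_vs_tabulated`,
#'   `mass_flag`, `authorized`), `ppm_tol`, `rt_tol_frac`, `version`.
#' @examples
#' db <- load_compound_db()
#' nrow(db$compounds)
#' @export
load_compound_db <- function(path = NULL, ppm_flag_tol = 0.5,
                             ppm_tol = 5, rt_tol_frac = 0.025) {
  if (is.null(path))
    path <- system.file("extdata", "compound_db.csv", package = "milkscreen",
                        mustWork = TRUE)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "class", "formula", "adduct", "rt_min", "precursor_mz",
                "fragment1_mz", "fragment2_mz", "nce", "mrl_ug_kg", "stc_ug_kg")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0)
    stop(sprintf("compound DB is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (nrow(x) == 0) stop("compound DB is empty", call. = FALSE)
  dup <- x$name[duplicated(x$name)]
  if (length(dup) > 0)
    stop(sprintf("duplicate compound name(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)

  mz_theo <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    mz_theo[i] <- tryCatch(
      adduct_mz(x$formula[i], x$adduct[i]),
      error = function(e) stop(sprintf("row %d (%s): %s", i, x$name[i],
                                       conditionMessage(e)), call. = FALSE)
    )
  }
  bad_rt <- which(!(x$rt_min > 0 & x$rt_min <= 30))
  if (length(bad_rt) > 0)
    stop(sprintf("row %d: retention time outside the (0, 30] min window",
                 bad_rt[1]), call. = FALSE)
  bad_stc <- which(!(x$stc_ug_kg > 0))
  if (length(bad_stc) > 0)
    stop(sprintf("row %d: STC must be > 0", bad_stc[1]), call. = FALSE)
  bad_frag <- which(is.na(x$fragment1_mz) | is.na(x$fragment2_mz))
  if (length(bad_frag) > 0)
    stop(sprintf("row %d: at least two fragment m/z values are required",
                 bad_frag[1]), call. = FALSE)
  over <- which(!is.na(x$mrl_ug_kg) & x$stc_ug_kg > x$mrl_ug_kg)
  if (length(over) > 0)
    stop(sprintf("row %d (%s): STC exceeds MRL", over[1], x$name[over[1]]),
         call. = FALSE)

  x$mz_theoretical   <- mz_theo
  x$ppm_vs_tabulated <- ppm_error(x$precursor_mz, round(mz_theo, 4))
  x$mass_flag        <- abs(x$ppm_vs_tabulated) > ppm_flag_tol
  x$authorized       <- !is.na(x$mrl_ug_kg)

  structure(
    list(compounds = x, ppm_tol = ppm_tol, rt_tol_frac = rt_tol_frac,
         version = "table-2+8-v1", path = path),
    class = "compound_db"
  )
}

#' @export
print.compound_db <- function(x, ...) {
  cat(sprintf("<compound_db> %d analytes (%d authorized), version %s\n",
              nrow(x$compounds), sum(x$compounds$authorized), x$version))
  cat(sprintf("  tolerances: %.3g ppm, %.3g%% RT\n",
              x$ppm_tol, 100 * x$rt_tol_frac))
  flagged <- x$compounds$name[x$compounds$mass_flag]
  if (length(flagged) > 0)
    cat("  flagged precursor m/z discrepancies:",
        paste(flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a compound database to a subset of analytes
#'
#' @param db A `compound_db`.
#' @param names Character vector of analyte names to keep.
#' @return A `compound_db` restricted to `names` (in the given order).
#' @export
db_subset <- function(db, names) {
  stopifnot(inherits(db, "compound_db"))
  missing <- setdiff(names, db$compounds$name)
  if (length(missing) > 0)
    stop(sprintf("compound(s) not in database: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  db$compounds <- db$compounds[match(names, db$compounds$name), , drop = FALSE]
  rownames(db$compounds) <- NULL
  db
}

#' Look up the screening target concentration for a compound
#'
#' STC values are configured data, not a computed fraction of the MRL: the
#' panel's STCs follow class-wise policy choices (MRL for penicillins, the
#' lowest class MRL fraction elsewhere, a minimum achievable level for
#' substances without MRL) that do not reduce to a single formula.
#'
#' @param compound A single-row data frame (one row of `db$compounds`) or a
#'   compound name plus `db`.
#' @param stc_table Named numeric vector mapping compound name to STC (µg/kg).
#' @return STC in µg/kg.
#' @export
assign_stc <- function(compound, stc_table) {
  if (is.character(compound)) {
    name <- compound
    mrl <- NA_real_
  } else {
    name <- compound$name
    mrl <- compound$mrl_ug_kg
  }
  stopifnot(length(name) == 1L)
  if (!name %in% names(stc_table))
    stop(sprintf("no STC configured for '%s'", name), call. = FALSE)
  stc <- unname(stc_table[[name]])
  if (!is.na(mrl) && stc > mrl)
    stop(sprintf("configured STC (%g) exceeds MRL (%g) for '%s'",
                 stc, mrl, name), call. = FALSE)
  stc
}

#' Packaged within-laboratory reproducibility CVs
#'
#' The per-analyte within-lab CVs (percent) observed in the validation of the
#' reference method, used as default dispersion in the synthetic-data
#' generator.
#'
#' @return Data frame with `name`, `stc_ug_kg`, `cv_r_pct`.
#' @export
cv_reference <- function() {
  path <- system.file("extdata", "cv_within_lab.csv", package = "milkscreen",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Packaged isotope-labelled internal standards
#'
#' Four labelled standards added to every milk sample at 10 µg/kg; used by
#' the generator (always present in milk runs) and by batch QC (presence and
#' retention-time drift checks).
#'
#' @return Data frame with `name`, `formula`, `adduct`, `rt_min`,
#'   `conc_ug_kg`, plus computed `mz_theoretical`.
#' @export
internal_standards <- function() {
  path <- system.file("extdata", "internal_standards.csv",
                      package = "milkscreen", mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$mz_theoretical <- vapply(seq_len(nrow(x)),
                             function(i) adduct_mz(x$formula[i], x$adduct[i]),
                             numeric(1))
  x
}
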