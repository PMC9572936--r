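#' Write a run's feature table to delimited text
#'
#' Comma-separated, header row: `run_id`, `species`, `mz`, `rt_min`,
#' `response`, `fragment_mzs` (semicolon-joined).
#'
#' @param run A `synthetic_run` (or compatible list).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(run, path) {
  f <- run$features
  out <- data.frame(run_id = rep(run$run_id, nrow(f)),
                    species = rep(run$species, nrow(f)),
                    f, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Input file path.
#' @return A list shaped like a `synthetic_run` (without generation truth).
#' @export
read_feature_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(fragment_mzs = "character"))
  required <- c("run_id", "species", "mz", "rt_min", "response", "fragment_mzs")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0)
    stop(sprintf("feature table %s is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  feats <- x[, c("mz", "rt_min", "response", "fragment_mzs")]
  feats$fragment_mzs[is.na(feats$fragment_mzs)] <- ""
  new_run(run_id = if (nrow(x) > 0) x$run_id[1] else basename(path),
          species = if (nrow(x) > 0) x$species[1] else NA_character_,
          truth = NULL, features = feats, seed = NA_integer_)
}

#' Write a validation study to a directory
#'
#' Writes `manifest.csv` (run id, kind, species, file), `calibration.csv`,
#' and one feature table per run under `runs/`.
#'
#' @param study A `validation_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "validation_study"))
  dir.create(file.path(dir, "runs"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (kind in c("blank", "spiked")) {
    runs <- study[[paste0(kind, "_runs")]]
    for (run in runs) {
      file <- file.path("runs", paste0(run$run_id, ".csv"))
      write_feature_table(run, file.path(dir, file))
      rows[[length(rows) + 1L]] <- data.frame(
        run_id = run$run_id, kind = kind, species = run$species,
        file = file, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$seed <- study$seed
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(study$calibration),
                   file.path(dir, "calibration.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a validation study written by [write_study()]
#'
#' @param dir Study directory containing `manifest.csv`.
#' @return A `validation_study` (without generation truth).
#' @export
read_study <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath))
    stop(sprintf("no study manifest at %s", mpath), call. = FALSE)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  runs <- lapply(manifest$file, function(f) read_feature_table(file.path(dir, f)))
  calibration <- utils::read.csv(file.path(dir, "calibration.csv"),
                                 stringsAsFactors = FALSE)
  structure(
    list(blank_runs = runs[manifest$kind == "blank"],
         spiked_runs = runs[manifest$kind == "spiked"],
         calibration = calibration, resp = NULL,
         seed = if ("seed" %in% names(manifest)) manifest$seed[1] else NA),
    class = "validation_study"
  )
}

#' Write an analytical batch to a directory
#'
#' @param batch An `analysis_batch`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_batch <- function(batch, dir) {
  stopifnot(inherits(batch, "analysis_batch"))
  dir.create(file.path(dir, "runs"), recursive = TRUE, showWarnings = FALSE)
  manifest <- batch$manifest
  manifest$file <- NA_character_
  for (run in batch$runs) {
    file <- file.path("runs", paste0(run$run_id, ".csv"))
    write_feature_table(run, file.path(dir, file))
    manifest$file[manifest$run_id == run$run_id] <- file
  }
  manifest$seed <- batch$seed
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(batch$calibration),
                   file.path(dir, "calibration.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an analytical batch written by [write_batch()]
#'
#' @param dir Batch directory containing `manifest.csv`.
#' @return An `analysis_batch` (without generation truth).
#' @export
read_batch <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath))
    stop(sprintf("no batch manifest at %s", mpath), call. = FALSE)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  runs <- list()
  with_files <- manifest[!is.na(manifest$file), , drop = FALSE]
  for (i in seq_len(nrow(with_files))) {
    run <- read_feature_table(file.path(dir, with_files$file[i]))
    run$role <- with_files$role[i]
    key <- gsub("-", "_", with_files$run_id[i])
    runs[[key]] <- run
  }
  calibration <- utils::read.csv(file.path(dir, "calibration.csv"),
                                 stringsAsFactors = FALSE)
  structure(list(calibration = calibration, runs = runs,
                 manifest = manifest[, c("position", "run_id", "role")],
                 resp = NULL,
                 seed = if ("seed" %in% names(manifest)) manifest$seed[1] else NA),
            class = "analysis_batch")
}
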