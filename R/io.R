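#' Read a release curve from CSV
#'
#' The on-disk format is a plain CSV with header columns `time_days` and
#' `release_percent` (decimal point, days / percent); lines starting with
#' `#` are comments. The file is validated, not repaired: unsorted or
#' duplicated times are errors rather than being silently sorted, so that a
#' unit or transcription problem surfaces immediately.
#'
#' @param path Path to the CSV file.
#' @return A [release_curve()].
#' @export
read_release_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) abort(paste0("Could not parse CSV: ",
                                     conditionMessage(e)))
  )
  missing_cols <- setdiff(c("time_days", "release_percent"), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  for (col in c("time_days", "release_percent")) {
    if (!is.numeric(df[[col]])) {
      abort(paste0("Column `", col, "` contains non-numeric values."))
    }
  }
  if (anyDuplicated(df$time_days)) {
    abort("Duplicate time points in the file.")
  }
  if (is.unsorted(df$time_days, strictly = TRUE)) {
    abort("Times in the file are not strictly increasing; not silently sorting.")
  }
  as_release_curve(df)
}

#' Write a release curve to CSV
#'
#' Writes `time_days` and `release_percent` (plus any extra columns) at full
#' double precision, so a write/read cycle round-trips to better than 1e-12.
#'
#' @param curve A [release_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_release_csv <- function(curve, path) {
  curve <- as_release_curve(curve)
  df <- as.data.frame(curve)
  for (col in names(df)) {
    if (is.numeric(df[[col]])) {
      df[[col]] <- format(df[[col]], digits = 17, trim = TRUE,
                          scientific = FALSE)
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a serialisable report from a model comparison
#'
#' Collects everything needed to reproduce a [compare_models()] run: the
#' input curve, the filter threshold, the seed, and per-model parameters,
#' S values and derived diffusivities.
#'
#' @param comparison A `release_model_comparison`.
#' @param input A short free-text description of the data provenance.
#' @return A list of class `fit_report` ready for [write_fit_report()].
#' @export
fit_report <- function(comparison, input = "release curve") {
  if (!inherits(comparison, "release_model_comparison")) {
    abort("`comparison` must come from compare_models().")
  }
  curve <- comparison$fits[[1]]$curve
  models <- lapply(comparison$fits, function(f) {
    list(params = f$params,
         s_value = f$s_value,
         n_points = f$n_points,
         n_starts = f$n_starts,
         converged = f$converged)
  })
  structure(list(
    input = input,
    software = paste0("relkin ",
                      as.character(utils::packageVersion("relkin"))),
    options = list(filter_threshold = comparison$filter_threshold,
                   radius = comparison$radius,
                   seed = comparison$seed),
    n_points = comparison$n_points,
    curve = list(time_days = curve$time_days,
                 release_percent = curve$release_percent),
    models = models,
    ranking = as.character(comparison$table$model),
    errors = as.list(comparison$errors)
  ), class = "fit_report")
}

#' Write / read a fit report as JSON
#'
#' Reports round-trip losslessly (numbers serialised at full precision).
#'
#' @param report A [fit_report()].
#' @param path JSON path.
#' @return `write_fit_report()`: `path` invisibly. `read_fit_report()`: the
#'   report list.
#' @export
write_fit_report <- function(report, path) {
  if (!inherits(report, "fit_report")) {
    abort("`report` must come from fit_report().")
  }
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_report
#' @export
read_fit_report <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  rep <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(rep, class = "fit_report")
}
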