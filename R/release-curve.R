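#' Construct a release curve
#'
#' A release curve is the central observable of a dissolution/desorption
#' experiment: cumulative drug release (percent of the total load) recorded at
#' increasing times. `release_curve()` validates the data and returns a tibble
#' of class `release_curve` that the fitting and plotting functions accept.
#'
#' Times must be strictly increasing and non-negative (days). Release values
#' must lie in \[0, 110\]: small over-100 excursions are a routine feature of
#' cumulative assays and are tolerated (with a warning above 100), but larger
#' values indicate a unit or assay error and are rejected.
#'
#' @param time_days Numeric vector of sampling times, days.
#' @param release_percent Numeric vector of cumulative release, percent.
#' @param ... Additional equal-length columns carried along (e.g. a
#'   per-point `clipped` flag from [simulate_release()]).
#' @return A tibble with columns `time_days` and `release_percent` (plus any
#'   extras), of class `release_curve`.
#' @examples
#' release_curve(c(1, 2, 5), c(20, 45, 80))
#' @export
release_curve <- function(time_days, release_percent, ...) {
  if (length(time_days) != length(release_percent)) {
    abort("`time_days` and `release_percent` must have equal lengths.")
  }
  if (length(time_days) == 0L) {
    abort("A release curve needs at least one point.")
  }
  if (!is.numeric(time_days) || !is.numeric(release_percent)) {
    abort("`time_days` and `release_percent` must be numeric.")
  }
  if (anyNA(time_days) || anyNA(release_percent)) {
    abort("Release curves may not contain missing values.")
  }
  if (any(time_days < 0)) {
    abort("Times must be non-negative.")
  }
  if (is.unsorted(time_days, strictly = TRUE)) {
    abort("Times must be strictly increasing (duplicates are not allowed).")
  }
  if (any(release_percent < 0) || any(release_percent > 110)) {
    abort("Release values must lie in [0, 110] percent.")
  }
  if (any(release_percent > 100)) {
    warn("Release values above 100% retained (measurement excursion <= 110%).")
  }
  out <- tibble(time_days = as.numeric(time_days),
                release_percent = as.numeric(release_percent), ...)
  class(out) <- c("release_curve", class(out))
  out
}

#' Coerce a data frame to a release curve
#'
#' @param x A data frame with columns `time_days` and `release_percent`.
#' @return A validated [release_curve()].
#' @export
as_release_curve <- function(x) {
  if (inherits(x, "release_curve")) return(x)
  if (!is.data.frame(x)) abort("`x` must be a data frame.")
  missing_cols <- setdiff(c("time_days", "release_percent"), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  extras <- x[setdiff(names(x), c("time_days", "release_percent"))]
  do.call(release_curve,
          c(list(time_days = x$time_days,
                 release_percent = x$release_percent),
            as.list(extras)))
}

#' Drop trivial (plateau) points from a release curve
#'
#' Points at or above the plateau carry no information about the release
#' kinetics, so the fit statistic is defined over the non-trivial points
#' only: those with release below `threshold` (default 99%). Filtering is
#' applied before fitting; the retained count is the `n_points` of any
#' downstream fit.
#'
#' @param curve A [release_curve()] (or coercible data frame).
#' @param threshold Release cut-off in percent; points with
#'   `release_percent < threshold` are kept. Default 99.
#' @return The filtered `release_curve`, order preserved.
#' @examples
#' rc <- release_curve(1:5, c(10, 50, 98.5, 99.5, 100))
#' filter_nontrivial(rc)
#' @export
filter_nontrivial <- function(curve, threshold = 99) {
  curve <- as_release_curve(curve)
  keep <- curve$release_percent < threshold
  if (!any(keep)) {
    abort(paste0("No points below the ", threshold,
                 "% threshold: the curve is uninformative for fitting."))
  }
  out <- curve[keep, , drop = FALSE]
  class(out) <- unique(c("release_curve", class(out)))
  out
}

#' @export
print.release_curve <- function(x, ...) {
  cat("# A release curve:", nrow(x), "points,",
      sprintf("t = %g..%g d, R = %g..%g%%\n",
              min(x$time_days), max(x$time_days),
              min(x$release_percent), max(x$release_percent)))
  NextMethod()
}

#' Plot a release curve
#'
#' @param object A [release_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.release_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time_days,
                               y = .data$release_percent)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "Time (days)", y = "Cumulative release (%)")
}
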