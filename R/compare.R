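#' Fit and rank all applicable release models on one curve
#'
#' Fits the bimodal, single-term and (when a radius is supplied) exact series
#' models to the identically filtered curve and ranks them by the S
#' statistic. A failure of one model is recorded in the comparison table
#' rather than aborting the others.
#'
#' @param curve A [release_curve()] or coercible data frame.
#' @param radius Optional particle radius in meters; required for the series
#'   model and for reporting diffusivities alongside the rate-based fits.
#' @param filter_threshold Plateau threshold, see [filter_nontrivial()].
#' @param seed Optional integer recorded with each fit.
#' @return A `release_model_comparison`: list with `fits` (named list of
#'   `release_fit` objects), `table` (tibble ranked by S, including derived
#'   diffusivities when a radius is given), `errors` (named character), and
#'   the shared filtering metadata.
#' @examples
#' rc <- simulate_release(seq(0.5, 15, 0.5),
#'                        params = list(phi = 0.254, k1 = 1, k2 = 0.04),
#'                        noise_sd = 2, seed = 7)
#' compare_models(rc, radius = 69e-9)
#' @export
compare_models <- function(curve, radius = NULL, filter_threshold = 99,
                           seed = NULL) {
  filtered <- filter_nontrivial(curve, filter_threshold)
  fitters <- list(
    bimodal = function() fit_bimodal(filtered, filter_threshold = Inf, seed = seed),
    single_term = function() fit_single_term(filtered, filter_threshold = Inf, seed = seed)
  )
  if (!is.null(radius)) {
    fitters$series <- function() fit_series(filtered, radius,
                                            filter_threshold = Inf, seed = seed)
  }
  fits <- list()
  errors <- character()
  for (nm in names(fitters)) {
    res <- tryCatch(fitters[[nm]](), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[nm]] <- conditionMessage(res)
    } else {
      fits[[nm]] <- res
    }
  }
  if (length(fits) == 0) {
    abort("Every model fit failed; see the per-model error messages.")
  }
  table <- purrr::map_dfr(fits, function(f) {
    row <- glance(f)
    row$params <- list(f$params)
    if (!is.null(radius)) {
      if (f$model_id == "bimodal") {
        row$d_fast <- diffusivity_from_rate(f$params$k1, radius)
        row$d_slow <- diffusivity_from_rate(f$params$k2, radius)
      } else if (f$model_id == "single_term") {
        row$d_fast <- diffusivity_from_rate(f$params$rate, radius)
        row$d_slow <- NA_real_
      } else if (f$model_id == "series") {
        row$d_fast <- f$params$diffusivity
        row$d_slow <- NA_real_
      }
    }
    row
  })
  table <- dplyr::arrange(table, .data$s_value)
  structure(
    list(fits = fits, table = table, errors = errors,
         filter_threshold = filter_threshold,
         n_points = nrow(filtered), radius = radius, seed = seed),
    class = "release_model_comparison"
  )
}

#' @export
print.release_model_comparison <- function(x, ...) {
  cat("<release_model_comparison>", x$n_points, "points (threshold",
      x$filter_threshold, "%)\n")
  print(dplyr::select(x$table, -dplyr::any_of("params")))
  if (length(x$errors) > 0) {
    cat("Failed models:\n")
    for (nm in names(x$errors)) cat("  -", nm, ":", x$errors[[nm]], "\n")
  }
  invisible(x)
}

#' @export
tidy.release_model_comparison <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    out <- tidy(f)
    out$model <- f$model_id
    out[, c("model", "term", "estimate")]
  })
}

#' @export
glance.release_model_comparison <- function(x, ...) {
  dplyr::select(x$table, -dplyr::any_of("params"))
}

#' Plot all fitted models over the data
#'
#' @param object A `release_model_comparison`.
#' @param n_grid Grid resolution of the fitted lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.release_model_comparison <- function(object, n_grid = 200, ...) {
  curve <- object$fits[[1]]$curve
  tgrid <- seq(min(curve$time_days), max(curve$time_days), length.out = n_grid)
  lines <- purrr::map_dfr(object$fits, function(f) {
    tibble(model = f$model_id, time_days = tgrid,
           release_percent = predict(f, tgrid))
  })
  ggplot2::ggplot(curve,
                  ggplot2::aes(x = .data$time_days, y = .data$release_percent)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = lines, ggplot2::aes(colour = .data$model)) +
    ggplot2::labs(x = "Time (days)", y = "Cumulative release (%)",
                  colour = "Model")
}

#' Fast and slow diffusivities from a bimodal fit
#'
#' Converts the canonical rate constants of a bimodal `release_fit` to
#' diffusivities: `D_fast = K1 r^2 / 15`, `D_slow = K2 r^2 / 15`
#' (day-to-second conversion applied inside [diffusivity_from_rate()]).
#'
#' @param fit A bimodal `release_fit`.
#' @param radius Particle radius, meters.
#' @return A tibble with columns `mode` ("fast", "slow"), `rate` (per day)
#'   and `diffusivity` (m^2/s).
#' @export
fast_slow_diffusivities <- function(fit, radius) {
  if (!inherits(fit, "release_fit") || fit$model_id != "bimodal") {
    abort("`fit` must be a bimodal release_fit.")
  }
  check_radius(radius)
  tibble(mode = c("fast", "slow"),
         rate = c(fit$params$k1, fit$params$k2),
         diffusivity = c(diffusivity_from_rate(fit$params$k1, radius),
                         diffusivity_from_rate(fit$params$k2, radius)))
}

#' Percent change in fast/slow diffusivities between two formulations
#'
#' Compares two bimodal fits (e.g. a plain polymer nanoparticle versus a
#' MOF-composite one), each with its own particle radius:
#' `100 * (D_b / D_a - 1)` per mode.
#'
#' @param fit_a,fit_b Bimodal `release_fit` objects (reference and
#'   comparison formulation).
#' @param radius_a,radius_b The corresponding particle radii, meters.
#' @return A tibble with `mode`, `diffusivity_a`, `diffusivity_b` and
#'   `pct_change`.
#' @export
diffusivity_change <- function(fit_a, fit_b, radius_a, radius_b) {
  da <- fast_slow_diffusivities(fit_a, radius_a)
  db <- fast_slow_diffusivities(fit_b, radius_b)
  tibble(mode = da$mode,
         diffusivity_a = da$diffusivity,
         diffusivity_b = db$diffusivity,
         pct_change = 100 * (db$diffusivity / da$diffusivity - 1))
}
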