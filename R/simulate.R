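#' Simulate a noisy cumulative release curve
#'
#' Evaluates one of the three forward models on a sampling schedule and adds
#' i.i.d. Gaussian measurement noise to the cumulative release, clipped to
#' `clip` (default \[0, 102\]%: cumulative assays routinely show small
#' over-100 excursions). Noise is additive on cumulative release, the
#' simplest structure consistent with the unweighted least-squares fitting
#' criterion; the resulting noisy curves need not be monotone, as real
#' cumulative data with assay noise are not. An optional isotonic
#' post-processing step (`monotone = TRUE`, pooled-adjacent-violators) is
#' available but off by default.
#'
#' With `noise_sd = 0` the output is exactly the forward model; with a fixed
#' `seed` the output is bit-reproducible.
#'
#' @param times Strictly increasing sampling schedule, days.
#' @param model One of "bimodal", "single_term", "series".
#' @param params Named list of model parameters: `phi`, `k1`, `k2`
#'   (bimodal); `prefactor`, `rate` (single_term); `diffusivity` (series,
#'   with `radius` supplied).
#' @param noise_sd Additive Gaussian noise standard deviation, release-%.
#' @param clip Length-2 numeric, clipping range in percent.
#' @param seed Optional integer seed; the global RNG state is restored
#'   afterwards.
#' @param radius Particle radius, meters (series model only).
#' @param monotone If TRUE, apply an isotonic regression to the noisy curve.
#' @return A [release_curve()] with an additional logical column `clipped`
#'   flagging points that hit the clipping range.
#' @examples
#' simulate_release(1:15, params = list(phi = 0.254, k1 = 1, k2 = 0.04),
#'                  noise_sd = 2, seed = 42)
#' @export
simulate_release <- function(times,
                             model = c("bimodal", "single_term", "series"),
                             params,
                             noise_sd = 0,
                             clip = c(0, 102),
                             seed = NULL,
                             radius = NULL,
                             monotone = FALSE) {
  model <- match.arg(model)
  check_times(times)
  if (length(times) > 1 && is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing.")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    abort("`noise_sd` must be a single non-negative number.")
  }
  if (!is.numeric(clip) || length(clip) != 2 || clip[1] >= clip[2]) {
    abort("`clip` must be c(low, high) with low < high.")
  }
  mean_release <- switch(model,
    bimodal = bimodal_release(times, params$phi, params$k1, params$k2),
    single_term = single_term_release(times, params$prefactor, params$rate),
    series = {
      if (is.null(radius)) abort("The series model needs `radius` (meters).")
      series_release(times, params$diffusivity, radius)
    }
  )
  if (noise_sd > 0) {
    noise <- with_local_seed(seed, rnorm(length(times), sd = noise_sd))
    noisy <- mean_release + noise
  } else {
    noisy <- mean_release
  }
  clipped_vals <- pmin(pmax(noisy, clip[1]), clip[2])
  clipped <- clipped_vals != noisy
  if (monotone) {
    iso <- stats::isoreg(seq_along(clipped_vals), clipped_vals)
    clipped_vals <- iso$yf
  }
  # over-100 excursions inside the explicit clip range are by design here,
  # so the constructor's excursion warning would only be noise
  withCallingHandlers(
    release_curve(times, clipped_vals, clipped = clipped),
    warning = function(w) {
      if (grepl("above 100", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

# Run `expr` under a temporary RNG seed, restoring the global state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
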