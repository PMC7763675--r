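#' Exact sphere-diffusion release curve
#'
#' Fraction released from a uniformly loaded sphere by (surface) diffusion,
#' the classical series solution of the transient diffusion equation in
#' spherical coordinates:
#' \deqn{R(t) = 100\Big(1 - \frac{6}{\pi^2}\sum_{i\ge 1}\frac{1}{i^2}
#'   \exp(-D i^2 \pi^2 t / r^2)\Big)}
#' with `D` the surface diffusion coefficient and `r` the particle radius.
#'
#' The series is truncated adaptively: summation stops once a geometric
#' bound on the remaining tail falls below `rel_tol` of the partial sum
#' (hard cap `max_terms`). At `t = 0` the full series sums exactly to one
#' (\eqn{\sum 1/i^2 = \pi^2/6}) so the release is returned as exactly 0;
#' a finite truncation would otherwise give a spurious positive value.
#'
#' @param times Sampling times, days (non-negative).
#' @param diffusivity Surface diffusion coefficient `D`, m^2/s (> 0).
#' @param radius Particle radius `r`, meters (> 0).
#' @param rel_tol Relative truncation tolerance in (0, 1e-3]. Default 1e-10.
#' @param max_terms Hard cap on the number of series terms. Default 10000.
#' @return Numeric vector of cumulative release percentages in \[0, 100).
#' @examples
#' series_release(c(0, 1, 4), diffusivity = 1e-21, radius = 69e-9)
#' @export
series_release <- function(times, diffusivity, radius,
                           rel_tol = 1e-10, max_terms = 10000L) {
  check_times(times)
  if (!is.numeric(diffusivity) || length(diffusivity) != 1 || diffusivity <= 0) {
    abort("`diffusivity` must be a single positive number (m^2/s).")
  }
  check_radius(radius)
  if (!is.numeric(rel_tol) || length(rel_tol) != 1 ||
      rel_tol <= 0 || rel_tol > 1e-3) {
    abort("`rel_tol` must lie in (0, 1e-3].")
  }
  # dimensionless time D t / r^2 (t converted days -> seconds)
  tau <- diffusivity * times * SECONDS_PER_DAY / radius^2
  vapply(tau, function(tt) {
    if (tt == 0) return(0)
    s <- 0
    for (i in seq_len(max_terms)) {
      term <- exp(-tt * i^2 * pi^2) / i^2
      s <- s + term
      # remaining terms are bounded by a geometric tail with ratio
      # q = exp(-tau pi^2 (2i+1)); stop once that tail is negligible
      q <- exp(-tt * pi^2 * (2 * i + 1))
      if (term * q / (1 - q) < rel_tol * s) break
    }
    100 * (1 - (6 / pi^2) * s)
  }, numeric(1))
}

#' Single-exponential (long-time) release approximation
#'
#' Keeping only the first exponential of the sphere-diffusion series, with
#' both its amplitude and rate treated as free parameters, gives
#' \deqn{R(t) = 100(1 - A e^{-k t}).}
#' With `prefactor = 6/pi^2` and `rate = D pi^2 / r^2` it is exactly the
#' first series term. Note that for `A < 1` the model starts at
#' `R(0) = 100 (1 - A) > 0`: the approximation cannot reproduce the initial
#' diffusion burst.
#'
#' @param times Sampling times, days (non-negative).
#' @param prefactor Dimensionless amplitude `A` in (0, 1].
#' @param rate First-order rate constant `k`, per day (> 0).
#' @return Cumulative release percentages.
#' @examples
#' single_term_release(2, prefactor = 0.9, rate = 0.5)
#' @export
single_term_release <- function(times, prefactor, rate) {
  check_times(times)
  if (!is.numeric(prefactor) || length(prefactor) != 1 ||
      prefactor <= 0 || prefactor > 1) {
    abort("`prefactor` must lie in (0, 1].")
  }
  check_rate(rate)
  100 * (1 - prefactor * exp(-rate * times))
}

#' Bimodal (two-population) release curve
#'
#' Two sub-populations of drug molecules, fractions `phi` and `1 - phi`,
#' each released with its own first-order rate constant:
#' \deqn{R(t) = 100[\varphi(1 - e^{-K_1 t}) + (1-\varphi)(1 - e^{-K_2 t})].}
#' The two rates map to fast and slow diffusivities through the linear
#' driving force relation (see [diffusivity_from_rate()]).
#'
#' @param times Sampling times, days (non-negative).
#' @param phi Fast-population fraction in \[0, 1\].
#' @param k1,k2 First-order rate constants, per day (> 0). No ordering is
#'   imposed here; see [canonicalize_bimodal()] for the `k1 >= k2` convention.
#' @return Cumulative release percentages in \[0, 100).
#' @examples
#' bimodal_release(1, phi = 0.254, k1 = 1, k2 = 0.04)
#' @export
bimodal_release <- function(times, phi, k1, k2) {
  check_times(times)
  check_phi(phi)
  check_rate(k1, "k1")
  check_rate(k2, "k2")
  100 * (phi * (1 - exp(-k1 * times)) + (1 - phi) * (1 - exp(-k2 * times)))
}

#' Canonical ordering of bimodal parameters
#'
#' The bimodal model is invariant under the relabelling
#' `(phi, k1, k2) -> (1 - phi, k2, k1)`. The canonical representative has
#' `k1 >= k2`, so `phi` is always the fast-population fraction.
#'
#' @param phi,k1,k2 A valid bimodal parameter triple.
#' @return A named list `(phi, k1, k2)` with `k1 >= k2`, describing the
#'   identical release curve.
#' @examples
#' canonicalize_bimodal(0.3, 0.04, 1)
#' @export
canonicalize_bimodal <- function(phi, k1, k2) {
  check_phi(phi)
  check_rate(k1, "k1")
  check_rate(k2, "k2")
  if (k1 < k2) {
    list(phi = 1 - phi, k1 = k2, k2 = k1)
  } else {
    list(phi = phi, k1 = k1, k2 = k2)
  }
}

#' Convert a first-order release rate to a diffusivity (and back)
#'
#' The linear driving force approximation for a sphere relates a lumped
#' first-order rate constant to the internal diffusivity by
#' `K = 15 D / r^2`, i.e. `D = K r^2 / 15`. Rates are expressed per day in
#' the public interface (matching how release kinetics are reported) while
#' diffusivities are SI m^2/s; the 86,400 s/day factor is applied inside
#' these two functions only.
#'
#' @param rate First-order rate constant, per day (> 0).
#' @param diffusivity Diffusion coefficient, m^2/s (> 0).
#' @param radius Particle radius, meters (> 0). Conventionally half the
#'   hydrodynamic (DLS) diameter.
#' @return `diffusivity_from_rate()`: diffusivity in m^2/s.
#'   `rate_from_diffusivity()`: rate in per day. The two are exact inverses.
#' @examples
#' diffusivity_from_rate(1, radius = 69e-9)     # ~3.7e-21 m^2/s
#' rate_from_diffusivity(1.46e-22, radius = 69e-9)  # ~0.04 / day
#' @export
diffusivity_from_rate <- function(rate, radius) {
  if (!is.numeric(rate) || any(rate <= 0)) {
    abort("`rate` must be positive (per day).")
  }
  check_radius(radius)
  (rate / SECONDS_PER_DAY) * radius^2 / LDF_FACTOR
}

#' @rdname diffusivity_from_rate
#' @export
rate_from_diffusivity <- function(diffusivity, radius) {
  if (!is.numeric(diffusivity) || any(diffusivity <= 0)) {
    abort("`diffusivity` must be positive (m^2/s).")
  }
  check_radius(radius)
  LDF_FACTOR * diffusivity / radius^2 * SECONDS_PER_DAY
}

# ---- argument checks ------------------------------------------------------

check_times <- function(times) {
  if (!is.numeric(times) || anyNA(times)) {
    abort("`times` must be numeric without missing values.")
  }
  if (any(times < 0)) abort("Negative times are not allowed.")
  invisible(times)
}

check_radius <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    abort("`radius` must be a single positive number (meters).")
  }
  invisible(radius)
}

check_rate <- function(rate, name = "rate") {
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    abort(paste0("`", name, "` must be a single positive number (per day)."))
  }
  invisible(rate)
}

check_phi <- function(phi) {
  if (!is.numeric(phi) || length(phi) != 1 || phi < 0 || phi > 1) {
    abort("`phi` must be a single number in [0, 1].")
  }
  invisible(phi)
}
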