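test_that("series release matches the brute-force partial-sum oracle", {
  # single spot check at realistic nanoparticle parameters
  expect_equal(series_release(1, 1e-21, 69e-9),
               oracle_series_release(1, 1e-21, 69e-9),
               tolerance = 1e-8)

  # grid of dimensionless times D t / r^2 in [1e-4, 10]
  r <- 69e-9
  taus <- 10^seq(-4, 1, length.out = 25)
  d_for_tau <- function(tau, t_days = 1) tau * r^2 / (t_days * 86400)
  for (tau in taus) {
    d <- d_for_tau(tau)
    expect_lt(abs(series_release(1, d, r) - oracle_series_release(1, d, r)),
              1e-8)
  }
})

test_that("series release boundary behaviour: zero at t = 0, complete at large tau", {
  expect_identical(series_release(0, 1e-21, 69e-9), 0)
  # D t / r^2 = 10: all exponentials vanish
  r <- 69e-9
  d <- 10 * r^2 / 86400
  expect_equal(series_release(1, d, r), 100, tolerance = 1e-10)
})

test_that("series release is non-decreasing in t and bounded in [0, 100]", {
  tt <- seq(0, 15, by = 0.25)
  rel <- series_release(tt, 1e-21, 69e-9)
  expect_true(all(diff(rel) >= 0))
  expect_true(all(rel >= 0 & rel <= 100))
})

test_that("series release rejects invalid domains", {
  expect_error(series_release(-1, 1e-21, 69e-9), "Negative")
  expect_error(series_release(1, -1e-21, 69e-9), "diffusivity")
  expect_error(series_release(1, 1e-21, 0), "radius")
  expect_error(series_release(1, 1e-21, 69e-9, rel_tol = 1), "rel_tol")
})

test_that("single-term model evaluates its closed form", {
  # A = 1 starts at zero
  expect_equal(single_term_release(0, 1, 0.3), 0)
  # hand evaluation: 100 (1 - 0.9 e^-1)
  expect_equal(single_term_release(2, 0.9, 0.5), 100 * (1 - 0.9 * exp(-1)),
               tolerance = 1e-12)
  expect_equal(round(single_term_release(2, 0.9, 0.5), 2), 66.89)
  # A < 1 implies a positive intercept (the missing burst)
  expect_gt(single_term_release(0, 0.9, 0.5), 0)
})

test_that("single-term with A = 6/pi^2 reproduces the first series term", {
  d <- 1e-21; r <- 69e-9
  k <- d * pi^2 / r^2 * 86400  # per day
  tt <- c(0.5, 1, 2, 5)
  first_term <- 100 * (1 - (6 / pi^2) * exp(-k * tt))
  expect_equal(single_term_release(tt, 6 / pi^2, k), first_term,
               tolerance = 1e-12)
})

test_that("the initial diffusion burst outruns any zero-intercept exponential", {
  # The exact solution releases ~ sqrt(t) initially, so at small
  # dimensionless times D t / r^2 < 0.01 it lies far above the single
  # exponential that shares its zero intercept (A = 1, k = D pi^2 / r^2).
  # The A = 6/pi^2 variant instead jumps to 100(1 - 6/pi^2) = 39.2% at
  # t = 0 and therefore overshoots the exact curve at small times: a
  # single exponential can match one regime or the other, never both.
  r <- 69e-9
  for (tau in c(1e-4, 1e-3, 5e-3, 9e-3)) {
    d <- tau * r^2 / 86400
    k <- d * pi^2 / r^2 * 86400
    exact <- series_release(1, d, r)
    expect_gt(exact, single_term_release(1, 1, k))
    expect_gt(exact, 3 * single_term_release(1, 1, k))  # far above, not marginal
    expect_lt(exact, single_term_release(1, 6 / pi^2, k))
  }
})

test_that("bimodal release evaluates its closed form and limits", {
  expect_equal(bimodal_release(0, 0.3, 1, 0.1), 0)
  # hand evaluation at published mPEG-PCL constants
  expect_equal(round(bimodal_release(1, 0.254, 1, 0.04), 2), 18.98)
  # phi = 1 degenerates to one population
  tt <- c(0.5, 1, 3, 7)
  expect_equal(bimodal_release(tt, 1, 0.7, 0.01),
               100 * (1 - exp(-0.7 * tt)), tolerance = 1e-12)
  # strictly increasing, bounded, -> 100
  tt <- seq(0, 40, by = 0.5)
  rel <- bimodal_release(tt, 0.4, 1.5, 0.2)
  expect_true(all(diff(rel) > 0))
  expect_true(all(rel >= 0 & rel < 100))
  expect_equal(bimodal_release(1e4, 0.4, 1.5, 0.2), 100, tolerance = 1e-9)
})

test_that("canonicalize orders rates without changing the curve", {
  p <- canonicalize_bimodal(0.3, 0.04, 1)
  expect_equal(p, list(phi = 0.7, k1 = 1, k2 = 0.04))
  # tie left unchanged
  expect_equal(canonicalize_bimodal(0.5, 0.2, 0.2),
               list(phi = 0.5, k1 = 0.2, k2 = 0.2))
  # idempotent and curve-preserving on random triples
  set.seed(11)
  tt <- seq(0.5, 15, by = 0.5)
  for (i in 1:20) {
    phi <- runif(1); k <- sort(10^runif(2, -2, 1))
    a <- canonicalize_bimodal(phi, k[1], k[2])
    b <- do.call(canonicalize_bimodal, a)
    expect_identical(a, b)
    expect_equal(bimodal_release(tt, a$phi, a$k1, a$k2),
                 bimodal_release(tt, phi, k[1], k[2]), tolerance = 1e-12)
  }
})

test_that("rate <-> diffusivity conversion reproduces published coefficients", {
  # K = 1 / day at r = 69 nm (half the 138 nm DLS size) -> 3.7e-21 m^2/s
  expect_equal(diffusivity_from_rate(1, 69e-9), 3.7e-21, tolerance = 0.01)
  # K = 1.74 / day at r = 71.5 nm -> 6.9e-21 m^2/s
  expect_equal(diffusivity_from_rate(1.74, 71.5e-9), 6.9e-21, tolerance = 0.01)
  # D = 1.46e-22 m^2/s at 69 nm -> 0.04 / day
  expect_equal(rate_from_diffusivity(1.46e-22, 69e-9), 0.04, tolerance = 0.01)
})

test_that("rate <-> diffusivity are exact inverses with the stated unit factors", {
  # unit identity: K expressed so K [1/s] = 15 at r = 1 m -> D = 1 m^2/s
  expect_equal(diffusivity_from_rate(15 * 86400, 1), 1, tolerance = 1e-12)
  expect_equal(rate_from_diffusivity(1, 1), 15 * 86400, tolerance = 1e-12)
  # round trips
  for (k in c(0.01, 0.123, 1, 4.98)) {
    for (r in c(12.5e-9, 69e-9, 71.5e-9)) {
      expect_equal(rate_from_diffusivity(diffusivity_from_rate(k, r), r), k,
                   tolerance = 1e-12)
    }
  }
  expect_equal(rate_from_diffusivity(3.673611e-21, 69e-9), 1, tolerance = 1e-6)
  expect_error(diffusivity_from_rate(-1, 69e-9), "positive")
  expect_error(rate_from_diffusivity(1e-21, -1), "radius")
})
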