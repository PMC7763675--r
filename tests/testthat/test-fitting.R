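make_curve <- function(phi, k1, k2, times = seq(0.5, 15, by = 0.5),
                       noise_sd = 0, seed = NULL) {
  simulate_release(times, params = list(phi = phi, k1 = k1, k2 = k2),
                   noise_sd = noise_sd, seed = seed)
}

test_that("filter_nontrivial keeps exactly the sub-threshold points", {
  rc <- release_curve(1:5, c(10, 50, 98.5, 99.5, 100))
  kept <- filter_nontrivial(rc)
  expect_equal(kept$release_percent, c(10, 50, 98.5))
  expect_equal(kept$time_days, 1:3)
  # identity when everything is informative
  rc2 <- release_curve(1:3, c(10, 40, 70))
  expect_equal(filter_nontrivial(rc2)$release_percent, rc2$release_percent)
  # degenerate: everything on the plateau
  rc3 <- release_curve(1:3, c(99, 99.5, 100))
  expect_error(filter_nontrivial(rc3), "uninformative")
})

test_that("s_statistic computes the root mean squared deviation", {
  expect_equal(s_statistic(c(10, 50, 90), c(10, 50, 90)), 0)
  expect_equal(s_statistic(c(12, 52, 92, 30), c(10, 50, 90, 28)), 2)
  expect_equal(s_statistic(c(13, 54), c(10, 50)), sqrt(25 / 2))
  expect_error(s_statistic(1:3, 1:4), "equal lengths")
})

test_that("bimodal fit recovers parameters exactly on noiseless curves", {
  rc <- make_curve(0.29, 1.74, 0.123)
  fit <- fit_bimodal(rc)
  expect_lt(fit$s_value, 1e-6)
  expect_equal(fit$params$phi, 0.29, tolerance = 1e-4)
  expect_equal(fit$params$k1, 1.74, tolerance = 1e-4)
  expect_equal(fit$params$k2, 0.123, tolerance = 1e-4)
  expect_true(fit$converged)
  expect_gte(fit$params$k1, fit$params$k2)
})

test_that("fit results satisfy the S / residual consistency identity", {
  rc <- make_curve(0.254, 1, 0.04, noise_sd = 2, seed = 31)
  for (fit in list(fit_bimodal(rc), fit_single_term(rc))) {
    expect_equal(fit$s_value^2 * fit$n_points, sum(fit$residuals^2),
                 tolerance = 1e-9)
    expect_equal(fit$n_points, nrow(fit$curve))
  }
})

test_that("single-population data is fitted to S ~ 0, degeneracy tolerated", {
  rc <- simulate_release(seq(0.5, 15, 0.5), "single_term",
                         params = list(prefactor = 1, rate = 0.35))
  fit <- fit_bimodal(rc)
  expect_lt(fit$s_value, 1e-6)
})

test_that("bimodal fit on noisy data lands near the noise floor", {
  rc <- make_curve(0.254, 1, 0.04, noise_sd = 2, seed = 17)
  fit <- fit_bimodal(rc)
  expect_gt(fit$s_value, 0.5 * 2)
  expect_lt(fit$s_value, 2 * 2)
})

test_that("single-term fit recovers its own model and misfits bimodal data", {
  rc <- simulate_release(seq(0.5, 15, 0.5), "single_term",
                         params = list(prefactor = 0.8, rate = 0.3))
  fit <- fit_single_term(rc)
  expect_lt(fit$s_value, 1e-8)
  expect_equal(fit$params$prefactor, 0.8, tolerance = 1e-6)
  expect_equal(fit$params$rate, 0.3, tolerance = 1e-6)

  # widely separated rates (K1/K2 = 25) defeat a single exponential
  rc2 <- make_curve(0.4, 1, 0.04)
  s_single <- fit_single_term(rc2)$s_value
  s_bi <- fit_bimodal(rc2)$s_value
  expect_gt(s_single, 10 * s_bi)
  expect_gt(s_single, 1)

  expect_error(fit_single_term(release_curve(1:2, c(10, 20))), "at least 3")
})

test_that("series fit recovers D across magnitudes from a global search", {
  tt <- seq(0.25, 4, by = 0.25)
  for (d_true in c(6e-22, 6e-19, 6e-16)) {
    r <- sqrt(d_true / 6e-22) * 12.5e-9  # keep tau-range comparable
    rc <- simulate_release(tt, "series",
                           params = list(diffusivity = d_true), radius = r)
    fit <- fit_series(rc, r)
    expect_equal(fit$params$diffusivity, d_true, tolerance = 1e-4)
  }
})

test_that("series model misfits bimodal data with separated rates", {
  rc <- make_curve(0.3, 2, 0.05)
  s_series <- fit_series(rc, 69e-9)$s_value
  s_bi <- fit_bimodal(rc)$s_value
  expect_gt(s_series, s_bi)
  expect_gt(s_series, 1)
})

test_that("bimodal S never exceeds single-term S (nesting)", {
  set.seed(5)
  for (i in 1:6) {
    rc <- make_curve(runif(1, 0.2, 0.8), 10^runif(1, -0.5, 0.5),
                     10^runif(1, -2, -0.8), noise_sd = 2, seed = 400 + i)
    s_bi <- suppressWarnings(fit_bimodal(rc)$s_value)
    s_single <- suppressWarnings(fit_single_term(rc)$s_value)
    expect_lte(s_bi, s_single + 1e-6)
  }
})

test_that("fitting is deterministic: identical input gives identical result", {
  rc <- make_curve(0.29, 1.74, 0.123, noise_sd = 2, seed = 99)
  f1 <- fit_bimodal(rc, seed = 1L)
  f2 <- fit_bimodal(rc, seed = 1L)
  expect_identical(unlist(f1$params), unlist(f2$params))
  expect_identical(f1$s_value, f2$s_value)
})

test_that("compare_models ranks bimodal < series < single-term on bimodal data", {
  rc <- make_curve(0.254, 1, 0.04, noise_sd = 2, seed = 9)
  cmp <- compare_models(rc, radius = 69e-9)
  expect_equal(as.character(cmp$table$model),
               c("bimodal", "series", "single_term"))
  expect_true(all(diff(cmp$table$s_value) >= 0))
  expect_true(all(cmp$table$n_points == cmp$n_points))
})

test_that("compare_models reports diffusivities and survives model failure", {
  rc <- make_curve(0.254, 1, 0.04, noise_sd = 1, seed = 3)
  cmp <- compare_models(rc, radius = 69e-9)
  bi <- cmp$table[cmp$table$model == "bimodal", ]
  expect_equal(bi$d_fast,
               diffusivity_from_rate(cmp$fits$bimodal$params$k1, 69e-9))
  # without a radius the series model is simply absent, not an error
  cmp2 <- compare_models(rc)
  expect_setequal(names(cmp2$fits), c("bimodal", "single_term"))
  # a curve with only 3 informative points: bimodal fails, others survive
  rc3 <- release_curve(c(1, 2, 3, 4), c(30, 60, 80, 99.5))
  cmp3 <- compare_models(rc3, radius = 69e-9)
  expect_true("bimodal" %in% names(cmp3$errors))
  expect_true("single_term" %in% names(cmp3$fits))
  # empty-after-filter is a structured error
  rc4 <- release_curve(1:4, c(99, 99.2, 99.4, 100))
  expect_error(compare_models(rc4), "uninformative")
})

test_that("fast/slow diffusivities and formulation comparison match hand values", {
  rc_a <- make_curve(0.254, 1, 0.04)
  rc_b <- make_curve(0.29, 1.74, 0.123)
  fit_a <- fit_bimodal(rc_a)
  fit_b <- fit_bimodal(rc_b)
  d <- fast_slow_diffusivities(fit_a, 69e-9)
  expect_equal(d$diffusivity[d$mode == "fast"],
               diffusivity_from_rate(fit_a$params$k1, 69e-9))
  chg <- diffusivity_change(fit_a, fit_b, 69e-9, 71.5e-9)
  expect_equal(chg$pct_change[chg$mode == "fast"], 86, tolerance = 0.02)
  expect_equal(chg$pct_change[chg$mode == "slow"], 230, tolerance = 0.02)
  # identical fits -> 0% change
  chg0 <- diffusivity_change(fit_a, fit_a, 69e-9, 69e-9)
  expect_equal(chg0$pct_change, c(0, 0), tolerance = 1e-9)
  expect_error(fast_slow_diffusivities(fit_single_term(rc_a), 69e-9),
               "bimodal")
})

test_that("tidy and glance return well-formed tibbles", {
  rc <- make_curve(0.29, 1.74, 0.123, noise_sd = 1, seed = 2)
  fit <- fit_bimodal(rc)
  td <- tidy(fit)
  expect_equal(td$term, c("phi", "k1", "k2"))
  gl <- glance(fit)
  expect_equal(gl$model, "bimodal")
  expect_equal(gl$n_points, 30L)
  cmp <- compare_models(rc, radius = 71.5e-9)
  expect_true(all(c("model", "term", "estimate") %in% names(tidy(cmp))))
})
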