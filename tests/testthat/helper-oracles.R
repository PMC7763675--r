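# Independent brute-force oracle for the sphere-diffusion series: a fixed
# 10,000-term partial sum, written without reference to the adaptive
# implementation. Times in days, D in m^2/s, r in meters.
oracle_series_release <- function(t_days, diffusivity, radius,
                                  n_terms = 10000L) {
  i <- seq_len(n_terms)
  vapply(t_days, function(t) {
    tau <- diffusivity * t * 86400 / radius^2
    100 * (1 - (6 / pi^2) * sum(exp(-tau * i^2 * pi^2) / i^2))
  }, numeric(1))
}

# Closed-form bimodal evaluation, independent of the package function.
oracle_bimodal <- function(t_days, phi, k1, k2) {
  100 * (phi * (1 - exp(-k1 * t_days)) + (1 - phi) * (1 - exp(-k2 * t_days)))
}
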