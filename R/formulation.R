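#' Single-point intrinsic viscosity (Solomon-Ciuta)
#'
#' Estimates the intrinsic viscosity of a dilute polymer solution from one
#' capillary-viscometer measurement:
#' \deqn{[\eta] = \frac{[2(t/t_0 - \ln(t/t_0) - 1)]^{1/2}}{c}}
#' with `t` the flow time of the solution, `t0` of the pure solvent and `c`
#' the concentration. Returns exactly 0 in the limit `t = t0`.
#'
#' @param flow_time_solution Solution flow time `t`, seconds.
#' @param flow_time_solvent Solvent flow time `t0`, seconds (0 < t0 <= t).
#' @param concentration Polymer concentration `c`, g/dL (> 0).
#' @return Intrinsic viscosity, dL/g. Vectorised over its arguments.
#' @examples
#' intrinsic_viscosity(2, 1, 1)  # 0.7834 dL/g
#' @export
intrinsic_viscosity <- function(flow_time_solution, flow_time_solvent,
                                concentration) {
  if (any(flow_time_solvent <= 0)) {
    abort("Solvent flow time must be positive.")
  }
  if (any(flow_time_solution < flow_time_solvent)) {
    abort("Solution flow time must be >= solvent flow time.")
  }
  if (any(concentration <= 0)) {
    abort("Concentration must be positive (g/dL).")
  }
  ratio <- flow_time_solution / flow_time_solvent
  arg <- 2 * (ratio - log(ratio) - 1)
  sqrt(pmax(arg, 0)) / concentration
}

#' Viscosity-average molecular weight (Mark-Houwink-Sakurada)
#'
#' Inverts the Mark-Houwink-Sakurada relation `[eta] = k Mv^a`:
#' `Mv = ([eta]/k)^(1/a)`. The defaults are the constants for mPEG-PCL in
#' chloroform at 25 C (`k = 1.09e-3` dL/g, `a = 0.6021`).
#'
#' @param intrinsic_viscosity Intrinsic viscosity, dL/g (> 0).
#' @param k Mark-Houwink prefactor, dL/g (> 0).
#' @param a Mark-Houwink exponent, dimensionless (0 < a < 2).
#' @return Viscosity-average molecular weight, g/mol.
#' @examples
#' mhs_molecular_weight(0.68)  # ~4.4e4 g/mol
#' @export
mhs_molecular_weight <- function(intrinsic_viscosity, k = 1.09e-3, a = 0.6021) {
  if (any(intrinsic_viscosity <= 0)) {
    abort("Intrinsic viscosity must be positive (dL/g).")
  }
  if (any(k <= 0)) abort("`k` must be positive (dL/g).")
  if (any(a <= 0) || any(a >= 2)) abort("`a` must lie in (0, 2).")
  (intrinsic_viscosity / k)^(1 / a)
}

#' Gravimetric weight loss
#'
#' `100 * (W0 - Wr) / W0` for a specimen weighed before (`before`, W0) and
#' after (`after`, Wr) a degradation interval.
#'
#' @param before,after Masses in consistent units (mg), both > 0.
#' @return Weight loss, percent. Vectorised.
#' @export
weight_loss_percent <- function(before, after) {
  if (any(before <= 0) || any(after <= 0)) {
    abort("Masses must be positive.")
  }
  100 * (before - after) / before
}

#' Nanoparticle formulation metrics
#'
#' The three standard preparation ratios:
#' * yield: `100 * nanoparticle mass / initial (polymer + drug) mass`
#' * drug loading: `100 * drug mass in nanoparticles / nanoparticle mass`
#' * entrapment efficiency: `100 * drug mass in nanoparticles / initial drug mass`
#'
#' @param nanoparticle_mass Recovered nanoparticle mass, mg.
#' @param initial_mass Initial polymer + drug mass, mg (> 0).
#' @param drug_mass Drug mass recovered inside the nanoparticles, mg.
#' @param initial_drug_mass Drug mass initially added, mg (> 0).
#' @return Percent values. All functions are vectorised.
#' @examples
#' nanoparticle_yield(70, 100)     # 70 %
#' drug_loading(7.5, 100)          # 7.5 %
#' entrapment_efficiency(7.5, 10)  # 75 %
#' @export
nanoparticle_yield <- function(nanoparticle_mass, initial_mass) {
  if (any(initial_mass <= 0)) abort("Initial mass must be positive.")
  if (any(nanoparticle_mass < 0)) abort("Nanoparticle mass must be >= 0.")
  100 * nanoparticle_mass / initial_mass
}

#' @rdname nanoparticle_yield
#' @export
drug_loading <- function(drug_mass, nanoparticle_mass) {
  if (any(nanoparticle_mass <= 0)) abort("Nanoparticle mass must be positive.")
  if (any(drug_mass < 0)) abort("Drug mass must be >= 0.")
  if (any(drug_mass > nanoparticle_mass)) {
    abort("Drug mass cannot exceed the nanoparticle mass.")
  }
  100 * drug_mass / nanoparticle_mass
}

#' @rdname nanoparticle_yield
#' @export
entrapment_efficiency <- function(drug_mass, initial_drug_mass) {
  if (any(initial_drug_mass <= 0)) abort("Initial drug mass must be positive.")
  if (any(drug_mass < 0)) abort("Drug mass must be >= 0.")
  100 * drug_mass / initial_drug_mass
}

#' Formulation metrics from a table of weighings
#'
#' Convenience wrapper computing yield, drug loading and entrapment
#' efficiency for each row of a weighings table.
#'
#' @param weighings A data frame with columns `nanoparticle_mass`,
#'   `initial_mass`, `drug_mass`, `initial_drug_mass` (mg) and optionally an
#'   identifier column `sample`.
#' @return A tibble with one row per input row: `yield_percent`,
#'   `drug_loading_percent`, `entrapment_efficiency_percent`.
#' @export
formulation_metrics <- function(weighings) {
  needed <- c("nanoparticle_mass", "initial_mass", "drug_mass",
              "initial_drug_mass")
  missing_cols <- setdiff(needed, names(weighings))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing weighing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  out <- tibble(
    yield_percent = nanoparticle_yield(weighings$nanoparticle_mass,
                                       weighings$initial_mass),
    drug_loading_percent = drug_loading(weighings$drug_mass,
                                        weighings$nanoparticle_mass),
    entrapment_efficiency_percent =
      entrapment_efficiency(weighings$drug_mass, weighings$initial_drug_mass)
  )
  if ("sample" %in% names(weighings)) {
    out <- dplyr::bind_cols(tibble(sample = weighings$sample), out)
  }
  out
}
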