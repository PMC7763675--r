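#' Triaxial-ellipsoid guest axes
#'
#' Validates and sorts (ascending) the three full principal-axis lengths of
#' an ellipsoidal guest molecule.
#'
#' @param axes Numeric vector of three positive axis lengths, Angstrom.
#' @return Sorted numeric vector `c(a1, a2, a3)` with `a1 <= a2 <= a3`.
#' @export
ellipsoid_axes <- function(axes) {
  if (!is.numeric(axes) || length(axes) != 3 || anyNA(axes) || any(axes <= 0)) {
    abort("`axes` must be three positive axis lengths (Angstrom).")
  }
  sort(as.numeric(axes))
}

#' Paclitaxel (Taxol) as a triaxial ellipsoid
#'
#' A simplistic rigid-ellipsoid representation of paclitaxel with principal
#' axes 7.9, 15.2 and 18.2 Angstrom, used for pore-passage screening.
#'
#' @return Sorted axis lengths, Angstrom.
#' @export
taxol_axes <- function() c(7.9, 15.2, 18.2)

#' Cage and window dimensions of the Fe-BTC / MIL-100(Fe) topology
#'
#' The MIL-100-type network (Fe-BTC is its semi-amorphous analogue) has two
#' cage types: the s-cage (cavity 24.6 A, reached through 5-membered windows
#' of 7.3 A) and the l-cage (cavity 30.1 A, with additional 6-membered
#' windows of 10.8 A).
#'
#' @return A tibble with columns `feature`, `kind` ("window" or "cavity")
#'   and `diameter_A`.
#' @export
fe_btc_geometry <- function() {
  tibble(
    feature = c("5-membered window", "6-membered window",
                "s-cage cavity", "l-cage cavity"),
    kind = c("window", "window", "cavity", "cavity"),
    diameter_A = c(7.3, 10.8, 24.6, 30.1)
  )
}

#' Can an ellipsoidal guest traverse a circular pore window?
#'
#' A deliberately simple rigid-body screen. For translation along the
#' longest axis the limiting cross-section is the `a1 x a2` ellipse, which
#' fits through a circular window of diameter `d` iff `a2 <= d`
#' (PASSES_FREELY). If only the smallest axis fits (`a1 <= d < a2`) passage
#' is still possible for suitable orientations (PASSES_ORIENTED) - a
#' qualitative tier, since a rigorous tumbling-passage criterion would need
#' path planning. If even `a1` exceeds `d` by no more than `marginal_tol`
#' the window is marginally too small (MARGINALLY_BLOCKED); beyond that,
#' BLOCKED. These tiers are heuristics for screening, not an energetic or
#' flexible-molecule calculation.
#'
#' @param axes Guest principal axes (Angstrom); sorted internally.
#' @param window_diameter Window diameter(s), Angstrom. Vectorised.
#' @param marginal_tol Width of the "marginally blocked" band, Angstrom.
#'   Default 1.0.
#' @param label Optional window label(s) carried into the output.
#' @return A tibble with columns `window_diameter_A`, `verdict` (factor with
#'   levels PASSES_FREELY, PASSES_ORIENTED, MARGINALLY_BLOCKED, BLOCKED) and
#'   `clearance_A` (`d - a1`).
#' @examples
#' classify_passage(taxol_axes(), c(7.3, 10.8))
#' @export
classify_passage <- function(axes, window_diameter, marginal_tol = 1.0,
                             label = NULL) {
  axes <- ellipsoid_axes(axes)
  if (!is.numeric(window_diameter) || any(window_diameter <= 0)) {
    abort("`window_diameter` must be positive (Angstrom).")
  }
  if (!is.numeric(marginal_tol) || length(marginal_tol) != 1 ||
      marginal_tol < 0) {
    abort("`marginal_tol` must be a single non-negative number (Angstrom).")
  }
  a1 <- axes[1]; a2 <- axes[2]
  d <- as.numeric(window_diameter)
  verdict <- dplyr::case_when(
    a2 <= d ~ "PASSES_FREELY",
    a1 <= d ~ "PASSES_ORIENTED",
    a1 <= d + marginal_tol ~ "MARGINALLY_BLOCKED",
    TRUE ~ "BLOCKED"
  )
  out <- tibble(
    window_diameter_A = d,
    verdict = factor(verdict, levels = c("PASSES_FREELY", "PASSES_ORIENTED",
                                         "MARGINALLY_BLOCKED", "BLOCKED")),
    clearance_A = d - a1
  )
  if (!is.null(label)) out <- dplyr::bind_cols(tibble(label = label), out)
  out
}

#' Does an ellipsoidal guest fit inside a spherical cavity?
#'
#' True iff the longest guest axis does not exceed the cavity diameter.
#'
#' @param axes Guest principal axes, Angstrom.
#' @param cavity_diameter Cavity diameter(s), Angstrom. Vectorised.
#' @return Logical vector.
#' @examples
#' fits_in_cavity(taxol_axes(), c(24.6, 30.1))
#' @export
fits_in_cavity <- function(axes, cavity_diameter) {
  axes <- ellipsoid_axes(axes)
  if (!is.numeric(cavity_diameter) || any(cavity_diameter <= 0)) {
    abort("`cavity_diameter` must be positive (Angstrom).")
  }
  axes[3] <= cavity_diameter
}

#' Screen a guest against the built-in Fe-BTC geometry
#'
#' Runs [classify_passage()] on every window and [fits_in_cavity()] on every
#' cavity of [fe_btc_geometry()] (or a user-supplied table of the same
#' shape).
#'
#' @param axes Guest principal axes, Angstrom. Default [taxol_axes()].
#' @param geometry A tibble like [fe_btc_geometry()].
#' @param marginal_tol Passed to [classify_passage()].
#' @return A tibble with one row per feature: `feature`, `kind`,
#'   `diameter_A`, `verdict` (windows; for cavities FITS/DOES_NOT_FIT) and
#'   `clearance_A`.
#' @export
passage_screen <- function(axes = taxol_axes(), geometry = fe_btc_geometry(),
                           marginal_tol = 1.0) {
  axes <- ellipsoid_axes(axes)
  win <- geometry[geometry$kind == "window", , drop = FALSE]
  cav <- geometry[geometry$kind == "cavity", , drop = FALSE]
  rows <- list()
  if (nrow(win) > 0) {
    cls <- classify_passage(axes, win$diameter_A, marginal_tol)
    rows$win <- tibble(feature = win$feature, kind = "window",
                       diameter_A = win$diameter_A,
                       verdict = as.character(cls$verdict),
                       clearance_A = cls$clearance_A)
  }
  if (nrow(cav) > 0) {
    fits <- fits_in_cavity(axes, cav$diameter_A)
    rows$cav <- tibble(feature = cav$feature, kind = "cavity",
                       diameter_A = cav$diameter_A,
                       verdict = ifelse(fits, "FITS", "DOES_NOT_FIT"),
                       clearance_A = cav$diameter_A - axes[3])
  }
  dplyr::bind_rows(rows)
}
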