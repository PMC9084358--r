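#' Carbon-isotope delta convention
#'
#' Bundles the reference \eqn{^{13}C/^{12}C} ratio used to convert between
#' isotopologue ratios and delta notation. The default is the VPDB (Vienna Pee
#' Dee Belemnite) standard, \eqn{^{13}R_{std} = 1.12372\% = 0.0112372}.
#'
#' @param r_std Dimensionless \eqn{^{13}C/^{12}C} ratio of the reference
#'   material. Must be a single positive finite number.
#' @return An object of class `delta_convention`.
#' @examples
#' conv <- delta_convention()
#' delta_from_ratio(conv$r_std, conv)  # 0 permil by construction
#' @export
delta_convention <- function(r_std = 0.0112372) {
  stopifnot(is.numeric(r_std), length(r_std) == 1L, is.finite(r_std),
            r_std > 0)
  structure(list(r_std = r_std), class = "delta_convention")
}

#' Convert delta values (permil) to isotope ratios
#'
#' @param delta Numeric vector of delta values in permil.
#' @param conv A [delta_convention()].
#' @return Numeric vector of \eqn{^{13}C/^{12}C} ratios.
#' @export
ratio_from_delta <- function(delta, conv = delta_convention()) {
  if (!all(is.finite(delta))) stop("non-finite delta value")
  if (any(delta <= -1000)) {
    stop("delta at or below -1000 permil implies a non-positive isotope ratio")
  }
  conv$r_std * (1 + delta / 1000)
}

#' Convert isotope ratios to delta values (permil)
#'
#' @param ratio Numeric vector of \eqn{^{13}C/^{12}C} ratios (> 0).
#' @inheritParams ratio_from_delta
#' @return Numeric vector of delta values in permil.
#' @export
delta_from_ratio <- function(ratio, conv = delta_convention()) {
  if (!all(is.finite(ratio))) stop("non-finite isotope ratio")
  1000 * (ratio / conv$r_std - 1)
}

#' Mixing-ratio / mass unit convention
#'
#' Linear conversion between the global mean CH4 mixing ratio (ppb) and the
#' total atmospheric CH4 mass (Tg). The default factor, 2.767 Tg per ppb, is
#' the standard whole-atmosphere value derived from the dry air mass and the
#' CH4/air molar-mass ratio with the conventional correction for incomplete
#' stratospheric mixing. Hemispheric boxes are taken to hold equal air masses,
#' so at equal mixing ratios each box carries half the global mass.
#'
#' @param tg_per_ppb Tg of CH4 per ppb of global mean mixing ratio.
#' @return An object of class `unit_convention`.
#' @export
unit_convention <- function(tg_per_ppb = 2.767) {
  stopifnot(is.numeric(tg_per_ppb), length(tg_per_ppb) == 1L,
            is.finite(tg_per_ppb), tg_per_ppb > 0)
  structure(list(tg_per_ppb = tg_per_ppb), class = "unit_convention")
}

#' Convert mixing ratio (ppb) to total atmospheric mass (Tg) and back
#'
#' @param x Numeric vector: mixing ratios in ppb (`ppb_to_tg`) or masses in Tg
#'   (`tg_to_ppb`). Must be non-negative and finite.
#' @param units A [unit_convention()].
#' @return Numeric vector in the converted unit.
#' @export
ppb_to_tg <- function(x, units = unit_convention()) {
  if (!all(is.finite(x))) stop("non-finite mixing ratio")
  if (any(x < 0)) stop("negative mixing ratio")
  x * units$tg_per_ppb
}

#' @rdname ppb_to_tg
#' @export
tg_to_ppb <- function(x, units = unit_convention()) {
  if (!all(is.finite(x))) stop("non-finite mass")
  if (any(x < 0)) stop("negative mass")
  x / units$tg_per_ppb
}

#' Split a bulk CH4 flux into its isotopologues
#'
#' Exact two-isotopologue bookkeeping: the returned components satisfy
#' `s12 + s13 == flux` and `s13/s12 == r_std * (1 + delta/1000)`. This avoids
#' the ~1% bias of the common approximation `s13 = R * flux`.
#'
#' @param flux Non-negative flux (Tg CH4 / yr), vectorized.
#' @param delta Source signature in permil, vectorized (recycled against
#'   `flux`).
#' @param conv A [delta_convention()].
#' @return List with numeric components `s12` and `s13` (Tg / yr).
#' @export
split_isotopologues <- function(flux, delta, conv = delta_convention()) {
  if (!all(is.finite(flux))) stop("non-finite flux")
  if (any(flux < 0)) stop("negative flux")
  r <- ratio_from_delta(delta, conv)
  s13 <- flux * r / (1 + r)
  list(s12 = flux - s13, s13 = s13)
}

#' Recover the delta value of a (12C, 13C) flux or mass pair
#'
#' Inverse of [split_isotopologues()].
#'
#' @param s12,s13 Numeric vectors of isotopologue amounts; `s12` must be
#'   positive.
#' @param conv A [delta_convention()].
#' @return Delta values in permil.
#' @export
combine_isotopologues <- function(s12, s13, conv = delta_convention()) {
  if (any(s12 <= 0)) stop("12C component must be positive to form a ratio")
  delta_from_ratio(s13 / s12, conv)
}

# fraction of a bulk flux carried by 13CH4 for signature delta (vectorized)
q13_fraction <- function(delta, conv = delta_convention()) {
  r <- ratio_from_delta(delta, conv)
  r / (1 + r)
}
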