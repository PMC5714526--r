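#' Physical unit constants for the dose normalization chain
#'
#' The conversion chain from scored energy per primary photon to clinical
#' units assumes one primary photon per history and `yield` emitted photons
#' per decay: contained activity of 1 mCi is exactly 3.7e7 decays per second.
#'
#' @return A named list: `decays_per_s_per_mCi` (3.7e7), `joule_per_keV`,
#'   `s_per_h` (3600), `cGy_per_Gy` (100), `g_per_kg` (1000).
#' @export
unit_constants <- function() {
  list(decays_per_s_per_mCi = 3.7e7,
       joule_per_keV = 1.602176634e-16,
       s_per_h = 3600,
       cGy_per_Gy = 100,
       g_per_kg = 1000)
}

#' Convert scored energy per history to a clinical dose rate
#'
#' Converts collision kerma scored as keV per primary photon in a bin of
#' known mass to cGy/h per mCi of contained activity:
#' `rate = (E / m) * J_per_keV * g_per_kg * decays_per_s * yield * s_per_h *
#' cGy_per_Gy`.
#'
#' @param energy_keV_per_history scored energy in keV per primary photon.
#' @param bin_mass_g bin mass in grams, must be positive.
#' @param yield photons emitted per decay.
#' @param constants a list as returned by [unit_constants()].
#' @return Dose rate in cGy/h/mCi.
#' @examples
#' # 1 GeV-equivalent per history in 1 g with yield 1:
#' per_history_to_clinical(1e6, 1, 1)
#' @export
per_history_to_clinical <- function(energy_keV_per_history, bin_mass_g, yield,
                                    constants = unit_constants()) {
  if (any(bin_mass_g <= 0)) stop("degenerate bin: non-positive mass")
  gy_per_history <- energy_keV_per_history * constants$joule_per_keV *
    constants$g_per_kg / bin_mass_g
  gy_per_history * constants$decays_per_s_per_mCi * yield *
    constants$s_per_h * constants$cGy_per_Gy
}
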