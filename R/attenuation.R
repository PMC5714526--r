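.xsec_cache <- new.env(parent = emptyenv())

element_xsec <- function(symbol) {
  if (!is.null(.xsec_cache[[symbol]])) return(.xsec_cache[[symbol]])
  path <- file.path(.ybdosim_extdata("xsec"), paste0(symbol, ".txt"))
  if (!file.exists(path)) stop("no packaged interaction data for ", symbol)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("energy_keV", "pe", "incoh", "coh",
                                         "muen"))
  .xsec_cache[[symbol]] <- tab
  tab
}

element_formfactor_coefs <- function() {
  if (!is.null(.xsec_cache[["..ff"]])) return(.xsec_cache[["..ff"]])
  path <- file.path(.ybdosim_extdata("xsec"), "formfactors.txt")
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("element", paste0("a", 1:4),
                                         paste0("b", 1:4), "c"))
  rownames(tab) <- tab$element
  .xsec_cache[["..ff"]] <- tab
  tab
}

# IT92 form factor with s^-2 continuation beyond the fit validity (s > 2 1/A)
form_factor <- function(symbol, s) {
  co <- element_formfactor_coefs()[symbol, ]
  f_of <- function(sv) {
    co$a1 * exp(-co$b1 * sv^2) + co$a2 * exp(-co$b2 * sv^2) +
      co$a3 * exp(-co$b3 * sv^2) + co$a4 * exp(-co$b4 * sv^2) + co$c
  }
  out <- f_of(pmin(s, 2))
  big <- s > 2
  out[big] <- out[big] * (2 / s[big])^2
  out
}

#' Photon interaction coefficients of a material
#'
#' Builds the mass attenuation table of a compound from the packaged
#' per-element data using the mixture rule: each partial coefficient of the
#' compound is the mass-fraction weighted sum of the elemental coefficients.
#' Partial processes are photoelectric absorption, incoherent (Compton)
#' scattering, and coherent (Rayleigh) scattering; `muen` is the mass
#' energy-absorption coefficient.
#'
#' @param material a [material_spec()].
#' @return An object of class `attenuation_table`: a data.frame with columns
#'   `energy_keV`, `pe`, `incoh`, `coh`, `total`, `muen` (cm^2/g), carrying
#'   the material as an attribute.
#' @examples
#' atab <- attenuation_table(builtin_material("water"))
#' range(atab$energy_keV)
#' @export
attenuation_table <- function(material) {
  stopifnot(inherits(material, "material_spec"))
  comp <- material$composition
  grids <- lapply(names(comp), function(s) element_xsec(s))
  energy <- grids[[1L]]$energy_keV
  acc <- matrix(0, nrow = length(energy), ncol = 4L,
                dimnames = list(NULL, c("pe", "incoh", "coh", "muen")))
  for (i in seq_along(comp)) {
    g <- grids[[i]]
    for (col in colnames(acc)) {
      cn <- if (col == "muen") "muen" else col
      acc[, col] <- acc[, col] + comp[[i]] * loglog_interp(
        g$energy_keV, g[[cn]], energy)
    }
  }
  out <- data.frame(energy_keV = energy, pe = acc[, "pe"],
                    incoh = acc[, "incoh"], coh = acc[, "coh"],
                    total = acc[, "pe"] + acc[, "incoh"] + acc[, "coh"],
                    muen = acc[, "muen"])
  structure(out, material = material, class = c("attenuation_table",
                                                "data.frame"))
}

# log-log interpolation, tolerant of zeros (photoelectric for H is ~0 at the
# top of the grid); exact at nodes
loglog_interp <- function(x, y, xout) {
  eps <- 1e-300
  exp(stats::approx(log(x), log(pmax(y, eps)), log(xout), rule = 1)$y)
}

check_energy_range <- function(tab, energy_keV) {
  rng <- range(tab$energy_keV)
  if (any(energy_keV < rng[1L] - 1e-9) || any(energy_keV > rng[2L] + 1e-9)) {
    stop("energy outside tabulated range [", rng[1L], ", ", rng[2L], "] keV")
  }
}

#' Mass attenuation and linear attenuation coefficients
#'
#' `mu_over_rho()` interpolates the total mass attenuation coefficient
#' (cm^2/g) of a material at the requested energies (log-log interpolation,
#' exact at table nodes); `mu_total()` multiplies by the material density to
#' give the linear coefficient in 1/cm. `mu_en_over_rho()` interpolates the
#' mass energy-absorption coefficient.
#'
#' @param material a [material_spec()].
#' @param energy_keV photon energies in keV, within the tabulated range.
#' @param table optionally, a precomputed [attenuation_table()] for the
#'   material (avoids rebuilding it in hot loops).
#' @return Numeric vector, cm^2/g for the mass coefficients and 1/cm for
#'   `mu_total()`.
#' @examples
#' mu_total(builtin_material("water"), 100)  # about 0.17 1/cm
#' @export
mu_over_rho <- function(material, energy_keV, table = NULL) {
  if (is.null(table)) table <- attenuation_table(material)
  check_energy_range(table, energy_keV)
  loglog_interp(table$energy_keV, table$total, energy_keV)
}

#' @rdname mu_over_rho
#' @export
mu_total <- function(material, energy_keV, table = NULL) {
  mu_over_rho(material, energy_keV, table) * material$density
}

#' @rdname mu_over_rho
#' @export
mu_en_over_rho <- function(material, energy_keV, table = NULL) {
  if (is.null(table)) table <- attenuation_table(material)
  check_energy_range(table, energy_keV)
  loglog_interp(table$energy_keV, table$muen, energy_keV)
}

#' Compton kinematics: scattered photon energy at a given angle
#'
#' @param energy_keV incident photon energy in keV.
#' @param theta polar scattering angle in radians.
#' @return Scattered photon energy in keV,
#'   `E / (1 + (E/m_e c^2)(1 - cos(theta)))`.
#' @examples
#' compton_scattered_energy(100, pi)  # 71.9 keV backscatter
#' @export
compton_scattered_energy <- function(energy_keV, theta) {
  energy_keV / (1 + (energy_keV / 510.99895) * (1 - cos(theta)))
}

#' Sample Compton scattering from the Klein-Nishina distribution
#'
#' Draws (scattered energy, polar scattering angle) pairs from the
#' free-electron Klein-Nishina differential cross section using Kahn's
#' composition-rejection method; the returned energy obeys the Compton
#' kinematic relation for the sampled angle exactly. Uses R's random stream.
#'
#' @param energy_keV incident photon energy (keV), scalar, > 0.
#' @param n number of samples.
#' @return A data.frame with columns `energy_keV` (scattered energy) and
#'   `theta` (scattering angle, radians); attribute `"efficiency"` holds the
#'   rejection-sampling acceptance fraction.
#' @examples
#' set.seed(1)
#' s <- sample_compton(93, 1000)
#' @export
sample_compton <- function(energy_keV, n) {
  stopifnot(length(energy_keV) == 1L, energy_keV > 0, n >= 1L)
  m <- cpp_sample_compton(energy_keV, as.integer(n))
  out <- data.frame(energy_keV = m[, 1L], theta = acos(m[, 2L]))
  attr(out, "efficiency") <- attr(m, "efficiency")
  out
}

#' Sample the interaction type at a collision
#'
#' Draws one of photoelectric, Compton (incoherent) or Rayleigh (coherent)
#' with probability proportional to the material's partial attenuation
#' coefficients at the given energy.
#'
#' @param material a [material_spec()].
#' @param energy_keV photon energy in keV (scalar).
#' @param n number of draws.
#' @param table optional precomputed [attenuation_table()].
#' @return Character vector of `"photoelectric"`, `"compton"`, `"rayleigh"`.
#' @export
sample_interaction_type <- function(material, energy_keV, n, table = NULL) {
  if (is.null(table)) table <- attenuation_table(material)
  check_energy_range(table, energy_keV)
  p <- c(photoelectric = loglog_interp(table$energy_keV, table$pe, energy_keV),
         compton = loglog_interp(table$energy_keV, table$incoh, energy_keV),
         rayleigh = loglog_interp(table$energy_keV, table$coh, energy_keV))
  p[p < 1e-290] <- 0
  sample(names(p), n, replace = TRUE, prob = p)
}

# Coherent-scattering angular sampling table for a material: cumulative
# integral of the squared molecular form factor over x = s^2 (s in 1/A).
# Used by the transport kernel; x_max covers backscatter at 400 keV.
rayleigh_sampling_table <- function(material, n = 400L, x_max = 1100) {
  comp <- material$composition
  ff <- element_formfactor_coefs()
  x <- c(0, 10^seq(-6, log10(x_max), length.out = n - 1L))
  s <- sqrt(x)
  g <- numeric(length(x))
  amass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, Si = 28.085,
             P = 30.974, S = 32.06, Ar = 39.948, Ti = 47.867, Cr = 51.996,
             Mn = 54.938, Fe = 55.845, Ni = 58.693, Mo = 95.95, Yb = 173.045)
  for (el in names(comp)) {
    g <- g + comp[[el]] / amass[[el]] * form_factor(el, s)^2
  }
  cdf <- cumsum(c(0, diff(x)) * (g + c(g[1L], g[-length(g)])) / 2)
  list(x = x, cdf = cdf)
}
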