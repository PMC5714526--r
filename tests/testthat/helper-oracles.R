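# Independent oracles and small builders used across the test files.

# brute-force line-source geometry function: numerical integration of
# 1/|x - s|^2 over the active segment, divided by L
gl_numeric <- function(r, theta_deg, L) {
  th <- theta_deg * pi / 180
  y <- r * sin(th)
  z <- r * cos(th)
  f <- function(s) 1 / (y^2 + (z - s)^2)
  stats::integrate(f, -L / 2, L / 2, rel.tol = 1e-10)$value / L
}

# Klein-Nishina differential cross section in mu = cos(theta), unnormalized
kn_dsigma_dmu <- function(E, mu) {
  a <- E / 510.99895
  k <- 1 / (1 + a * (1 - mu))
  k^2 * (k + 1 / k - (1 - mu^2))
}

# quadrature mean of the scattered photon energy under Klein-Nishina
kn_mean_scattered <- function(E) {
  a <- E / 510.99895
  num <- stats::integrate(function(mu) {
    kn_dsigma_dmu(E, mu) * E / (1 + a * (1 - mu))
  }, -1, 1, rel.tol = 1e-10)$value
  den <- stats::integrate(function(mu) kn_dsigma_dmu(E, mu), -1, 1,
                          rel.tol = 1e-10)$value
  num / den
}

# an unencapsulated near-point source in water (for closed-form transport
# oracles: every region is water so the phantom is homogeneous)
bare_point_model <- function(spectrum = yb169_spectrum(),
                             radius = 1e-4, length = 1e-3) {
  water <- builtin_material("water")
  source_model(list(list(name = "core", radius = radius,
                         zmin = -length / 2, zmax = length / 2,
                         material = water)),
               active_length = length, spectrum = spectrum)
}

# closed-form primary (first-collision) kerma rate averaged over a
# transverse-axis bin of the default grid, for a bare point source
primary_rate_oracle <- function(spectrum, r_lo, r_hi) {
  water <- builtin_material("water")
  wtab <- attenuation_table(water)
  li <- spectrum$lines
  p <- li$intensity / sum(li$intensity)
  total <- 0
  for (i in seq_len(nrow(li))) {
    E <- li$energy_keV[i]
    mu <- mu_total(water, E, wtab)
    muen <- mu_en_over_rho(water, E, wtab)
    # volume average of exp(-mu r) / (4 pi r^2) over the shell:
    # [int 4 pi r^2 f(r) dr] / [(4 pi / 3)(r_hi^3 - r_lo^3)]
    avg <- stats::integrate(function(r) exp(-mu * r), r_lo, r_hi,
                            rel.tol = 1e-10)$value /
      ((4 * pi / 3) * (r_hi^3 - r_lo^3))
    total <- total + p[i] * E * muen * avg
  }
  per_history_to_clinical(total, 1, spectrum$total_yield)
}
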