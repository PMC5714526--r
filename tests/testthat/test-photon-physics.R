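water <- builtin_material("water")
wtab <- attenuation_table(water)

test_that("interpolation reproduces table nodes exactly and obeys the mixture rule", {
  idx <- c(1L, 10L, 25L, nrow(wtab))
  expect_equal(mu_over_rho(water, wtab$energy_keV[idx], wtab),
               wtab$total[idx], tolerance = 1e-12)
  expect_equal(mu_en_over_rho(water, wtab$energy_keV[idx], wtab),
               wtab$muen[idx], tolerance = 1e-12)
  # partial coefficients sum to the total at every node
  expect_equal(wtab$total, wtab$pe + wtab$incoh + wtab$coh,
               tolerance = 1e-12)
  # mixture rule: compound equals the mass-fraction weighted element sum
  o <- ybdosim:::element_xsec("O")
  h <- ybdosim:::element_xsec("H")
  manual <- 0.111894 * h$incoh + 0.888106 * o$incoh
  expect_equal(wtab$incoh[match(o$energy_keV, wtab$energy_keV)], manual,
               tolerance = 1e-9)
  # out-of-range energies are a data-range error
  expect_error(mu_total(water, 5), "range")
  expect_error(mu_total(water, 1000), "range")
})

test_that("water attenuation matches reference values and is monotone 60-300 keV", {
  expect_equal(mu_total(water, 100), 0.171, tolerance = 0.02)
  # doubling density doubles mu
  w2 <- material_spec("water2", 2 * water$density, water$composition)
  expect_equal(mu_total(w2, 80), 2 * mu_total(water, 80), tolerance = 1e-12)
  ee <- seq(60, 300, by = 5)
  expect_true(all(diff(mu_over_rho(water, ee, wtab)) < 0))
})

test_that("Compton kinematics and Klein-Nishina sampling match closed forms", {
  # 180-degree scatter of 100 keV -> E / (1 + 2 E / mec2)
  expect_equal(compton_scattered_energy(100, pi), 71.9, tolerance = 1e-3)
  expect_equal(compton_scattered_energy(100, pi),
               100 / (1 + 2 * 100 / 510.99895), tolerance = 1e-12)
  set.seed(42)
  s <- sample_compton(93, 1e6)
  # sampled energies obey the kinematic relation for the sampled angle
  expect_equal(s$energy_keV[1:1000],
               compton_scattered_energy(93, s$theta[1:1000]),
               tolerance = 1e-9)
  # mean scattered energy vs quadrature of the closed-form cross section
  expect_equal(mean(s$energy_keV), kn_mean_scattered(93), tolerance = 0.005)
  # rejection efficiency above 0.3 across the energy range
  for (E in c(10, 93, 350)) {
    set.seed(E)
    expect_gt(attr(sample_compton(E, 2e4), "efficiency"), 0.3)
  }
})

test_that("sampled Klein-Nishina angular distribution passes a chi-squared test", {
  set.seed(2024)
  s <- sample_compton(93, 1e6)
  mu <- cos(s$theta)
  breaks <- seq(-1, 1, length.out = 51)
  obs <- as.numeric(table(cut(mu, breaks, include.lowest = TRUE)))
  p <- vapply(seq_len(50), function(i) {
    stats::integrate(function(m) kn_dsigma_dmu(93, m), breaks[i],
                     breaks[i + 1L], rel.tol = 1e-9)$value
  }, 0)
  p <- p / sum(p)
  expect_gt(stats::chisq.test(obs, p = p)$p.value, 0.01)
})

test_that("low-energy Compton limit is symmetric about 90 degrees (Thomson)", {
  set.seed(5)
  mu <- cos(sample_compton(0.5, 2e5)$theta)
  expect_lt(abs(mean(mu)), 4 * sd(mu) / sqrt(2e5))
})

test_that("interaction types are drawn proportionally to partial coefficients", {
  set.seed(9)
  n <- 1e5
  E <- 50
  draws <- sample_interaction_type(water, E, n, wtab)
  p <- c(ybdosim:::loglog_interp(wtab$energy_keV, wtab$pe, E),
         ybdosim:::loglog_interp(wtab$energy_keV, wtab$incoh, E),
         ybdosim:::loglog_interp(wtab$energy_keV, wtab$coh, E))
  p <- p / sum(p)
  counts <- as.numeric(table(factor(draws, c("photoelectric", "compton",
                                             "rayleigh"))))
  expect_true(all(abs(counts - n * p) <= 4 * sqrt(n * p * (1 - p))))
  # a material with no photoelectric partial never returns photoelectric:
  # hydrogen's photoelectric coefficient vanishes at high energy
  htab <- attenuation_table(material_spec("h", 1, c(H = 1)))
  set.seed(10)
  d2 <- sample_interaction_type(material_spec("h", 1, c(H = 1)), 350, 1e4,
                                htab)
  expect_lt(mean(d2 == "photoelectric"), 1e-3)
  # photoelectric fraction strictly larger at 30 than 300 keV
  frac <- function(E) {
    pe <- ybdosim:::loglog_interp(wtab$energy_keV, wtab$pe, E)
    pe / ybdosim:::loglog_interp(wtab$energy_keV, wtab$total, E)
  }
  expect_gt(frac(30), frac(300))
})
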