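test_that("fixed seed gives bit-identical dose tables", {
  m <- build_default_m42()
  cfg <- simulation_config(n_histories = 2e4, seed = 123, n_batch = 4)
  a <- run_water_phantom(m, cfg = cfg)
  b <- run_water_phantom(m, cfg = cfg)
  expect_identical(a$dose_rate, b$dose_rate)
  expect_identical(a$rel_err, b$rel_err)
  c2 <- run_water_phantom(m, cfg = simulation_config(n_histories = 2e4,
                                                     seed = 124, n_batch = 4))
  expect_false(identical(a$dose_rate, c2$dose_rate))
})

test_that("no particles are lost and energy bookkeeping is consistent", {
  m <- build_default_m42()
  tab <- run_water_phantom(m, cfg = simulation_config(n_histories = 5e4,
                                                      seed = 21))
  meta <- attr(tab, "meta")
  expect_equal(meta$lost, 0)
  expect_lt(meta$deposited_keV, meta$emitted_keV)
  expect_gt(meta$deposited_keV, 0)
  # zero-score bins are flagged with undefined uncertainty, not zero
  zero <- tab$dose_rate == 0
  if (any(zero)) expect_true(all(is.na(tab$rel_err[zero])))
})

test_that("attenuation-free point source follows the inverse-square law", {
  m <- bare_point_model()
  tab <- run_water_phantom(m, cfg = simulation_config(
    n_histories = 2e5, seed = 31, interactions = "none",
    estimator = "tracklength"))
  g <- ring_detector_grid()
  tr <- subset(tab, theta_deg == 90)
  # fluence-kerma in each shell should scale as the volume-averaged 1/r^2
  invr2 <- 3 * (g$r_hi - g$r_lo) / (g$r_hi^3 - g$r_lo^3)
  ratio <- tr$dose_rate / invr2
  rel <- subset(tab, theta_deg == 90)$rel_err
  expect_true(all(abs(ratio / ratio[2L] - 1) <= 3 * sqrt(rel^2 + rel[2L]^2)
                  + 0.01))
})

test_that("primary-only kerma matches the closed-form attenuation oracle", {
  sp <- yb169_spectrum()
  m <- bare_point_model(sp)
  tab <- run_water_phantom(m, cfg = simulation_config(
    n_histories = 4e5, seed = 41, interactions = "primary_only"))
  g <- ring_detector_grid()
  for (node in c(1, 2, 5)) {
    i <- which(g$radial_nodes == node)
    cell <- subset(tab, r_cm == node & theta_deg == 90)
    oracle <- primary_rate_oracle(sp, g$r_lo[i], g$r_hi[i])
    tol <- 3 * cell$rel_err + 0.02  # 3 sigma plus interpolation slack
    expect_lt(abs(cell$dose_rate / oracle - 1), tol)
  }
})

test_that("unscattered survival through water follows exp(-mu r)", {
  # single 100 keV line: the ratio of primary kerma in successive shells
  # isolates exp(-mu dr) since the 1/r^2 and mu_en factors cancel in the
  # oracle ratio
  sp <- emission_spectrum(100, 1)
  m <- bare_point_model(sp)
  tab <- run_water_phantom(m, cfg = simulation_config(
    n_histories = 4e5, seed = 43, interactions = "primary_only"))
  g <- ring_detector_grid()
  c1 <- subset(tab, r_cm == 1 & theta_deg == 90)
  c3 <- subset(tab, r_cm == 3 & theta_deg == 90)
  o1 <- primary_rate_oracle(sp, g$r_lo[2L], g$r_hi[2L])
  o3 <- primary_rate_oracle(sp, g$r_lo[4L], g$r_hi[4L])
  rel <- sqrt(c1$rel_err^2 + c3$rel_err^2)
  expect_lt(abs((c3$dose_rate / c1$dose_rate) / (o3 / o1) - 1), 3 * rel + 0.01)
})

test_that("air-kerma scoring matches the closed-form vacuum oracle", {
  sp <- emission_spectrum(100, 1)
  m <- bare_point_model(sp)
  ak <- run_air_kerma(m, cfg = simulation_config(n_histories = 2e5,
                                                 seed = 51))
  air <- builtin_material("air")
  keV_per_g <- 100 * mu_en_over_rho(air, 100) / (4 * pi * 100^2)
  oracle <- per_history_to_clinical(keV_per_g, 1, sp$total_yield)
  expect_lt(abs(ak$kerma_rate / oracle - 1), 3 * ak$rel_err + 0.005)
  expect_equal(ak$sk, air_kerma_strength(ak$kerma_rate, 100))
})

test_that("batch-means relative error scales as one over root N", {
  m <- build_default_m42()
  # average the per-bin log relative errors over the well-populated inner
  # bins, in the regime where every batch holds many collisions: bins with
  # only a few collisions per batch underestimate their own sigma and would
  # bias the scaling measurement
  ns <- c(5e5, 1.58e6, 5e6)
  mean_log_rel <- vapply(ns, function(n) {
    tab <- run_water_phantom(m, cfg = simulation_config(
      n_histories = n, seed = 61, n_batch = 25))
    ok <- is.finite(tab$rel_err) & tab$rel_err > 0 & tab$r_cm <= 3
    mean(log10(tab$rel_err[ok]))
  }, 0)
  slope <- stats::coef(stats::lm(mean_log_rel ~ log10(ns)))[[2L]]
  expect_equal(slope, -0.5, tolerance = 0.05 / 0.5)
})

test_that("cylindrical region binning re-binned to the polar grid agrees with direct scoring", {
  m <- build_default_m42()
  sph <- run_water_phantom(m, cfg = simulation_config(n_histories = 4e5,
                                                      seed = 71))
  cyl <- run_water_phantom(m, cfg = simulation_config(
    n_histories = 4e5, seed = 71, scoring = "cylindrical"))
  for (node in c(1, 2, 4)) {
    a <- subset(sph, r_cm == node & theta_deg == 90)
    b <- subset(cyl, r_cm == node & theta_deg == 90)
    expect_lt(abs(b$dose_rate / a$dose_rate - 1), 6 * a$rel_err + 0.15)
  }
})

test_that("duplicate azimuthal cells merge into the canonical table", {
  tab <- polar_dose_table(c(1, 1, 2), c(90, 90, 90), c(1.2, 1.3, 0.3),
                          c(0.02, 0.02, 0.02))
  merged <- average_symmetric_bins(tab)
  expect_equal(nrow(merged), 2L)
  # inverse-variance weights from the absolute sigmas 0.024 and 0.026
  w <- 1 / c(0.024, 0.026)^2
  expect_equal(merged$dose_rate[merged$r_cm == 1],
               sum(w * c(1.2, 1.3)) / sum(w))
})
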