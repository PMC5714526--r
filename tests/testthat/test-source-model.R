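test_that("default seed model has the documented geometry and materials", {
  m <- build_default_m42()
  expect_equal(m$active_length, 0.6)
  expect_equal(m$regions[[1L]]$material$name, "yb2o3")
  expect_equal(m$regions[[1L]]$material$density, 7.1)
  expect_equal(m$regions[[2L]]$material$density, 4.51)
  ss <- m$regions[[3L]]$material
  expect_equal(ss$density, 7.80)
  expect_equal(unname(ss$composition[["Fe"]]), 0.69095)
  expect_equal(sum(ss$composition), 1, tolerance = 1e-9)
  # cable on the negative-z (theta = 180) side
  cab <- m$regions[[4L]]
  expect_lt(cab$zmax, 0)
  # dimensions overridable, invalid overrides rejected
  m2 <- build_default_m42(list(core_radius = 0.03))
  expect_equal(m2$regions[[1L]]$radius, 0.03)
  expect_error(build_default_m42(list(core_density = 0)), "density")
  expect_error(build_default_m42(list(not_a_key = 1)), "not_a_key")
})

test_that("spectrum mean energy is intensity-weighted and near 93 keV", {
  expect_equal(spectrum_mean_energy(emission_spectrum(50, 1)), 50)
  expect_equal(spectrum_mean_energy(emission_spectrum(c(60, 120), c(1, 1))),
               90)
  sp <- yb169_spectrum()
  expect_equal(spectrum_mean_energy(sp), 93, tolerance = 1 / 93)
  expect_equal(sp$total_yield, sum(sp$lines$intensity), tolerance = 1e-12)
  expect_true(all(diff(sp$lines$energy_keV) > 0))
  expect_error(emission_spectrum(numeric(0), numeric(0)), "empty")
  expect_error(emission_spectrum(c(-5, 10), c(1, 1)), "positive")
})

test_that("sampled decays are uniform in the core with isotropic emission", {
  m <- build_default_m42()
  set.seed(101)
  d <- sample_decay(m, 1e5)
  # every position inside the active core
  core <- m$regions[[1L]]
  rho <- sqrt(d$position[, 1L]^2 + d$position[, 2L]^2)
  expect_true(all(rho <= core$radius))
  expect_true(all(d$position[, 3L] >= core$zmin &
                    d$position[, 3L] <= core$zmax))
  expect_true(all(locate_region(m, d$position) == "core"))
  # unit directions with CLT-bounded mean (3/sqrt(N) isotropy bound)
  expect_equal(rowSums(d$direction^2)[1:100], rep(1, 100), tolerance = 1e-12)
  expect_lt(sqrt(sum(colMeans(d$direction)^2)), 3 / sqrt(1e5))
  # mean emitted energy close to the 93 keV spectrum average
  expect_equal(mean(d$energy_keV), spectrum_mean_energy(m$spectrum),
               tolerance = 1 / 93)
  expect_lt(abs(mean(d$energy_keV) - 93), 1)
  # single-line spectrum: every draw is that line
  m1 <- build_default_m42(list(spectrum = emission_spectrum(77, 2)))
  set.seed(1)
  expect_true(all(sample_decay(m1, 1000)$energy_keV == 77))
})

test_that("line sampling frequencies match intensities (multinomial 4 sigma)", {
  m <- build_default_m42()
  set.seed(7)
  n <- 2e5
  e <- sample_decay(m, n)$energy_keV
  li <- m$spectrum$lines
  p <- li$intensity / sum(li$intensity)
  counts <- table(factor(e, levels = li$energy_keV))
  expect_true(all(abs(as.numeric(counts) - n * p) <=
                    4 * sqrt(n * p * (1 - p))))
})

test_that("every point maps to exactly one region or the medium", {
  m <- build_default_m42()
  set.seed(3)
  pts <- cbind(runif(2e4, -0.1, 0.1), runif(2e4, -0.1, 0.1),
               runif(2e4, -0.7, 0.7))
  reg <- locate_region(m, pts)
  expect_true(all(reg %in% c("core", "capsule_ti", "capsule_ss", "cable",
                             "medium")))
  # manual exclusive classification must agree
  rho2 <- pts[, 1L]^2 + pts[, 2L]^2
  z <- pts[, 3L]
  core <- rho2 <= 0.025^2 & abs(z) <= 0.3
  expect_identical(reg == "core", core)
})
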