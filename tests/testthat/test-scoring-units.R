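test_that("grid construction matches the canonical table layout", {
  g <- ring_detector_grid()
  expect_equal(nrow(g$bins), 209)
  expect_equal(g$radial_nodes, c(0.5, 1:10))
  expect_equal(g$polar_nodes, seq(0, 180, 10))
  # caps are full cones, no azimuthal seam
  expect_equal(g$theta_lo[1L], 0)
  expect_equal(g$theta_hi[1L], 3)
  expect_equal(g$theta_lo[19L], 177)
  expect_equal(g$theta_hi[19L], 180)
  expect_error(ring_detector_grid(radial_nodes = c(1, 1.2),
                                  radial_half_width = 0.25), "overlap")
})

test_that("analytic bin volumes agree with numerical integration", {
  g <- ring_detector_grid()
  b <- g$bins
  for (i in c(1L, 10L, 100L, 209L)) {
    vnum <- stats::integrate(function(r) r^2, b$r_lo[i], b$r_hi[i],
                             rel.tol = 1e-12)$value *
      2 * pi * stats::integrate(function(th) sin(th),
                                b$theta_lo[i] * pi / 180,
                                b$theta_hi[i] * pi / 180,
                                rel.tol = 1e-12)$value
    expect_equal(b$volume_cm3[i], vnum, tolerance = 1e-6)
  }
  # total binned volume cannot exceed the enclosing sphere
  expect_lt(sum(b$volume_cm3), 4 / 3 * pi * max(g$r_hi)^3)
})

test_that("bin lookup assigns points to the right cells", {
  g <- ring_detector_grid()
  expect_equal(unlist(bin_index(c(0, 0, 1), g)),
               c(radial = 2L, polar = 1L))
  # r = 1 cm at theta = 90 lands in the (1 cm, 90 deg) bin
  expect_equal(unlist(bin_index(c(1, 0, 0), g)),
               c(radial = 2L, polar = 10L))
  # cable side: on-axis below the source is theta = 180
  expect_equal(unlist(bin_index(c(0, 0, -2), g)),
               c(radial = 3L, polar = 19L))
  # gap between shells maps to no bin
  expect_true(is.na(bin_index(c(1.5, 0, 0), g)$radial))
})

test_that("bin hit fractions of uniform points match analytic volumes", {
  g <- ring_detector_grid()
  set.seed(77)
  n <- 1e5
  # sample uniformly within each shell, check polar partitioning
  for (ri in c(1L, 5L, 11L)) {
    r <- (runif(n, g$r_lo[ri]^3, g$r_hi[ri]^3))^(1 / 3)
    ct <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    st <- sqrt(1 - ct^2)
    pts <- cbind(r * st * cos(phi), r * st * sin(phi), r * ct)
    idx <- bin_index(pts, g)
    expect_true(all(idx$radial == ri, na.rm = TRUE))
    shell_v <- (4 * pi / 3) * (g$r_hi[ri]^3 - g$r_lo[ri]^3)
    for (ti in c(1L, 10L, 19L)) {
      p <- g$bins$volume_cm3[(ri - 1L) * 19L + ti] / shell_v
      hits <- sum(idx$polar == ti, na.rm = TRUE)
      expect_lt(abs(hits - n * p), 4 * sqrt(n * p * (1 - p)) + 1)
    }
  }
})

test_that("unit conversion matches the hand-computed constant product", {
  # 1 GeV-equivalent (1e6 keV) in 1 g with yield 1:
  # 1e6 * 1.602176634e-16 J/keV / 1e-3 kg * 3.7e7 /s * 3600 s/h * 100 cGy/Gy
  expect_equal(per_history_to_clinical(1e6, 1, 1),
               1e6 * 1.602176634e-16 * 1e3 * 3.7e7 * 3600 * 100,
               tolerance = 1e-12)
  expect_equal(per_history_to_clinical(1e6, 1, 1), 2134099.3, tolerance = 1e-7)
  expect_equal(per_history_to_clinical(0, 1, 1), 0)
  expect_equal(per_history_to_clinical(5, 1, 2),
               2 * per_history_to_clinical(5, 1, 1))
  expect_error(per_history_to_clinical(1, 0, 1), "mass")
})

test_that("duplicate-cell averaging uses inverse-variance weights", {
  t0 <- polar_dose_table(c(1, 2), c(90, 90), c(1, 2), c(0.1, 0.1))
  expect_equal(average_symmetric_bins(t0)$dose_rate, c(1, 2))
  # equal absolute errors -> arithmetic mean
  te <- polar_dose_table(c(1, 1), c(90, 90), c(2, 4), c(0.5, 0.25))
  expect_equal(average_symmetric_bins(te)$dose_rate, 3)
  # absolute sigmas 1 and 2 -> weights 4:1
  tw <- polar_dose_table(c(1, 1), c(90, 90), c(10, 20), c(0.1, 0.1))
  expect_equal(average_symmetric_bins(tw)$dose_rate,
               (10 / 1 + 20 / 4) / (1 + 1 / 4))
  # theta-mirror cells are NOT merged (asymmetric source)
  tm <- polar_dose_table(c(1, 1), c(30, 150), c(5, 7))
  expect_equal(nrow(average_symmetric_bins(tm)), 2L)
})

test_that("polar tables round-trip through the CSV writer", {
  tab <- polar_dose_table(c(0.5, 1), c(0, 90), c(4.544, 1.229),
                          c(0.01, 0.002), meta = list(seed = 5, mode = "x"))
  f <- tempfile(fileext = ".csv")
  write_polar_dose_table(tab, f)
  back <- read_polar_dose_table(f)
  expect_equal(back$dose_rate, tab$dose_rate, tolerance = 1e-12)
  expect_equal(back$rel_err, tab$rel_err, tolerance = 1e-6)
  expect_equal(attr(back, "meta")$mode, "x")
})
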