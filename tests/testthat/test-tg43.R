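L <- 0.6
t1 <- load_fixture("table1")

test_that("line-source geometry function matches closed forms and limits", {
  expect_equal(geometry_function_line(1, 90, L), 2 * atan(L / 2) / L,
               tolerance = 1e-12)
  expect_equal(geometry_function_line(1, 90, L), 0.97152, tolerance = 1e-5)
  expect_equal(geometry_function_line(0.5, 0, L), 1 / (0.25 - 0.09),
               tolerance = 1e-12)
  expect_equal(geometry_function_line(0.5, 0, L), 6.25)
  # point-source limit
  expect_equal(geometry_function_line(2, 37, 1e-5), 1 / 4, tolerance = 1e-6)
  # continuity near the axis
  expect_equal(geometry_function_line(1, 1e-7, L),
               geometry_function_line(1, 0, L), tolerance = 1e-6)
  expect_error(geometry_function_line(0.2, 0, L), "inside")
})

test_that("geometry function agrees with the line-integral oracle", {
  # r starts above L/2 = 0.3 cm: on-axis points touching the segment tip
  # are singular for both the closed form and the oracle
  rs <- c(0.35, 0.5, 1, 2, 5, 10)
  ths <- c(0, 1, 15, 45, 90, 135, 179, 180)
  for (r in rs) for (th in ths) {
    expect_equal(geometry_function_line(r, th, L), gl_numeric(r, th, L),
                 tolerance = 1e-6)
  }
})

test_that("radial dose function from the reference table matches published values", {
  g <- radial_dose_function(t1, L)
  expect_equal(g$g[g$r_cm == 1], 1)  # exact normalization
  expect_equal(g$g[g$r_cm == 0.5], 0.965, tolerance = 0.005 / 0.965)
  expect_equal(g$g[g$r_cm == 2], 1.071, tolerance = 0.005 / 1.071)
  expect_error(radial_dose_function(
    polar_dose_table(c(2, 3), c(90, 90), c(1, 1)), L), "reference")
})

test_that("anisotropy function from the reference table matches published values", {
  f <- anisotropy_function(t1, L)
  expect_equal(f$F[f$r_cm == 0.5 & f$theta_deg == 0], 0.595,
               tolerance = 0.005 / 0.595)
  expect_equal(f$F[f$r_cm == 1 & f$theta_deg == 0], 0.696,
               tolerance = 0.005 / 0.696)
  expect_true(all(f$F[f$theta_deg == 90] == 1))
})

test_that("air-kerma strength and dose-rate constant follow their definitions", {
  expect_equal(air_kerma_strength(1e-4, 100), 1.0)
  expect_equal(air_kerma_strength(0, 100), 0)
  expect_equal(air_kerma_strength(5e-5, 100), air_kerma_strength(1e-4, 100) / 2)
  expect_equal(dose_rate_constant(1.229, 1.082), 1.136, tolerance = 5e-4)
  expect_equal(dose_rate_constant(3, 3), 1)
  expect_equal(dose_rate_constant(2 * 1.229, 2 * 1.082),
               dose_rate_constant(1.229, 1.082))
  expect_error(dose_rate_constant(1, 0), "positive")
})

test_that("polynomial fit recovers exact fifth-order data and published stats", {
  r <- c(0.5, 1:10)
  a <- c(0.9, 0.1, -0.01, 0.002, -3e-4, 1.5e-5)
  g_exact <- drop(outer(r, 0:5, `^`) %*% a)
  fit <- fit_radial_polynomial(data.frame(r_cm = r, g = g_exact))
  expect_equal(unname(fit$coefficients), a, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  t2 <- load_fixture("table2")
  pub <- fit_radial_polynomial(data.frame(r_cm = t2$r_cm, g = t2$g_fluka))
  expect_gte(pub$r_squared, 0.999)
  expect_equal(unname(pub$coefficients["a0"]), 9.19e-1, tolerance = 0.02 / 0.919)
  expect_error(fit_radial_polynomial(data.frame(r_cm = 1:5, g = rep(1, 5))),
               "at least 7")
})

test_that("extraction followed by reconstruction is the identity on grid nodes", {
  params <- extract_tg43(t1, L, s_k = 1.082)
  d <- reconstruct_dose(params, t1$r_cm, t1$theta_deg, s_k = 1.082)
  expect_equal(d, t1$dose_rate, tolerance = 1e-10)
  # at the reference point the reconstruction is S_k * Lambda exactly
  expect_equal(reconstruct_dose(params, 1, 90, s_k = 1.082),
               1.082 * params$Lambda, tolerance = 1e-12)
  expect_equal(reconstruct_dose(params, 1, 90, s_k = 2.164),
               2 * reconstruct_dose(params, 1, 90, s_k = 1.082))
  expect_error(reconstruct_dose(params, 12, 90), "range")
})

test_that("extracted parameters are invariant under rescaling the input table", {
  t_scaled <- polar_dose_table(t1$r_cm, t1$theta_deg, 17.3 * t1$dose_rate)
  p1 <- extract_tg43(t1, L)
  p2 <- extract_tg43(t_scaled, L)
  expect_equal(p2$g_table$g, p1$g_table$g, tolerance = 1e-12)
  expect_equal(p2$F_table$F, p1$F_table$F, tolerance = 1e-12)
})

test_that("extracted parameters converge to truth as synthetic noise shrinks", {
  spec0 <- synthetic_spec(Lambda = 1.3)
  err_at <- function(sigma) {
    errs <- vapply(1:12, function(k) {
      tab <- generate_polar_dose_table(synthetic_spec(Lambda = 1.3,
                                                      sigma = sigma),
                                       seed = 1000 + k)
      p <- extract_tg43(tab, 0.6)
      abs(p$Lambda - 1.3)
    }, 0)
    mean(errs)
  }
  e <- vapply(c(0.04, 0.02, 0.01, 0), err_at, 0)
  expect_true(all(diff(e) < 0))
  expect_equal(e[4L], 0, tolerance = 1e-12)
})

test_that("isodose contours are circular for radial maps and polar-flattened for the seed", {
  y <- seq(-5, 5, length.out = 501)
  z <- seq(-5, 5, length.out = 501)
  dmap <- outer(y, z, function(a, b) 1 / (a^2 + b^2 + 1e-9))
  cl <- isodose_contours(y, z, dmap, levels = 1 / 9)
  rr <- sqrt(cl[[1L]]$y^2 + cl[[1L]]$z^2)
  expect_lt((max(rr) - min(rr)) / mean(rr), 1e-3)
  expect_identical(isodose_contours(y, z, dmap, numeric(0)), list())
  # seed parameters: contour reaches the source more closely along the axis
  params <- extract_tg43(t1, 0.6, s_k = 1.082)
  grid1 <- seq(-4.5, 4.5, length.out = 241)
  dm <- matrix(0, 241, 241)
  for (i in seq_along(grid1)) {
    r <- pmax(sqrt(grid1[i]^2 + grid1^2), 0.55)
    th <- acos(pmin(1, pmax(-1, grid1 / r))) * 180 / pi
    dm[i, ] <- reconstruct_dose(params, pmin(r, 10), th)
  }
  lev <- reconstruct_dose(params, 2, 90)
  cl2 <- isodose_contours(grid1, grid1, dm, lev)
  pts <- do.call(rbind, cl2)
  z_extent <- max(abs(pts$z))  # along source axis
  y_extent <- max(abs(pts$y))  # transverse
  expect_lt(z_extent, y_extent)
})
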