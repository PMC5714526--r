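#' Line-source geometry function
#'
#' `G_L(r, theta) = beta / (L r sin theta)`, where `beta` is the angle
#' subtended by the active line of length `L` at the field point; on the
#' long axis (`theta` 0 or 180 degrees) the continuous limit
#' `1 / (r^2 - L^2/4)` applies. For `L -> 0` the point-source inverse
#' square `1/r^2` is recovered.
#'
#' @param r radial distance in cm (vectorized); points inside the active
#'   segment (on-axis closer than L/2) are a domain error.
#' @param theta_deg polar angle in degrees (vectorized).
#' @param L active length in cm.
#' @return Geometry function values in 1/cm^2.
#' @examples
#' geometry_function_line(1, 90, 0.6)    # 0.97152
#' geometry_function_line(0.5, 0, 0.6)   # 6.25
#' @export
geometry_function_line <- function(r, theta_deg, L) {
  stopifnot(L > 0)
  n <- max(length(r), length(theta_deg))
  r <- rep_len(r, n); theta_deg <- rep_len(theta_deg, n)
  if (any(r <= 0)) stop("r must be positive")
  th <- theta_deg * pi / 180
  h <- r * sin(th)
  z <- r * cos(th)
  on_axis <- abs(sin(th)) < 1e-9
  if (any(on_axis & r <= L / 2 + 1e-12) ||
      any(!on_axis & h < 1e-12 & abs(z) <= L / 2)) {
    stop("field point inside the active source segment")
  }
  out <- numeric(n)
  # beta via the angles from the perpendicular foot to the segment ends
  b <- atan2(z + L / 2, h) - atan2(z - L / 2, h)
  out <- b / (L * h)
  out[on_axis] <- 1 / (r[on_axis]^2 - L^2 / 4)
  out
}

g_ref <- function(L) geometry_function_line(1, 90, L)

#' Radial dose function from a polar dose table
#'
#' `g_L(r) = [D(r, 90) / G_L(r, 90)] / [D(1, 90) / G_L(1, 90)]`, the
#' transverse-axis fall-off after removal of the line-source geometry
#' factor, normalized to 1 at the reference point r0 = 1 cm.
#'
#' @param table a [polar_dose_table()] containing the 90-degree column
#'   including r = 1 cm.
#' @param L active length in cm.
#' @return A data.frame with columns `r_cm` and `g`, of class
#'   `radial_dose_function`; `g` is exactly 1 at r = 1.
#' @export
radial_dose_function <- function(table, L) {
  tr <- table[abs(table$theta_deg - 90) < 1e-9, ]
  if (nrow(tr) == 0L) stop("table has no theta = 90 column")
  i0 <- which(abs(tr$r_cm - 1) < 1e-9)
  if (length(i0) != 1L) stop("missing reference cell at r0 = 1 cm")
  q <- tr$dose_rate / geometry_function_line(tr$r_cm, 90, L)
  out <- data.frame(r_cm = tr$r_cm, g = q / q[i0])
  out <- out[order(out$r_cm), ]
  rownames(out) <- NULL
  structure(out, L = L, class = c("radial_dose_function", "data.frame"))
}

#' Two-dimensional anisotropy function from a polar dose table
#'
#' `F(r, theta) = [D(r, theta) / G_L(r, theta)] /
#' [D(r, 90) / G_L(r, 90)]`: the polar variation of dose about the
#' transverse axis after geometry-function correction (capsule
#' self-filtration and end effects). Exactly 1 at theta = 90 for every r.
#'
#' @inheritParams radial_dose_function
#' @return A data.frame `r_cm`, `theta_deg`, `F` of class
#'   `anisotropy_function`.
#' @export
anisotropy_function <- function(table, L) {
  if (!any(abs(table$theta_deg - 90) < 1e-9)) {
    stop("table has no theta = 90 reference column")
  }
  q <- table$dose_rate /
    geometry_function_line(table$r_cm, table$theta_deg, L)
  ref <- table[abs(table$theta_deg - 90) < 1e-9, ]
  qref <- ref$dose_rate / geometry_function_line(ref$r_cm, 90, L)
  idx <- match(signif(table$r_cm, 12), signif(ref$r_cm, 12))
  if (any(is.na(idx))) stop("missing theta = 90 reference cell for some r")
  out <- data.frame(r_cm = table$r_cm, theta_deg = table$theta_deg,
                    F = q / qref[idx])
  out <- out[order(out$r_cm, out$theta_deg), ]
  rownames(out) <- NULL
  structure(out, L = L, class = c("anisotropy_function", "data.frame"))
}

#' Air-kerma strength from a kerma rate at distance d
#'
#' `S_k = Kdot_delta(d) * d^2` expressed in U (1 U = 1 uGy m^2/h) per unit
#' contained activity.
#'
#' @param kerma_rate air-kerma rate in cGy/h (per mCi) at `d_cm`.
#' @param d_cm reference distance in cm.
#' @return Air-kerma strength in U (per mCi).
#' @examples
#' air_kerma_strength(1e-4, 100)  # 1 U
#' @export
air_kerma_strength <- function(kerma_rate, d_cm) {
  stopifnot(d_cm > 0)
  kerma_rate * 1e4 * (d_cm / 100)^2
}

#' Dose-rate constant
#'
#' The in-water dose rate at the reference point (1 cm, 90 degrees) divided
#' by the air-kerma strength; the per-activity normalization cancels in the
#' ratio.
#'
#' @param dose_at_ref dose rate at (1 cm, 90 deg) in cGy/h/mCi.
#' @param s_k air-kerma strength in U/mCi.
#' @return Dose-rate constant in cGy/h/U.
#' @export
dose_rate_constant <- function(dose_at_ref, s_k) {
  if (s_k <= 0) stop("air-kerma strength must be positive")
  dose_at_ref / s_k
}

#' Fifth-order polynomial fit of the radial dose function
#'
#' Ordinary least squares of `g(r) = a0 + a1 r + ... + a5 r^5` over the
#' tabulated radii, with the coefficient of determination computed against
#' the mean model.
#'
#' @param g_table a data.frame with columns `r_cm` and `g` (at least 7
#'   points), e.g. from [radial_dose_function()].
#' @return A list with `coefficients` (named a0..a5) and `r_squared`.
#' @export
fit_radial_polynomial <- function(g_table) {
  stopifnot(all(c("r_cm", "g") %in% names(g_table)))
  if (nrow(g_table) < 7L) stop("need at least 7 points for a 5th-order fit")
  fit <- stats::lm(g ~ poly(r_cm, 5, raw = TRUE), data = g_table)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient fit: degenerate input")
  co <- stats::setNames(as.numeric(stats::coef(fit)), paste0("a", 0:5))
  # R^2 against the mean model (computed directly: summary.lm warns on
  # numerically perfect fits)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((g_table$g - mean(g_table$g))^2)
  list(coefficients = co, r_squared = 1 - ss_res / ss_tot)
}

#' Bundle of extracted dose-formalism parameters
#'
#' @param L active length, cm.
#' @param Lambda dose-rate constant, cGy/h/U.
#' @param s_k air-kerma strength per contained activity, U/mCi (NA when the
#'   parameters come from a table with unknown absolute normalization).
#' @param g_table data.frame `r_cm`, `g` (must contain g(1) = 1).
#' @param F_table data.frame `r_cm`, `theta_deg`, `F` on a complete grid.
#' @param poly fit list from [fit_radial_polynomial()], optional.
#' @return An object of class `tg43_parameter_set`.
#' @export
tg43_parameter_set <- function(L, Lambda, s_k = NA_real_, g_table, F_table,
                               poly = NULL) {
  stopifnot(L > 0, Lambda > 0)
  i0 <- which(abs(g_table$r_cm - 1) < 1e-9)
  if (length(i0) != 1L || abs(g_table$g[i0] - 1) > 1e-12) {
    stop("g_table must be normalized: g(1) = 1")
  }
  f90 <- F_table$F[abs(F_table$theta_deg - 90) < 1e-9]
  if (any(abs(f90 - 1) > 1e-12)) {
    stop("F_table must be normalized: F(r, 90) = 1")
  }
  structure(list(L = L, Lambda = Lambda, s_k = s_k, r0 = 1, theta0 = 90,
                 g_table = g_table, F_table = F_table, poly = poly),
            class = "tg43_parameter_set")
}

#' @export
print.tg43_parameter_set <- function(x, ...) {
  cat("<tg43_parameter_set> L =", x$L, "cm\n")
  cat("  Lambda =", format(x$Lambda, digits = 4), "cGy/h/U",
      if (!is.na(x$s_k)) paste("; S_k =", format(x$s_k, digits = 4),
                               "U/mCi"), "\n")
  cat("  g_L: ", nrow(x$g_table), " radii in [",
      min(x$g_table$r_cm), ", ", max(x$g_table$r_cm), "] cm\n", sep = "")
  cat("  F: ", nrow(x$F_table), " cells\n", sep = "")
  if (!is.null(x$poly)) {
    cat("  poly fit R^2 =", format(x$poly$r_squared, digits = 5), "\n")
  }
  invisible(x)
}

#' Extract the full parameter set from a polar dose table
#'
#' Convenience wrapper: computes the radial dose function, anisotropy
#' function, fifth-order polynomial fit, and the dose-rate constant
#' (given the air-kerma strength) from one polar dose table.
#'
#' @param table a [polar_dose_table()] on a complete grid.
#' @param L active length, cm.
#' @param s_k air-kerma strength in U/mCi used for the dose-rate constant;
#'   if NA, `Lambda` is computed with `s_k = 1` (unit-strength convention).
#' @return A [tg43_parameter_set()].
#' @export
extract_tg43 <- function(table, L, s_k = NA_real_) {
  g <- radial_dose_function(table, L)
  f <- anisotropy_function(table, L)
  d_ref <- table$dose_rate[abs(table$r_cm - 1) < 1e-9 &
                             abs(table$theta_deg - 90) < 1e-9]
  lam <- dose_rate_constant(d_ref, if (is.na(s_k)) 1 else s_k)
  tg43_parameter_set(L, lam, s_k, g, f, fit_radial_polynomial(g))
}

# log-linear interpolation of g_L in r; bilinear interpolation of F
interp_g <- function(params, r) {
  gt <- params$g_table
  if (any(r < min(gt$r_cm) - 1e-9 | r > max(gt$r_cm) + 1e-9)) {
    stop("r outside the tabulated range of g_L")
  }
  exp(stats::approx(gt$r_cm, log(gt$g), pmin(pmax(r, min(gt$r_cm)),
                                             max(gt$r_cm)))$y)
}

interp_F <- function(params, r, theta_deg) {
  ft <- params$F_table
  rs <- sort(unique(ft$r_cm)); ts <- sort(unique(ft$theta_deg))
  if (any(r < min(rs) - 1e-9 | r > max(rs) + 1e-9) ||
      any(theta_deg < min(ts) - 1e-9 | theta_deg > max(ts) + 1e-9)) {
    stop("(r, theta) outside the tabulated range of F")
  }
  m <- matrix(NA_real_, length(ts), length(rs))
  m[cbind(match(ft$theta_deg, ts), match(ft$r_cm, rs))] <- ft$F
  if (any(is.na(m))) stop("F_table is not a complete grid")
  r <- pmin(pmax(r, min(rs)), max(rs))
  theta_deg <- pmin(pmax(theta_deg, min(ts)), max(ts))
  ri <- pmin(pmax(findInterval(r, rs), 1L), length(rs) - 1L)
  ti <- pmin(pmax(findInterval(theta_deg, ts), 1L), length(ts) - 1L)
  wr <- (r - rs[ri]) / (rs[ri + 1L] - rs[ri])
  wt <- (theta_deg - ts[ti]) / (ts[ti + 1L] - ts[ti])
  m[cbind(ti, ri)] * (1 - wr) * (1 - wt) +
    m[cbind(ti, ri + 1L)] * wr * (1 - wt) +
    m[cbind(ti + 1L, ri)] * (1 - wr) * wt +
    m[cbind(ti + 1L, ri + 1L)] * wr * wt
}

#' Reconstruct dose rates from an extracted parameter set
#'
#' Evaluates the two-dimensional dose formalism
#' `D(r, theta) = S_k Lambda [G_L(r, theta) / G_L(r0, theta0)] g_L(r)
#' F(r, theta)` with log-linear interpolation of `g_L` in r and bilinear
#' interpolation of `F` in (r, theta). Requests outside the tabulated range
#' are an error.
#'
#' @param params a [tg43_parameter_set()].
#' @param r,theta_deg evaluation points (vectorized).
#' @param s_k air-kerma strength in U; defaults to the set's own value, or
#'   1 if that is NA.
#' @return Dose rate in cGy/h.
#' @export
reconstruct_dose <- function(params, r, theta_deg, s_k = NULL) {
  stopifnot(inherits(params, "tg43_parameter_set"))
  if (is.null(s_k)) s_k <- if (is.na(params$s_k)) 1 else params$s_k
  n <- max(length(r), length(theta_deg))
  r <- rep_len(r, n); theta_deg <- rep_len(theta_deg, n)
  gl <- geometry_function_line(r, theta_deg, params$L) / g_ref(params$L)
  s_k * params$Lambda * gl * interp_g(params, r) *
    interp_F(params, r, theta_deg)
}

#' Isodose contours of a planar dose map
#'
#' Extracts contour polylines at the requested dose levels from a dose map
#' sampled on a regular (y, z) Cartesian grid in a plane containing the
#' source axis. For the extracted seed parameters the contours are
#' elongated ellipse-like curves with depressions at both poles.
#'
#' @param y,z grid coordinates (cm), strictly increasing.
#' @param dose matrix of dose values, `length(y)` x `length(z)`.
#' @param levels numeric vector of dose levels; empty gives an empty list.
#' @return A list of data.frames (`y`, `z`, `level`), one per closed
#'   polyline.
#' @export
isodose_contours <- function(y, z, dose, levels) {
  stopifnot(is.matrix(dose), nrow(dose) == length(y),
            ncol(dose) == length(z), all(is.finite(dose)))
  if (length(levels) == 0L) return(list())
  cl <- grDevices::contourLines(y, z, dose, levels = levels)
  lapply(cl, function(c0) data.frame(y = c0$x, z = c0$y, level = c0$level))
}
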