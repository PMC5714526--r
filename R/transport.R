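#' Configuration for a transport run
#'
#' @param n_histories number of primary photons (one emitted photon per
#'   history).
#' @param seed integer seed for R's random stream; a fixed seed makes runs
#'   bit-reproducible.
#' @param n_batch number of batches for the batch-means uncertainty
#'   estimate; `n_histories >= n_batch >= 2`.
#' @param cutoff_keV photon cutoff energy; photons falling below it are
#'   absorbed on the spot (their residual energy is deposited locally).
#' @param phantom_radius_cm radius of the water phantom sphere.
#' @param interactions `"full"` (analogue transport), `"primary_only"`
#'   (histories end at their first collision; scores primary kerma), or
#'   `"none"` (no interactions anywhere: bare inverse-square fluence).
#' @param estimator `"collision"` (expected energy transfer tallied at real
#'   collision sites; the default) or `"tracklength"` (fluence x E x
#'   mu_en/rho integrated along flight paths; usable with `"none"`).
#' @param substep_cm marching step for track-length scoring.
#' @param fluorescence emit a mean K x-ray after photoelectric absorption in
#'   the ytterbium core (above its K edge)? Off by default: the Tm K x-rays
#'   that follow electron capture are already in the source spectrum, and
#'   capsule fluorescence falls below the transport cutoff.
#' @param scoring `"spherical"` for the shell-cone grid or `"cylindrical"`
#'   for the (R, Z) mesh re-binned onto the polar grid by volume-weighted
#'   averaging.
#' @param cyl_r_edges,cyl_z_edges cell edges (cm) for cylindrical scoring.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_histories = 1e6, seed = 1L, n_batch = 20L,
                              cutoff_keV = 10, phantom_radius_cm = 50,
                              interactions = c("full", "primary_only",
                                               "none"),
                              estimator = c("collision", "tracklength"),
                              substep_cm = 0.25, fluorescence = FALSE,
                              scoring = c("spherical", "cylindrical"),
                              cyl_r_edges = NULL, cyl_z_edges = NULL) {
  interactions <- match.arg(interactions)
  estimator <- match.arg(estimator)
  scoring <- match.arg(scoring)
  if (n_histories < n_batch || n_batch < 2L) {
    stop("need n_histories >= n_batch >= 2")
  }
  if (scoring == "cylindrical" && is.null(cyl_r_edges)) {
    cyl_r_edges <- c(0, 10^seq(log10(0.1), log10(11), length.out = 80))
    cyl_z_edges <- seq(-11, 11, by = 0.2)
  }
  structure(list(n_histories = as.double(n_histories), seed = as.integer(seed),
                 n_batch = as.integer(n_batch), cutoff_keV = cutoff_keV,
                 phantom_radius_cm = phantom_radius_cm,
                 interactions = interactions, estimator = estimator,
                 substep_cm = substep_cm, fluorescence = fluorescence,
                 scoring = scoring, cyl_r_edges = cyl_r_edges,
                 cyl_z_edges = cyl_z_edges),
            class = "simulation_config")
}

#' Air-kerma measurement geometry
#'
#' The air-kerma rate is scored in an air ring detector formed by the
#' intersection of two spherical shells and two cones in an otherwise empty
#' (vacuum) world, and referenced to the distance `d_cm` on the transverse
#' axis with an inverse-square weighting of each scored path element.
#' Photons below the energy cutoff `delta_keV` are excluded.
#'
#' @param inner_radius_cm,outer_radius_cm shell radii bounding the ring.
#' @param cone_lo_deg,cone_hi_deg polar cone band (degrees about 90).
#' @param d_cm reference distance.
#' @param delta_keV low-energy exclusion cutoff.
#' @return A list of class `air_kerma_spec`.
#' @export
air_kerma_spec <- function(inner_radius_cm = 97.5, outer_radius_cm = 102.5,
                           cone_lo_deg = 88, cone_hi_deg = 92, d_cm = 100,
                           delta_keV = 10) {
  stopifnot(inner_radius_cm < d_cm, d_cm < outer_radius_cm,
            cone_lo_deg < 90, cone_hi_deg > 90)
  if (abs((90 - cone_lo_deg) - (cone_hi_deg - 90)) > 1e-9) {
    stop("cone band must be symmetric about 90 degrees")
  }
  structure(list(inner_radius_cm = inner_radius_cm,
                 outer_radius_cm = outer_radius_cm,
                 cone_lo_deg = cone_lo_deg, cone_hi_deg = cone_hi_deg,
                 d_cm = d_cm, delta_keV = delta_keV),
            class = "air_kerma_spec")
}

# ---- internal: pack materials and geometry for the kernel ----------------

.fine_energy_grid <- function(materials) {
  e <- sort(unique(c(
    10^seq(1, log10(400), length.out = 120),
    unlist(lapply(materials, function(m) {
      unlist(lapply(names(m$composition),
                    function(s) element_xsec(s)$energy_keV))
    })))))
  e[e >= 10 & e <= 400]
}

.pack_material <- function(material, energy) {
  tab <- attenuation_table(material)
  pe <- loglog_interp(tab$energy_keV, tab$pe, energy)
  ic <- loglog_interp(tab$energy_keV, tab$incoh, energy)
  co <- loglog_interp(tab$energy_keV, tab$coh, energy)
  muen <- loglog_interp(tab$energy_keV, tab$muen, energy)
  tot <- pe + ic + co
  ray <- rayleigh_sampling_table(material)
  # K-fluorescence bookkeeping for the ytterbium core (dominant
  # photoabsorber); the jump ratio comes from the packaged edge doublet
  fluor_p <- 0; fluor_E <- 0; fluor_edge <- Inf
  if ("Yb" %in% names(material$composition) &&
      material$composition[["Yb"]] > 0.5) {
    yb <- element_xsec("Yb")
    edge <- 61.3323
    below <- max(yb$pe[yb$energy_keV < edge])
    above <- yb$pe[which(yb$energy_keV > edge)[1L]]
    fluor_p <- (above - below) / above * 0.936  # K-shell fraction x omega_K
    fluor_E <- 52.2
    fluor_edge <- edge
  }
  list(logE = log(energy), log_mu = log(tot * material$density),
       fpe = pe / tot, fpic = (pe + ic) / tot, ftr = muen / tot,
       ray_x = ray$x, ray_cdf = ray$cdf,
       fluor_p = fluor_p, fluor_E = fluor_E, fluor_edge = fluor_edge)
}

.pack_run <- function(model, cfg, mode, grid = NULL, spec = NULL) {
  phantom_medium <- if (mode == 0L) builtin_material("water") else NULL
  mats <- lapply(model$regions, `[[`, "material")
  keys <- vapply(mats, function(m) paste0(m$name, "@", m$density), "")
  umats <- mats[!duplicated(keys)]
  ukeys <- keys[!duplicated(keys)]
  region_mat <- match(keys, ukeys) - 1L
  phantom_mat <- -1L
  if (!is.null(phantom_medium)) {
    umats <- c(umats, list(phantom_medium))
    phantom_mat <- length(umats) - 1L
  }
  energy <- .fine_energy_grid(c(umats, list(builtin_material("water"),
                                            builtin_material("air"))))
  packed <- lapply(umats, .pack_material, energy = energy)

  rmax <- max(vapply(model$regions, `[[`, 0, "radius"))
  zr <- range(unlist(lapply(model$regions, function(r) c(r$zmin, r$zmax))))
  geom <- list(
    cyl_r = vapply(model$regions, `[[`, 0, "radius"),
    cyl_zmin = vapply(model$regions, `[[`, 0, "zmin"),
    cyl_zmax = vapply(model$regions, `[[`, 0, "zmax"),
    cyl_mat = as.integer(region_mat),
    bound_r = rmax * 1.05 + 0.01, bound_zmin = zr[1L] * 1.05 - 0.01,
    bound_zmax = zr[2L] * 1.05 + 0.01,
    world_R = if (mode == 0L) cfg$phantom_radius_cm else
      (spec$outer_radius_cm + 8),
    phantom_mat = as.integer(phantom_mat))
  if (mode == 1L) {
    airtab <- attenuation_table(builtin_material("air"))
    geom$ring_rin <- spec$inner_radius_cm
    geom$ring_rout <- spec$outer_radius_cm
    geom$cone_lo_deg <- spec$cone_lo_deg
    geom$cone_hi_deg <- spec$cone_hi_deg
    geom$d_ref <- spec$d_cm
    geom$delta_keV <- spec$delta_keV
    geom$air_logE <- log(airtab$energy_keV)
    geom$air_log_muen_rho <- log(airtab$muen)
  }
  core <- model$regions[[1L]]
  li <- model$spectrum$lines
  src <- list(core_r = core$radius, core_zmin = core$zmin,
              core_zmax = core$zmax, energies = li$energy_keV,
              cdf = cumsum(li$intensity) / sum(li$intensity))
  gridspec <- if (is.null(grid)) {
    list(r_lo = 1, r_hi = 1, theta_lo = 0, theta_hi = 0)
  } else {
    list(r_lo = grid$r_lo, r_hi = grid$r_hi, theta_lo = grid$theta_lo,
         theta_hi = grid$theta_hi)
  }
  if (cfg$scoring == "cylindrical") {
    gridspec$cyl_redges <- cfg$cyl_r_edges
    gridspec$cyl_zedges <- cfg$cyl_z_edges
  }
  ccfg <- list(mode = as.integer(mode), n_histories = cfg$n_histories,
               n_batch = cfg$n_batch, cutoff_keV = cfg$cutoff_keV,
               interactions = match(cfg$interactions,
                                    c("full", "primary_only", "none")) - 1L,
               estimator = match(cfg$estimator,
                                 c("collision", "tracklength")) - 1L,
               substep = cfg$substep_cm, fluorescence = cfg$fluorescence)
  if (mode == 0L) {
    wtab <- attenuation_table(builtin_material("water"))
    ccfg$score_logE <- log(wtab$energy_keV)
    ccfg$score_log_muen_rho <- log(wtab$muen)
  }
  list(src = src, mats = packed, geom = geom, grid = gridspec, cfg = ccfg)
}

.batch_stats <- function(tally_matrix) {
  m <- rowMeans(tally_matrix)
  nb <- ncol(tally_matrix)
  se <- apply(tally_matrix, 1L, stats::sd) / sqrt(nb)
  rel <- ifelse(m > 0, se / m, NA_real_)
  list(mean = m, rel_err = rel)
}

#' Simulate the seed in the water phantom and score a polar dose table
#'
#' Runs analogue photon transport of `n_histories` primaries from the seed
#' through the spherical water phantom, scoring collision kerma (assumed
#' equal to absorbed dose at the scoring points: secondary electrons at
#' these energies are absorbed locally) on the shell-cone detector grid.
#' Scored energy per history is converted to cGy/h per mCi of contained
#' activity using 3.7e7 decays/s/mCi and the spectrum's photons-per-decay
#' yield. Per-bin relative uncertainties come from batch means; runs with
#' the same seed and configuration are bit-identical.
#'
#' @param model a [source_model()].
#' @param grid a [ring_detector_grid()]; must lie inside the phantom.
#' @param cfg a [simulation_config()].
#' @return A [polar_dose_table()] with one row per grid bin, metadata in
#'   `attr(, "meta")` (seed, histories, lost-particle count, totals, Compton
#'   sampling efficiency).
#' @export
run_water_phantom <- function(model, grid = ring_detector_grid(),
                              cfg = simulation_config()) {
  stopifnot(inherits(model, "source_model"),
            inherits(grid, "ring_detector_grid"),
            inherits(cfg, "simulation_config"))
  if (max(grid$r_hi) > cfg$phantom_radius_cm) {
    stop("detector grid extends outside the phantom")
  }
  packed <- .pack_run(model, cfg, mode = 0L, grid = grid)
  set.seed(cfg$seed)
  res <- cpp_run_transport(packed$src, packed$mats, packed$geom, packed$grid,
                           packed$cfg)
  yield <- model$spectrum$total_yield
  water <- builtin_material("water")

  if (cfg$scoring == "cylindrical") {
    tab <- .rebin_cylindrical(res, cfg, grid, yield, water)
  } else {
    st <- .batch_stats(res$tally / (cfg$n_histories / cfg$n_batch))
    keV_per_g <- if (cfg$estimator == "collision") {
      st$mean / (grid$bins$volume_cm3 * water$density)
    } else {
      st$mean / grid$bins$volume_cm3
    }
    rate <- per_history_to_clinical(keV_per_g, 1, yield)
    tab <- polar_dose_table(grid$bins$r_node, grid$bins$theta_node, rate,
                            st$rel_err)
  }
  attr(tab, "meta") <- list(
    mode = "water_phantom", seed = cfg$seed, histories = cfg$n_histories,
    estimator = cfg$estimator, interactions = cfg$interactions,
    scoring = cfg$scoring, yield_photons_per_decay = yield,
    emitted_keV = res$emitted_keV, deposited_keV = res$deposited_keV,
    lost = res$lost, compton_efficiency = res$compton_efficiency,
    package_version = as.character(utils::packageVersion("ybdosim")))
  tab
}

# volume-weighted re-binning of the cylindrical (R,Z) mesh onto the polar
# grid: each polar bin is averaged over the cylindrical cells it intersects
# (cells sampled uniformly in the bin volume)
.rebin_cylindrical <- function(res, cfg, grid, yield, water, npts = 400L) {
  re <- cfg$cyl_r_edges; ze <- cfg$cyl_z_edges
  nr <- length(re) - 1L; nz <- length(ze) - 1L
  # cell index is r-major (cell k = (ri-1)*nz + zi), matching the kernel
  vol <- as.vector(t(outer(pi * (re[-1L]^2 - re[-(nr + 1L)]^2), diff(ze))))
  cell_mean <- rowMeans(res$cyl_tally) / (cfg$n_histories / cfg$n_batch)
  cell_rate <- per_history_to_clinical(
    cell_mean / (vol * water$density), 1, yield)
  bins <- grid$bins
  out <- numeric(nrow(bins))
  set.seed(cfg$seed + 1L)
  for (i in seq_len(nrow(bins))) {
    u3 <- stats::runif(npts, bins$r_lo[i]^3, bins$r_hi[i]^3)
    r <- u3^(1 / 3)
    ct <- stats::runif(npts, cos(bins$theta_hi[i] * pi / 180),
                       cos(bins$theta_lo[i] * pi / 180))
    rho <- r * sqrt(1 - ct^2); z <- r * ct
    ri <- findInterval(rho, re, rightmost.closed = TRUE)
    zi <- findInterval(z, ze, rightmost.closed = TRUE)
    ok <- ri >= 1L & ri <= nr & zi >= 1L & zi <= nz
    out[i] <- mean(cell_rate[(ri[ok] - 1L) * nz + zi[ok]])
  }
  polar_dose_table(bins$r_node, bins$theta_node, out, NA_real_)
}

#' Simulate the air-kerma geometry and return the strength per activity
#'
#' Places the seed at the centre of an empty (vacuum) world surrounded by
#' the air ring detector of `spec` and scores air kerma with a track-length
#' estimator (fluence x energy x mass energy-absorption coefficient of air),
#' each path element referenced to the distance `d` by an inverse-square
#' weight. The ring is treated as a non-perturbing detector: attenuation
#' over 5 cm of air (~0.1%) is neglected, consistent with the in-vacuo
#' definition of air-kerma strength.
#'
#' @param model a [source_model()].
#' @param spec an [air_kerma_spec()].
#' @param cfg a [simulation_config()].
#' @return A list: `kerma_rate` (cGy/h/mCi at `d`), `rel_err`, `sk`
#'   (air-kerma strength, U/mCi, 1 U = 1 uGy m^2/h), `d_cm`, `lost`.
#' @export
run_air_kerma <- function(model, spec = air_kerma_spec(),
                          cfg = simulation_config()) {
  stopifnot(inherits(model, "source_model"), inherits(spec, "air_kerma_spec"),
            inherits(cfg, "simulation_config"))
  packed <- .pack_run(model, cfg, mode = 1L, spec = spec)
  set.seed(cfg$seed)
  res <- cpp_run_transport(packed$src, packed$mats, packed$geom, packed$grid,
                           packed$cfg)
  vol <- shell_cone_volume(spec$inner_radius_cm, spec$outer_radius_cm,
                           spec$cone_lo_deg, spec$cone_hi_deg)
  per_batch <- res$air_tally / (cfg$n_histories / cfg$n_batch) / vol
  m <- mean(per_batch)
  rel <- stats::sd(per_batch) / sqrt(cfg$n_batch) / m
  rate <- per_history_to_clinical(m, 1, model$spectrum$total_yield)
  list(kerma_rate = rate, rel_err = rel,
       sk = air_kerma_strength(rate, spec$d_cm), d_cm = spec$d_cm,
       lost = res$lost)
}
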