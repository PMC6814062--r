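#' Thermal parameters
#'
#' Homogeneous ex vivo tissue: a single thermal diffusivity (the iterative
#' Gaussian-kernel method implies a spatially invariant kernel) and no
#' perfusion. Temperature is always an elevation above baseline.
#'
#' @param diffusivity_m2s Thermal diffusivity (m^2/s), default 1.4e-7.
#' @param vol_heat_capacity_Jm3K Volumetric heat capacity (J/(m^3 K)),
#'   default 3.8e6.
#' @param time_step_s Solver time step (s).
#' @return Object of class `thermal_params`.
#' @export
thermal_params <- function(diffusivity_m2s = 1.4e-7,
                           vol_heat_capacity_Jm3K = 3.8e6,
                           time_step_s = 2) {
  stopifnot(diffusivity_m2s > 0, vol_heat_capacity_Jm3K > 0, time_step_s > 0)
  structure(list(diffusivity_m2s = diffusivity_m2s,
                 vol_heat_capacity_Jm3K = vol_heat_capacity_Jm3K,
                 time_step_s = time_step_s),
            class = "thermal_params")
}

# discrete 1-D Gaussian kernel for one diffusion step, normalized to sum 1
.gauss_kernel <- function(sigma_vox) {
  hw <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-hw):hw)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' One diffusion step
#'
#' `T <- G_sigma * T + q dt / C` with `sigma = sqrt(2 D dt)`: convolution
#' with the heat-equation Green's function followed by explicit source
#' injection. Zero (absorbing) boundary; pad the domain so edge effects stay
#' negligible in the region of interest.
#'
#' @param T Temperature-elevation array (degC), or `NULL` for a zero field.
#' @param q Heat-source array (W/m^3) or `heat_source_map`, or `NULL`.
#' @param params A [thermal_params].
#' @param map A `tissue_map` (see [build_tissue_map()]) providing the grid spacing.
#' @param dt_s Optional override of `params$time_step_s`.
#' @return Temperature array.
#' @export
thermal_step <- function(T, q, params, map, dt_s = NULL) {
  dt <- dt_s %||% params$time_step_s
  h <- map$spacing_mm * 1e-3
  sigma_vox <- sqrt(2 * params$diffusivity_m2s * dt) / h
  if (sigma_vox < 0.5)
    stop(sprintf("kernel under-resolved: sigma = %.2f voxel < 0.5 (increase dt or refine grid)", sigma_vox))
  dims <- dim(map$labels)
  if (is.null(T)) T <- array(0, dims)
  Tn <- gauss_blur3_cpp(T, dims, .gauss_kernel(sigma_vox))
  if (!is.null(q)) {
    qa <- if (inherits(q, "heat_source_map")) q$q else q
    Tn <- Tn + qa * (dt / params$vol_heat_capacity_Jm3K)
  }
  Tn
}

# nearest voxel linear index for physical coordinates (mm)
.voxel_index <- function(map, at_mm) {
  i <- vapply(1:3, function(a) {
    ax <- list(map$x, map$y, map$z)[[a]]
    which.min(abs(ax - at_mm[a]))
  }, integer(1))
  d <- dim(map$labels)
  i[1] + (i[2] - 1L) * d[1] + (i[3] - 1L) * d[1] * d[2]
}

#' Simulate a sonication schedule
#'
#' Runs the diffusion solver with the source scaled by a duty factor per
#' step; during OFF periods both the cortical and tumoral terms are nulled
#' (post-sonication cooling). The pulse period (0.5 s) is far below the
#' thermal timescale, so within a step the duty cycle is applied as average
#' power.
#'
#' @param q `heat_source_map` or array: full-power source.
#' @param params A [thermal_params].
#' @param map A `tissue_map` (see [build_tissue_map()]).
#' @param duration_s Total simulated time (s).
#' @param duty Either a single number, or a function of time (s) returning
#'   the duty factor in `[0, 1]` for the step starting at that time.
#' @param probe_mm Optional (x, y, z) mm: record a scalar trace there.
#' @param snapshot_s Times (s) at which to keep full fields.
#' @param T0 Initial field (default zero).
#' @return `temperature_series`: list with `t_s`, `probe_degC`, `snapshots`
#'   (named by time), `final` field, and the `duty` trace.
#' @export
simulate_temperature <- function(q, params, map, duration_s,
                                 duty = 1, probe_mm = NULL,
                                 snapshot_s = numeric(), T0 = NULL) {
  dt <- params$time_step_s
  n <- ceiling(duration_s / dt)
  qa <- if (inherits(q, "heat_source_map")) q$q else q
  dims <- dim(map$labels)
  T <- if (is.null(T0)) array(0, dims) else T0
  dfun <- if (is.function(duty)) duty else function(t) duty
  pi_ <- if (!is.null(probe_mm)) .voxel_index(map, probe_mm)
  probe <- numeric(n)
  snaps <- list()
  snap_left <- sort(snapshot_s)
  t <- 0
  for (s in seq_len(n)) {
    dl <- dfun(t)
    T <- thermal_step(T, if (dl > 0) qa * dl else NULL, params, map)
    t <- t + dt
    if (!is.null(pi_)) probe[s] <- T[pi_]
    while (length(snap_left) && t >= snap_left[1] - dt / 2) {
      snaps[[sprintf("%g", snap_left[1])]] <- T
      snap_left <- snap_left[-1]
    }
  }
  structure(list(t_s = seq_len(n) * dt,
                 probe_degC = if (!is.null(pi_)) probe,
                 snapshots = snaps, final = T,
                 duty = vapply(seq_len(n) * dt - dt, dfun, numeric(1))),
            class = "temperature_series")
}

#' Impulse response at the focal point
#'
#' Short sonication followed by free cooling; records the focal-point
#' elevation. With a cortical-only source the curve peaks after the
#' sonication ends (delayed, centripetal heating from the facet).
#'
#' @param q Full-power `heat_source_map` (typically oven-only).
#' @param params,map See [simulate_temperature()].
#' @param sonication_s ON duration (s), default 10 (short vs the >= 100 s
#'   lags).
#' @param follow_s Cooling time simulated after the pulse.
#' @param probe_mm Focal-point coordinates (mm).
#' @return `temperature_series` with attribute `t_end_s = sonication_s`.
#' @export
impulse_response <- function(q, params, map, probe_mm,
                             sonication_s = 10, follow_s = 600) {
  ser <- simulate_temperature(q, params, map,
                              duration_s = sonication_s + follow_s,
                              duty = function(t) as.numeric(t < sonication_s),
                              probe_mm = probe_mm)
  attr(ser, "t_end_s") <- sonication_s
  ser
}

#' Time lag of the post-sonication temperature maximum
#'
#' `epsilon = t(max) - t(end of sonication)`, with sub-step refinement by
#' parabolic interpolation around the discrete maximum. Zero for a monotone
#' decay; error if the maximum sits at the final sample (simulation too
#' short).
#'
#' @param series A `temperature_series` from [impulse_response()] (or any
#'   series with a `t_end_s` attribute).
#' @param t_end_s Sonication end time; default from the series attribute.
#' @return Lag in seconds (>= 0).
#' @export
time_lag <- function(series, t_end_s = attr(series, "t_end_s")) {
  y <- series$probe_degC
  t <- series$t_s
  if (is.null(y)) stop("series has no probe trace")
  i <- which.max(y)
  if (i == length(y))
    stop("temperature still rising at the final sample: simulation too short")
  tp <- t[i]
  if (i > 1) {                       # parabolic vertex through 3 points
    dy1 <- y[i] - y[i - 1]; dy2 <- y[i] - y[i + 1]
    den <- dy1 + dy2
    if (den > 0) tp <- t[i] + (t[2] - t[1]) * (dy1 - dy2) / (2 * den)
  }
  max(0, tp - t_end_s)
}

#' Simulated time-lag table over (R, H)
#'
#' For each bone-section radius and focal offset, builds the phantom,
#' computes the field, isolates the cortical oven source (the lag
#' mechanism), runs an impulse response and extracts the lag. `R` follows
#' the source study's usage: the radius of the bone section, i.e. of the
#' medullar cavity / internal cortical surface where the oven term is
#' deposited (the samples' cavity long axes average ~12 mm, "average radius
#' 6 mm"); the outer cylinder radius is `R + thickness`. Offsets are
#' specified as fractions of `R` so every radius sweeps the same relative
#' range `(-R, R)`.
#'
#' @param R_values_mm Bone-section (medullar) radii (mm).
#' @param H_frac Focal offsets as fractions of `R`.
#' @param cortical_thickness_mm Cortical shell thickness (mm).
#' @param spec,medium,params,src_params Component configs; defaults match
#'   the desk-scale world.
#' @param spacing_mm Grid spacing for the sweep.
#' @param follow_s Cooling time per impulse response.
#' @return `data.frame` with columns `R_mm`, `H_mm`, `eps_s`.
#' @export
lag_table <- function(R_values_mm = seq(6, 10, length.out = 6),
                      H_frac = seq(-0.7, 0.7, length.out = 6),
                      cortical_thickness_mm = 3,
                      spec = transducer_spec(), medium = medium_spec(),
                      params = thermal_params(time_step_s = 4),
                      src_params = source_params(),
                      spacing_mm = 1, follow_s = 1100) {
  rows <- list()
  for (R in R_values_mm) {
    geo <- geometry_params(cortical_radius_mm = R + cortical_thickness_mm,
                           cortical_thickness_mm = cortical_thickness_mm,
                           grid_spacing_mm = spacing_mm)
    map <- build_tissue_map(geo)
    for (hf in H_frac) {
      H <- round(hf * R / spacing_mm) * spacing_mm
      sp <- spec; sp$focal_offset_H_mm <- H
      pf <- rayleigh_pressure(sp, medium, map, warn_aliasing = FALSE)
      If <- intensity_from_pressure(pf)
      If$I[beam_shadow(map, pf$focus_z_mm)] <- 0
      # full internal facet: the oven redistribution is near-isotropic, and a
      # sharp beam-cone membership would make the uniform deposition (hence
      # the lag) jump discontinuously as the focus shifts
      facet <- inner_cortical_facet(map)
      oven <- oven_effect_source(If, facet, map, src_params)
      ser <- impulse_response(oven, params, map,
                              probe_mm = c(0, 0, pf$focus_z_mm),
                              follow_s = follow_s)
      rows[[length(rows) + 1L]] <-
        data.frame(R_mm = R, H_mm = H, eps_s = time_lag(ser))
    }
  }
  do.call(rbind, rows)
}

#' Quadratic time-lag surface fit
#'
#' Least-squares fit of the six-term quadratic
#' `eps = sum_{m,n} c_mn H^m R^n` (m, n in 0..2, m + n <= 2) to a lag table,
#' in mm units.
#'
#' @param table `data.frame` with `R_mm`, `H_mm`, `eps_s`.
#' @return `lag_surface_fit`: coefficients `c00, c10, c01, c20, c11, c02`
#'   (s, s/mm, s/mm^2) and `mean_abs_residual_s`.
#' @export
fit_lag_surface <- function(table) {
  X <- with(table, cbind(1, H_mm, R_mm, H_mm^2, H_mm * R_mm, R_mm^2))
  if (qr(X)$rank < 6) stop("rank-deficient lag-surface design")
  fit <- lm.fit(X, table$eps_s)
  co <- setNames(fit$coefficients, c("c00", "c10", "c01", "c20", "c11", "c02"))
  structure(list(coefficients = co,
                 mean_abs_residual_s = mean(abs(fit$residuals)),
                 range_R_mm = range(table$R_mm),
                 range_H_mm = range(table$H_mm)),
            class = "lag_surface_fit")
}

#' Evaluate a fitted lag surface
#' @param fit A `lag_surface_fit`.
#' @param H_mm,R_mm Offsets and radii (mm), recycled.
#' @return Predicted lags (s).
#' @export
predict_lag <- function(fit, H_mm, R_mm) {
  co <- fit$coefficients
  co["c00"] + co["c10"] * H_mm + co["c01"] * R_mm +
    co["c20"] * H_mm^2 + co["c11"] * H_mm * R_mm + co["c02"] * R_mm^2
}

#' Ring uniformity of an intra-cavitary temperature field
#'
#' Coefficient of variation (sd/mean) of the elevation on the circle of
#' radius `(Rc - thickness)/2` in the axial mid-plane; quantifies how
#' circumferential the isotherms are.
#'
#' @param T Temperature array.
#' @param map A `tissue_map` (see [build_tissue_map()]).
#' @return CV (dimensionless).
#' @export
ring_uniformity <- function(T, map) {
  p <- map$params
  r0 <- (p$cortical_radius_mm - p$cortical_thickness_mm) / 2
  ix <- which.min(abs(map$x))
  r <- sqrt(outer(map$y^2, map$z^2, "+"))
  sel <- abs(r - r0) <= map$spacing_mm / 2
  v <- T[ix, , ][sel]
  if (mean(v) == 0) return(0)
  sd(v) / mean(v)
}
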