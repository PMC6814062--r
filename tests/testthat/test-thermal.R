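mini_map <- function(spacing = 1, extent = 25)
  build_tissue_map(geometry_params(grid_spacing_mm = spacing,
                                   domain_extent_mm = rep(extent, 3)))

test_that("a point impulse relaxes to the analytic 3-D heat kernel", {
  map <- mini_map()
  th <- thermal_params(time_step_s = 2)
  d <- dim(map$labels)
  T <- array(0, d)
  c0 <- (d + 1) / 2
  T[c0[1], c0[2], c0[3]] <- 1
  n_steps <- 10
  for (s in 1:n_steps) T <- thermal_step(T, NULL, th, map)
  # Green's function oracle: unit mass spread over t = n * dt
  sig <- sqrt(2 * th$diffusivity_m2s * n_steps * th$time_step_s) * 1e3  # mm
  g1 <- function(x) exp(-x^2 / (2 * sig^2)) / sqrt(2 * pi * sig^2)
  Ga <- outer(outer(g1(map$x), g1(map$y)), g1(map$z))
  expect_lt(sqrt(sum((T - Ga)^2) / sum(Ga^2)), 0.01)
})

test_that("heat is conserved over 100 source-free steps in a padded domain", {
  map <- mini_map(extent = 49)   # pad: diffusion length ~5 mm at 100 s
  th <- thermal_params(time_step_s = 1)
  T <- array(0, dim(map$labels))
  T[25, 25, 25] <- 1
  tot0 <- sum(T)
  for (s in 1:100) T <- thermal_step(T, NULL, th, map)
  expect_lt(abs(sum(T) - tot0) / tot0, 0.005)
})

test_that("zero stays zero, sources superpose, and the solver is linear", {
  map <- mini_map()
  th <- thermal_params(time_step_s = 2)
  expect_true(all(thermal_step(NULL, NULL, th, map) == 0))
  q <- array(0, dim(map$labels)); q[10, 12, 14] <- 5e5
  ser1 <- simulate_temperature(q, th, map, 60)
  ser2 <- simulate_temperature(2 * q, th, map, 60)
  expect_equal(ser2$final, 2 * ser1$final, tolerance = 1e-12)
  # all-OFF schedule keeps a uniform field uniform (no spurious gradients
  # away from the absorbing boundary)
  Tu <- array(1, dim(map$labels))
  ser3 <- simulate_temperature(q, th, map, 8, duty = 0, T0 = Tu)
  core <- ser3$final[11:15, 11:15, 11:15]   # deeper than the boundary halo
  expect_lt(max(core) - min(core), 1e-6)
})

test_that("under-resolved kernels are rejected", {
  map <- mini_map()
  expect_error(thermal_step(NULL, NULL, thermal_params(time_step_s = 0.2),
                            map), "under-resolved")
})

test_that("time_lag handles constructed series, decay and too-short runs", {
  ser <- structure(list(t_s = seq(2, 400, by = 2),
                        probe_degC = exp(-seq(2, 400, by = 2) / 50)),
                   class = "temperature_series")
  expect_equal(time_lag(ser, t_end_s = 10), 0)       # monotone decay
  y <- dnorm(seq(2, 400, by = 2), mean = 50, sd = 30)
  ser$probe_degC <- y                                 # peak inserted at 50 s
  expect_equal(time_lag(ser, t_end_s = 10), 40, tolerance = 0.01)
  ser$probe_degC <- seq_along(ser$t_s)                # still rising
  expect_error(time_lag(ser, t_end_s = 10), "too short")
})

test_that("cortical-only impulse response peaks after sonication, tumoral does not", {
  w <- small_world()
  th <- thermal_params(time_step_s = 4)
  p <- source_params()
  oven <- oven_effect_source(w$If, inner_cortical_facet(w$map), w$map, p)
  probe <- c(0, 0, w$pf$focus_z_mm)
  ser_c <- impulse_response(oven, th, w$map, probe, follow_s = 500)
  eps_c <- time_lag(ser_c)
  expect_gt(eps_c, 20)      # delayed centripetal heating
  direct <- direct_absorption_source(w$If, w$map, p)
  ser_t <- impulse_response(direct, th, w$map, probe, follow_s = 200)
  expect_lt(time_lag(ser_t), 8)  # focal deposit: peak at the end of the pulse
})

test_that("quadratic surface fit recovers exact quadratics to machine precision", {
  set.seed(3)
  tab <- expand.grid(R_mm = seq(6, 10, length.out = 6),
                     H_mm = seq(-5, 5, length.out = 6))
  co <- c(c00 = 236, c10 = 7.83, c01 = -65, c20 = 1.54, c11 = -4, c02 = 7.94)
  tab$eps_s <- co["c00"] + co["c10"] * tab$H_mm + co["c01"] * tab$R_mm +
    co["c20"] * tab$H_mm^2 + co["c11"] * tab$H_mm * tab$R_mm +
    co["c02"] * tab$R_mm^2
  fit <- fit_lag_surface(tab)
  expect_equal(unname(fit$coefficients), unname(co), tolerance = 1e-9)
  expect_lt(fit$mean_abs_residual_s, 1e-9)
  expect_equal(unname(predict_lag(fit, 0, 6)),
               unname(co["c00"] + 6 * co["c01"] + 36 * co["c02"]),
               tolerance = 1e-9)
  # rank-deficient designs error
  tab2 <- tab; tab2$H_mm <- 0
  expect_error(fit_lag_surface(tab2), "rank")
})

test_that("ring uniformity is zero for uniform fields and positive otherwise", {
  w <- small_world()
  expect_equal(ring_uniformity(array(3, dim(w$map$labels)), w$map), 0)
  T <- array(0, dim(w$map$labels))
  T[, , w$map$z > 0] <- 1
  expect_gt(ring_uniformity(T, w$map), 0.5)
})
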