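quiet_cfg <- thermo_config(noise_std_degC = 0, drift = function(t) 0)

test_that("noise- and drift-free frames equal the slab-averaged truth", {
  w <- small_world()
  T <- array(0, dim(w$map$labels))
  T[, , w$map$z > 0] <- 2
  fr <- sample_frame(T, w$map, quiet_cfg)
  expect_equal(max(abs(fr[!attr(fr, "mask")] -
                         apply(T[abs(w$map$x) <= 2, , ], c(2, 3),
                               mean)[!attr(fr, "mask")])), 0)
  # masked classes are NaN in every frame
  expect_true(all(is.nan(fr[attr(fr, "mask")])))
  ix <- which.min(abs(w$map$x))
  cort <- w$map$labels[ix, , ] == TISSUE_CODES[["cortical"]]
  expect_true(all(is.nan(fr[cort])))
})

test_that("temporal noise std reproduces the configured 0.2 degC", {
  w <- small_world()
  cfg <- thermo_config(drift = function(t) 0)
  T <- array(1, dim(w$map$labels))
  set.seed(5)
  frames <- replicate(100, as.vector(sample_frame(T, w$map, cfg)))
  ok <- is.finite(frames[, 1])
  # mean per-pixel temporal std across the slice, as reported "on average"
  expect_equal(mean(apply(frames[ok, ], 1, sd)), 0.2, tolerance = 0.02)
  # seed reproducibility: identical noise for identical seeds
  set.seed(99); f1 <- sample_frame(T, w$map, cfg)
  set.seed(99); f2 <- sample_frame(T, w$map, cfg)
  expect_identical(f1, f2)
})

test_that("drift correction recovers injected drift", {
  w <- small_world()
  T <- array(0, dim(w$map$labels))
  # uniform 1.0 degC drift, no noise: correction restores truth exactly
  cfg <- thermo_config(noise_std_degC = 0, drift = function(t) 1.0)
  fr <- drift_correct(sample_frame(T, w$map, cfg, t_s = 60))
  expect_lt(max(abs(fr[!attr(fr, "mask")])), 1e-12)
  # linear drift 0.05 degC/min over 12 min with noise: residual bias small
  cfg2 <- thermo_config(drift = function(t) 0.05 * t / 60)
  set.seed(8)
  frs <- replicate(50, {
    f <- drift_correct(sample_frame(T, w$map, cfg2, t_s = 720))
    mean(f[!attr(f, "mask")])
  })
  expect_lt(abs(mean(frs)), 0.05)
  # correction commutes with adding a uniform offset
  cfg3 <- quiet_cfg
  f3 <- sample_frame(T, w$map, cfg3)
  expect_equal(drift_correct(f3 + 0.7), drift_correct(f3),
               ignore_attr = TRUE)
})

test_that("drift correction warns when the reference ROI is heated", {
  w <- small_world()
  T <- array(1, dim(w$map$labels))   # everything heated
  fr <- sample_frame(T, w$map, quiet_cfg)
  expect_warning(drift_correct(fr, truth = fr), "heated")
})

test_that("the 13-pixel ROI is a disc of radius 2 and its mean tracks truth", {
  w <- small_world()
  T <- array(0, dim(w$map$labels))
  fr <- sample_frame(T + 6, w$map, quiet_cfg)
  roi <- roi_disc(fr, c(0, w$map$params$cortical_radius_mm))
  expect_equal(nrow(roi), 13)
  ctr <- c(which.min(abs(attr(fr, "y_mm"))),
           which.min(abs(attr(fr, "z_mm") -
                           w$map$params$cortical_radius_mm)))
  expect_true(all((roi[, 1] - ctr[1])^2 + (roi[, 2] - ctr[2])^2 <= 4))
  expect_equal(roi_mean(fr, roi), 6)
  # focal ROI mean tracks the true focal elevation closely (noise-free)
  pl <- default_plant()
  ser <- simulate_temperature(pl$q_full, thermal_params(time_step_s = 2),
                              pl$map, 60, duty = 0.3)
  fr2 <- sample_frame(ser$final, pl$map, quiet_cfg)
  roi2 <- roi_disc(fr2, c(0, pl$focus_z_mm))
  truth_roi <- mean(apply(ser$final[abs(pl$map$x) <= 2, , ],
                          c(2, 3), mean)[roi2])
  expect_equal(roi_mean(fr2, roi2), truth_roi, tolerance = 1e-9)
  # mostly-masked ROI errors
  cort_ctr <- c(0, -(w$map$params$cortical_radius_mm - 1))
  expect_error(roi_mean(fr, roi_disc(fr, cort_ctr)), "masked")
})

test_that("virtual sensor quantizes to 0.1 degC at an intracortical locus", {
  w <- small_world()
  T <- array(0.234, dim(w$map$labels))
  expect_equal(virtual_sensor(T, w$map), 0.2)
  loc <- sensor_locus(w$map)
  i <- osteotherm:::.voxel_index(w$map, loc)
  expect_equal(unname(w$map$labels[i]), unname(TISSUE_CODES[["cortical"]]))
})

test_that("cross-correlation statistics behave on constructed traces", {
  t <- seq(0, 100, by = 1.6)
  y <- 6 * (1 - exp(-t / 40))
  # identical series
  xc <- cross_correlate(t, y, t, y)
  expect_equal(xc$r, 1)
  expect_equal(xc$mean_offset, 0)
  # constant offset: sensor = prfs + 0.75 -> mean offset -0.75, r = 1
  xc2 <- cross_correlate(t, y, t, y + 0.75)
  expect_equal(xc2$r, 1)
  expect_equal(xc2$mean_offset, -0.75)
  expect_equal(xc2$min_offset, -0.75)
  # too little overlap errors
  expect_error(cross_correlate(t[1:4], y[1:4], t[1:4], y[1:4]), "10")
})
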