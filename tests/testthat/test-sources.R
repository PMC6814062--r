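# unit-constant parameters isolate the spec'd relations from the calibrated
# in-situ efficiency
unit_params <- function(...) source_params(efficiency = 1, ...)

test_that("0.5 dB/cm/MHz converts to 5.756 Np/m and q = 2 beta I", {
  w <- small_world()
  p <- unit_params()
  expect_equal(p$beta_Npm, 5.756, tolerance = 1e-3)
  I <- array(1e4, dim(w$map$labels))      # uniform 10^4 W/m^2
  src <- direct_absorption_source(I, w$map, p)
  gel <- w$map$labels == TISSUE_CODES[["tumour_gel"]]
  expect_equal(unique(src$q[gel]), 2 * p$beta_Npm * 1e4, tolerance = 1e-9)
  expect_equal(unique(src$q[gel]) / 1.15e5, 1, tolerance = 0.005)
  # zero in cortical bone
  expect_true(all(src$q[w$map$labels == TISSUE_CODES[["cortical"]]] == 0))
})

test_that("direct source is zero for a zero field and maximal at the focus", {
  w <- small_world()
  p <- unit_params()
  z <- direct_absorption_source(array(0, dim(w$map$labels)), w$map, p)
  expect_true(all(z$q == 0))
  src <- direct_absorption_source(w$If, w$map, p)
  ijk <- arrayInd(which.max(src$q), dim(src$q))
  expect_equal(w$map$z[ijk[3]], w$pf$focus_z_mm, tolerance = 1.01)
})

test_that("oven power bookkeeping matches direct summation within 0.5%", {
  w <- small_world()
  p <- unit_params(alpha = 0.37, deposition_layers = 2L)
  src <- oven_effect_source(w$If, w$facet, w$map, p)
  # independent summation oracle
  P_inc <- sum(w$If$I[w$facet]) * (w$map$spacing_mm * 1e-3)^2
  expect_equal(attr(src, "incident_power_W"), P_inc, tolerance = 1e-12)
  expect_equal(total_source_power(src) / (0.37 * P_inc), 1, tolerance = 0.005)
  # alpha = 0 gives the cooling configuration
  z <- oven_effect_source(w$If, w$facet, w$map, unit_params(alpha = 0))
  expect_true(all(z$q == 0))
})

test_that("uniform incident intensity is a fixed point of the averaging", {
  w <- small_world()
  p <- unit_params(alpha = 0.5, deposition_layers = 1L)
  I1 <- array(2e4, dim(w$map$labels))
  src_u <- oven_effect_source(I1, w$facet, w$map, p)
  # averaging a point-symmetric (here uniform) facet pattern changes nothing:
  # deposited density equals alpha * I * dA * N / (N * vol) voxel-wise
  q_expect <- 0.5 * 2e4 * (w$map$spacing_mm * 1e-3)^2 /
    (w$map$spacing_mm * 1e-3)^3
  expect_equal(unique(src_u$q[w$facet]), q_expect, tolerance = 1e-9)
})

test_that("oven term is invariant under rotation of the incident pattern", {
  # closed ring (no breakthrough): rotate the intensity pattern 90 degrees
  # about the bone axis; the averaged deposit must not change
  geo <- geometry_params(cone_aperture_deg = 0, grid_spacing_mm = 1,
                         domain_extent_mm = c(20, 20, 20))
  map <- build_tissue_map(geo)
  facet <- inner_cortical_facet(map)
  set.seed(7)
  I <- array(runif(length(map$labels), 0, 1e4), dim(map$labels))
  Irot <- aperm(I, c(1, 3, 2))[, , dim(I)[2]:1]     # (y,z) -> (z,-y)
  p <- unit_params(alpha = 0.8)
  q1 <- oven_effect_source(I, facet, map, p)
  q2 <- oven_effect_source(Irot, facet, map, p)
  expect_equal(total_source_power(q1), total_source_power(q2),
               tolerance = 1e-10)
})

test_that("combine_sources sums voxel-wise with provenance union", {
  w <- small_world()
  p <- unit_params()
  a <- direct_absorption_source(w$If, w$map, p)
  b <- oven_effect_source(w$If, w$facet, w$map, p)
  both <- combine_sources(a, b)
  expect_equal(both$q, a$q + b$q)
  expect_setequal(both$provenance, c("tumoral", "cortical"))
  # identity with a zero source
  b0 <- b; b0$q <- array(0, dim(b$q))
  expect_equal(combine_sources(a, b0)$q, a$q)
  # linearity of totals
  expect_equal(total_source_power(both),
               total_source_power(a) + total_source_power(b))
  # grid mismatch errors
  small <- build_tissue_map(geometry_params(grid_spacing_mm = 1,
                                            domain_extent_mm = rep(24, 3)))
  c2 <- direct_absorption_source(array(0, dim(small$labels)), small, p)
  expect_error(combine_sources(a, c2), "match")
})

test_that("cumulated session source has a focal maximum and a cortical ring, within the power budget", {
  pl <- default_plant()
  q <- pl$q_full
  # total deposited power never exceeds the acoustic power
  expect_lt(total_source_power(q), pl$field$spec$acoustic_power_W)
  # focal maximum in soft tissue
  ijk <- arrayInd(which.max(q$q), dim(q$q))
  expect_equal(pl$map$z[ijk[3]], pl$focus_z_mm, tolerance = 1.01)
  # non-zero deposit on the cortical shell (the ring term)
  cort <- pl$map$labels == TISSUE_CODES[["cortical"]]
  expect_gt(sum(q$q[cort] > 0), 100)
  expect_setequal(q$provenance, c("tumoral", "cortical"))
})

test_that("empty facet produces a zero source with a warning", {
  w <- small_world()
  expect_warning(
    z <- oven_effect_source(w$If, integer(0), w$map, unit_params()),
    "empty")
  expect_true(all(z$q == 0))
})
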