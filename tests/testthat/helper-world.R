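# Shared miniature worlds, built once per test run.
# Coarse grids keep unit tests fast; the acceptance tests use the
# package-default desk-scale world (1 mm grid) via the same cache.

.world_env <- new.env()

# small phantom: Rc = 6 mm, 2 mm grid, 32 mm domain
small_world <- function() {
  w <- .world_env$small
  if (!is.null(w)) return(w)
  geo <- geometry_params(grid_spacing_mm = 1, domain_extent_mm = c(32, 32, 32))
  map <- build_tissue_map(geo)
  spec <- transducer_spec(element_size_mm = 1.0)  # coarse cap for speed
  med <- medium_spec()
  pf <- rayleigh_pressure(spec, med, map, warn_aliasing = FALSE)
  If <- intensity_from_pressure(pf)
  facet <- inner_cortical_facet(map, beam_cone(pf$focus_z_mm, 27.5))
  w <- list(geo = geo, map = map, spec = spec, med = med,
            pf = pf, If = If, facet = facet)
  .world_env$small <- w
  w
}

# default desk-scale session plant (cached across acceptance tests)
default_plant <- function() {
  w <- .world_env$plant
  if (!is.null(w)) return(w)
  w <- build_plant(session_config())
  .world_env$plant <- w
  w
}
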