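#' Tissue class codes
#'
#' Integer codes used in the `labels` array of a `tissue_map`. The phantom
#' distinguishes the ambient coupling medium (water or muscle), the cortical
#' shell, the medullar interior, and the tumour-mimicking gel filling the
#' osteolytic breakthrough.
#'
#' @format Named integer vector.
#' @export
TISSUE_CODES <- c(water = 0L, muscle = 1L, tumour_gel = 2L,
                  cortical = 3L, medulla = 4L)

# soft-tissue classes that absorb ultrasound and carry PRFS signal
.soft_codes <- function() TISSUE_CODES[c("muscle", "tumour_gel", "medulla")]

#' Geometry parameters for the osteolytic-lesion phantom
#'
#' The bone is a cylinder of outer radius `cortical_radius` along the x axis,
#' with a cortical shell of the given thickness. The osteolytic breakthrough
#' is the intersection of the cylinder with a cone whose apex sits on the
#' cylinder axis and whose axis is the beam (+z) axis, opening toward the
#' transducer; breakthrough voxels are filled with tumour-mimicking gel.
#'
#' @param cortical_radius_mm Outer radius of the bone cylinder (mm). The
#'   medullar cavity has radius `cortical_radius_mm - cortical_thickness_mm`.
#' @param cortical_thickness_mm Cortical shell thickness (mm). The paper gives
#'   only "a few millimeters"; 3 mm is the package default.
#' @param cone_aperture_deg Full aperture of the breakthrough cone (deg).
#' @param grid_spacing_mm Isotropic voxel spacing (mm).
#' @param domain_extent_mm Numeric length-3, physical extent (mm) along
#'   (x, y, z). The cylinder is finite, spanning the domain along x.
#' @param exterior `"muscle"` (default) or `"water"`: class of voxels outside
#'   the bone and breakthrough cone.
#' @return Object of class `geometry_params`.
#' @export
geometry_params <- function(cortical_radius_mm = 6,
                            cortical_thickness_mm = 3,
                            cone_aperture_deg = 72,
                            grid_spacing_mm = 1,
                            domain_extent_mm = c(48, 48, 48),
                            exterior = c("muscle", "water")) {
  exterior <- match.arg(exterior)
  stopifnot(grid_spacing_mm > 0,
            cortical_thickness_mm < cortical_radius_mm,
            cone_aperture_deg >= 0, cone_aperture_deg < 180,
            length(domain_extent_mm) == 3, all(domain_extent_mm > 0))
  structure(list(cortical_radius_mm = cortical_radius_mm,
                 cortical_thickness_mm = cortical_thickness_mm,
                 cone_aperture_deg = cone_aperture_deg,
                 grid_spacing_mm = grid_spacing_mm,
                 domain_extent_mm = domain_extent_mm,
                 exterior = exterior),
            class = "geometry_params")
}

# voxel-center coordinates: odd counts, centred on 0 so the cylinder axis,
# the cone apex and the breakthrough plane all fall on voxel centres
.grid_axes <- function(params) {
  h <- params$grid_spacing_mm
  lapply(params$domain_extent_mm, function(E) {
    n <- 2L * floor(E / (2 * h)) + 1L
    (seq_len(n) - (n + 1L) / 2L) * h
  })
}

#' Build the voxelized tissue map
#'
#' Assigns every voxel exactly one tissue class by geometric membership:
#' voxels inside both the cylinder and the breakthrough cone are tumour gel,
#' the remaining annulus `Rc - thickness < r <= Rc` is cortical bone, the
#' remaining interior is medulla, and the exterior is muscle (or water).
#'
#' @param params A [geometry_params] object.
#' @return Object of class `tissue_map`: list with `labels` (3-D integer
#'   array), `x`, `y`, `z` voxel-centre coordinates (mm), `spacing_mm`,
#'   `origin_mm` and the generating `params`.
#' @export
build_tissue_map <- function(params) {
  stopifnot(inherits(params, "geometry_params"))
  h <- params$grid_spacing_mm
  if (params$cortical_thickness_mm / h < 2)
    stop("grid too coarse to resolve the cortical shell ",
         "(need >= 2 voxels across its thickness)")
  ax <- .grid_axes(params)
  x <- ax[[1]]; y <- ax[[2]]; z <- ax[[3]]
  nx <- length(x); ny <- length(y); nz <- length(z)
  Rc <- params$cortical_radius_mm
  Ri <- Rc - params$cortical_thickness_mm
  tanh2 <- tan(params$cone_aperture_deg / 2 * pi / 180)

  # cylinder radius uses (y, z); cone is about +z with apex at the origin
  r_cyl2 <- outer(y^2, z^2, "+")                    # ny x nz
  in_cyl <- r_cyl2 <= Rc^2
  in_med <- r_cyl2 <= Ri^2
  lab_yz <- matrix(TISSUE_CODES[[params$exterior]], ny, nz)
  lab_yz[in_cyl] <- TISSUE_CODES[["cortical"]]
  lab_yz[in_med] <- TISSUE_CODES[["medulla"]]

  labels <- array(0L, c(nx, ny, nz))
  zp <- matrix(z, ny, nz, byrow = TRUE)             # z coordinate, ny x nz
  y2 <- matrix(y^2, ny, nz)
  for (i in seq_len(nx)) {
    li <- lab_yz
    if (params$cone_aperture_deg > 0) {
      in_cone <- zp > 0 & (x[i]^2 + y2) <= (zp * tanh2)^2
      li[in_cone & in_cyl] <- TISSUE_CODES[["tumour_gel"]]
    }
    labels[i, , ] <- li
  }
  structure(list(labels = labels, x = x, y = y, z = z,
                 spacing_mm = h,
                 origin_mm = c(x[1], y[1], z[1]),
                 params = params),
            class = "tissue_map")
}

#' @export
print.tissue_map <- function(x, ...) {
  d <- dim(x$labels)
  cat("tissue_map:", paste(d, collapse = " x "), "voxels @",
      x$spacing_mm, "mm\n")
  tb <- table(factor(x$labels, levels = TISSUE_CODES,
                     labels = names(TISSUE_CODES)))
  print(tb)
  invisible(x)
}

#' Tissue volumes
#'
#' @param map A `tissue_map` (see [build_tissue_map()]).
#' @return Named numeric vector of per-class volumes in mm^3.
#' @export
tissue_volumes <- function(map) {
  v <- map$spacing_mm^3
  tb <- tabulate(map$labels + 1L, nbins = length(TISSUE_CODES))
  setNames(tb * v, names(TISSUE_CODES))
}

#' Inner cortical facet exposed to the beam
#'
#' Returns the cortical voxels adjacent (6-neighbourhood) to the medullar
#' cavity that lie inside the post-focal beam cone. This is the surface on
#' which the "acoustic oven" term deposits the averaged post-focal energy.
#'
#' @param map A `tissue_map` (see [build_tissue_map()]).
#' @param beam Optional beam description as returned by [beam_cone()]; if
#'   `NULL`, the whole inner facet is returned.
#' @return Integer vector of linear voxel indices into `map$labels`, with
#'   attribute `area_mm2` (per-voxel surface measure, `spacing^2`). Empty
#'   (with a warning) if the beam misses the bone.
#' @export
inner_cortical_facet <- function(map, beam = NULL) {
  lab <- map$labels
  d <- dim(lab)
  cort <- which(lab == TISSUE_CODES[["cortical"]])
  if (!length(cort)) stop("tissue map contains no cortical voxels")
  cavity <- lab == TISSUE_CODES[["medulla"]] | lab == TISSUE_CODES[["tumour_gel"]]
  idx <- arrayInd(cort, d)
  adj <- logical(length(cort))
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- idx
    nb[, ax] <- nb[, ax] + s
    ok <- nb[, ax] >= 1L & nb[, ax] <= d[ax]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    adj[ok] <- adj[ok] | cavity[lin]
  }
  facet <- cort[adj]
  if (!is.null(beam)) {
    fi <- arrayInd(facet, d)
    px <- map$x[fi[, 1]]; py <- map$y[fi[, 2]]; pz <- map$z[fi[, 3]]
    keep <- .in_postfocal_cone(px, py, pz, beam)
    facet <- facet[keep]
    if (!length(facet)) warning("beam misses the bone: empty cortical facet")
  }
  attr(facet, "area_mm2") <- map$spacing_mm^2
  facet
}

#' Post-focal beam cone
#'
#' Geometric description of the diverging beam past the focus, used to select
#' the exposed portion of the inner cortical facet.
#'
#' @param focus_z_mm Focal z coordinate (mm); the beam propagates toward -z.
#' @param half_angle_deg Divergence half-angle (deg); for a spherical cap this
#'   is `asin(aperture/2 / focal_radius)`.
#' @param waist_mm Focal waist added to the cone radius (mm).
#' @return List of class `beam_cone`.
#' @export
beam_cone <- function(focus_z_mm, half_angle_deg, waist_mm = 1) {
  structure(list(focus_z_mm = focus_z_mm,
                 half_angle_deg = half_angle_deg,
                 waist_mm = waist_mm),
            class = "beam_cone")
}

.in_postfocal_cone <- function(px, py, pz, beam) {
  dz <- beam$focus_z_mm - pz
  r <- sqrt(px^2 + py^2)
  dz > 0 & r <= dz * tan(beam$half_angle_deg * pi / 180) + beam$waist_mm
}

#' Cortical shadow mask of the focused beam
#'
#' Cortical bone is essentially opaque to the beam; the free-field intensity
#' is therefore masked wherever the acoustic path is blocked. All rays of a
#' focused beam pass (approximately) through the focal point, so a voxel is
#' shadowed when the segment from the focus to its centre crosses cortical
#' bone. The last voxel length of each segment is excluded so that the first
#' cortical layer hit by the beam (the exposed facet) is not self-shadowed.
#'
#' @param map A `tissue_map` (see [build_tissue_map()]).
#' @param focus_z_mm Focal z coordinate (mm), on the beam axis.
#' @return Logical array (`TRUE` = shadowed) with the map's dimensions.
#' @export
beam_shadow <- function(map, focus_z_mm) {
  d <- dim(map$labels)
  cort <- map$labels == TISSUE_CODES[["cortical"]]
  h <- map$spacing_mm
  g <- expand.grid(x = map$x, y = map$y, z = map$z)
  dx <- g$x; dy <- g$y; dz <- g$z - focus_z_mm
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  step <- h / 2
  nseg <- pmax(0L, floor((dist - h) / step))
  shadow <- logical(nrow(g))
  ax <- list(map$x, map$y, map$z)
  for (s in seq_len(max(nseg))) {
    act <- which(nseg >= s & !shadow)
    if (!length(act)) break
    f <- s * step / dist[act]
    ix <- pmin(pmax(round((dx[act] * f - ax[[1]][1]) / h), 0), d[1] - 1L)
    iy <- pmin(pmax(round((dy[act] * f - ax[[2]][1]) / h), 0), d[2] - 1L)
    iz <- pmin(pmax(round((focus_z_mm + dz[act] * f - ax[[3]][1]) / h), 0),
               d[3] - 1L)
    lin <- 1L + ix + iy * d[1] + iz * d[1] * d[2]
    shadow[act] <- cort[lin]
  }
  array(shadow, d)
}
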