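#' PRFS thermometry emulation configuration
#'
#' Single-slice acquisition: 1 x 1 mm in-plane, 4 mm slice, 1.6 s frames,
#' 0.2 degC pixel noise, slow background phase drift, and signal voids
#' (NaN) in cortical bone and fatty medulla (fat-suppressed sequence; PRFS
#' does not apply there).
#'
#' @param inplane_mm In-plane pixel size (mm).
#' @param slice_mm Slice thickness (mm).
#' @param frame_interval_s Temporal resolution (s).
#' @param noise_std_degC Per-pixel temporal noise sd.
#' @param drift Function of time (s) returning the spatially uniform drift
#'   (degC-equivalent); default linear 0.3 degC over 12 min plus a slow
#'   0.1 degC sinusoid.
#' @param mask_classes Tissue classes carrying no PRFS signal.
#' @return Object of class `thermo_config`.
#' @export
thermo_config <- function(inplane_mm = 1, slice_mm = 4,
                          frame_interval_s = 1.6, noise_std_degC = 0.2,
                          drift = function(t) 0.3 * t / 720 +
                            0.1 * sin(2 * pi * t / 240),
                          mask_classes = c("cortical", "medulla")) {
  stopifnot(noise_std_degC >= 0, frame_interval_s > 0)
  structure(list(inplane_mm = inplane_mm, slice_mm = slice_mm,
                 frame_interval_s = frame_interval_s,
                 noise_std_degC = noise_std_degC, drift = drift,
                 mask_classes = mask_classes),
            class = "thermo_config")
}

#' Sample one thermometry frame
#'
#' Axial single slice through `x = slice_x_mm`: the truth field is averaged
#' across the slice thickness, Gaussian noise and the global drift are
#' added, and masked tissue classes are set to NaN (mask taken from the
#' central slice of the label map).
#'
#' @param T Temperature-elevation array (truth).
#' @param map A `tissue_map` (see [build_tissue_map()]) (grid assumed at the acquisition in-plane
#'   resolution).
#' @param cfg A [thermo_config].
#' @param t_s Acquisition time (s), drives the drift term.
#' @param slice_x_mm Slice position along the bone axis.
#' @return `thermo_frame`: numeric matrix (ny x nz) with attributes `y_mm`,
#'   `z_mm`, `t_s`, `mask` (logical matrix of voids).
#' @export
sample_frame <- function(T, map, cfg, t_s = 0, slice_x_mm = 0) {
  sel <- which(abs(map$x - slice_x_mm) <= cfg$slice_mm / 2)
  slab <- apply(T[sel, , , drop = FALSE], c(2, 3), mean)
  ix <- sel[which.min(abs(map$x[sel] - slice_x_mm))]
  mask <- matrix(map$labels[ix, , ] %in% TISSUE_CODES[cfg$mask_classes],
                 nrow = dim(T)[2])
  fr <- slab + cfg$drift(t_s)
  if (cfg$noise_std_degC > 0)
    fr <- fr + matrix(rnorm(length(fr), 0, cfg$noise_std_degC), nrow(fr))
  fr[mask] <- NaN
  structure(fr, y_mm = map$y, z_mm = map$z, t_s = t_s, mask = mask,
            class = c("thermo_frame", "matrix", "array"))
}

#' Pixel indices of an unheated reference ROI
#'
#' A square patch of muscle in a frame corner, lateral to the beam, used for
#' background drift correction.
#'
#' @param frame A `thermo_frame`.
#' @param size_px Patch edge length (pixels).
#' @return Integer matrix of (row, col) indices.
#' @export
unheated_roi <- function(frame, size_px = 3) {
  as.matrix(expand.grid(row = 2:(1 + size_px), col = 2:(1 + size_px)))
}

#' Background drift correction
#'
#' Subtracts the mean of a small unheated ROI from the whole frame; the
#' spatially uniform phase drift cancels exactly (up to ROI noise).
#'
#' @param frame A `thermo_frame`.
#' @param roi Pixel index matrix, e.g. [unheated_roi()].
#' @param truth Optional truth field slice: warns if the ROI overlaps heated
#'   tissue (truth elevation > 0.5 degC).
#' @return Corrected `thermo_frame`.
#' @export
drift_correct <- function(frame, roi = unheated_roi(frame), truth = NULL) {
  v <- frame[roi]
  if (sum(is.finite(v)) < 5)
    stop("unheated ROI needs >= 5 unmasked pixels")
  if (!is.null(truth) && any(truth[roi] > 0.5, na.rm = TRUE))
    warning("unheated ROI overlaps heated region (truth > 0.5 degC)")
  out <- frame - mean(v, na.rm = TRUE)
  attributes(out) <- attributes(frame)
  out
}

#' 13-pixel disc ROI
#'
#' The centre pixel plus its 12 nearest in-plane neighbours (all pixels
#' with squared pixel distance <= 4), matching the 13-pixel ROI used for
#' the focal-point average.
#'
#' @param frame A `thermo_frame` (or any matrix with `y_mm`/`z_mm`).
#' @param center_mm (y, z) centre in mm.
#' @return Integer matrix of (row, col) indices, 13 rows.
#' @export
roi_disc <- function(frame, center_mm) {
  y <- attr(frame, "y_mm"); z <- attr(frame, "z_mm")
  r0 <- which.min(abs(y - center_mm[1]))
  c0 <- which.min(abs(z - center_mm[2]))
  off <- expand.grid(dr = -2:2, dc = -2:2)
  off <- off[off$dr^2 + off$dc^2 <= 4, ]
  idx <- cbind(row = r0 + off$dr, col = c0 + off$dc)
  idx[idx[, 1] >= 1 & idx[, 1] <= length(y) &
      idx[, 2] >= 1 & idx[, 2] <= length(z), , drop = FALSE]
}

#' ROI mean of a frame
#'
#' NaN-excluding mean; errors if more than half the ROI is masked.
#'
#' @param frame A `thermo_frame`.
#' @param roi Pixel index matrix.
#' @return Mean elevation (degC).
#' @export
roi_mean <- function(frame, roi) {
  v <- frame[roi]
  if (mean(!is.finite(v)) > 0.5) stop("more than 50% of the ROI is masked")
  mean(v, na.rm = TRUE)
}

#' Intracortical virtual sensor reading
#'
#' Fluoroptic point sensor emulation: the truth elevation at an
#' intracortical locus, quantized to the instrument precision (0.1 degC).
#'
#' @param T Temperature array.
#' @param map A `tissue_map` (see [build_tissue_map()]).
#' @param locus_mm Sensor position (x, y, z) mm; default: distal inner
#'   cortex (opposite the breakthrough), two-thirds into the cortical
#'   thickness.
#' @param precision_degC Quantization step.
#' @return Scalar reading (degC).
#' @export
virtual_sensor <- function(T, map, locus_mm = NULL, precision_degC = 0.1) {
  if (is.null(locus_mm)) locus_mm <- sensor_locus(map)
  round(T[.voxel_index(map, locus_mm)] / precision_degC) * precision_degC
}

#' Periosteal PRFS probe locus
#'
#' The soft-tissue voxel used as the PRFS stand-in for cortical-bone
#' temperature: in the imaging plane (x = 0), adjacent (6-neighbourhood) to
#' a cortical voxel, beyond the focus along the beam (`z < focus_z`), and
#' closest to the focal point — i.e. adjacent to the periosteum immediately
#' behind the focal point, where MR signal is preserved.
#'
#' @param map A `tissue_map` (see [build_tissue_map()]).
#' @param focus_z_mm Focal z coordinate (mm).
#' @return (row, col) in-plane pixel indices (y, z) as a 1 x 2 matrix, with
#'   attribute `mm` giving the (y, z) coordinates.
#' @export
periosteal_locus <- function(map, focus_z_mm) {
  d <- dim(map$labels)
  ix <- which.min(abs(map$x))
  lab <- map$labels[ix, , ]
  soft <- matrix(lab %in% .soft_codes() &
                   !(lab %in% TISSUE_CODES[["medulla"]]), d[2], d[3])
  cort <- matrix(lab == TISSUE_CODES[["cortical"]], d[2], d[3])
  adj <- matrix(FALSE, d[2], d[3])
  adj[-1, ] <- adj[-1, ] | cort[-d[2], ]
  adj[-d[2], ] <- adj[-d[2], ] | cort[-1, ]
  adj[, -1] <- adj[, -1] | cort[, -d[3]]
  adj[, -d[3]] <- adj[, -d[3]] | cort[, -1]
  cand <- which(soft & adj, arr.ind = TRUE)
  zc <- map$z[cand[, 2]]
  cand <- cand[zc < focus_z_mm, , drop = FALSE]
  if (!nrow(cand)) stop("no periosteal soft-tissue voxel behind the focus")
  dist2 <- map$y[cand[, 1]]^2 + (map$z[cand[, 2]] - focus_z_mm)^2
  best <- cand[which.min(dist2), , drop = FALSE]
  attr(best, "mm") <- c(map$y[best[1]], map$z[best[2]])
  best
}

#' Default intracortical sensor locus
#' @param map A `tissue_map` (see [build_tissue_map()]).
#' @return (x, y, z) mm inside the distal cortical wall.
#' @export
sensor_locus <- function(map) {
  p <- map$params
  r <- p$cortical_radius_mm - 2 / 3 * p$cortical_thickness_mm
  c(0, 0, -r)
}

#' Cross-correlate PRFS and sensor traces
#'
#' Pearson correlation on a common time grid (linear interpolation of the
#' sensor trace onto the PRFS times over the overlap) plus offset
#' statistics of `prfs - sensor`.
#'
#' @param t_prfs_s,prfs_degC PRFS series.
#' @param t_sensor_s,sensor_degC Sensor series.
#' @return List: `r`, `mean_offset`, `min_offset`, `max_offset`, `n`.
#' @export
cross_correlate <- function(t_prfs_s, prfs_degC, t_sensor_s, sensor_degC) {
  lo <- max(min(t_prfs_s), min(t_sensor_s))
  hi <- min(max(t_prfs_s), max(t_sensor_s))
  keep <- t_prfs_s >= lo & t_prfs_s <= hi
  if (sum(keep) < 10) stop("fewer than 10 overlapping samples")
  s <- approx(t_sensor_s, sensor_degC, xout = t_prfs_s[keep])$y
  d <- prfs_degC[keep] - s
  r <- if (sd(s) < 1e-12 || sd(prfs_degC[keep]) < 1e-12) NA_real_
       else cor(prfs_degC[keep], s)
  list(r = r, mean_offset = mean(d), min_offset = min(d),
       max_offset = max(d), n = sum(keep))
}
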