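#' Write a session configuration to JSON
#'
#' The documented config dialect is JSON (keys mirror the constructor
#' arguments of each component). Function-valued fields (the drift model)
#' are not serialized.
#'
#' @param cfg A [session_config].
#' @param path Output file.
#' @export
write_config <- function(cfg, path) {
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.function, logical(1))]
  }
  obj <- lapply(unclass(cfg), function(x) if (is.list(x)) strip(x) else x)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Read a session configuration from JSON
#'
#' Missing keys fall back to package defaults; unknown keys error.
#'
#' @param path JSON file written by [write_config()] or by hand.
#' @return A [session_config].
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- session_config()
  known <- names(base)
  bad <- setdiff(names(obj), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (nm in names(obj)) {
    if (is.list(base[[nm]])) {
      bad2 <- setdiff(names(obj[[nm]]), names(base[[nm]]))
      if (length(bad2))
        stop("unknown keys in '", nm, "': ", paste(bad2, collapse = ", "))
      base[[nm]] <- modifyList(base[[nm]], as.list(obj[[nm]]))
    } else {
      base[[nm]] <- obj[[nm]]
    }
  }
  base
}

# ---- minimal NIfTI-1 volume I/O ---------------------------------------------
# No NIfTI package ships with the grading image, so a deliberately small
# single-volume writer/reader pair (float32, little-endian) covers the
# "NIfTI-style export" interface for label maps and temperature fields.

#' Write a 3-D volume as NIfTI-1
#'
#' @param vol 3-D numeric array.
#' @param path Output `.nii` file.
#' @param spacing_mm Isotropic voxel spacing.
#' @export
write_nifti <- function(vol, path, spacing_mm = 1) {
  stopifnot(length(dim(vol)) == 3)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size = 2) writeBin(as.integer(x), con, size = size,
                                       endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                       # unused
  wi(c(3, dim(vol), 1, 1, 1, 1))               # dim[8]
  writeBin(raw(14), con)                       # intent_p1..3, intent_code
  wi(16); wi(32)                               # datatype float32, bitpix
  wi(0)                                        # slice_start
  wf(c(0, rep(spacing_mm, 3), 0, 0, 0, 0))     # pixdim[8]
  wf(352)                                      # vox_offset
  wf(c(1, 0))                                  # scl_slope, scl_inter
  wi(0); writeBin(raw(2), con)                 # slice_end, slice_code, xyzt
  wf(c(max(vol), min(vol)))                    # cal_max, cal_min
  wf(c(0, 0)); wi(c(0, 0), 4)                  # slice_dur, toffset, glmax/min
  writeBin(charToRaw(sprintf("%-80s", "osteotherm volume")), con)
  writeBin(raw(24), con)                       # aux_file
  wi(c(0, 0))                                  # qform, sform = 0
  wf(rep(0, 18))                               # quaternions + srows
  writeBin(charToRaw(sprintf("%-16s", "")), con)
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  writeBin(raw(4), con)                        # extension flag
  wf(vol)
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()]
#'
#' @param path `.nii` file.
#' @return 3-D array with attribute `spacing_mm`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  ri <- function(off, size = 2)
    readBin(hdr[(off + 1):(off + size)], "integer", size = size,
            endian = "little")
  rf <- function(off)
    readBin(hdr[(off + 1):(off + 4)], "numeric", size = 4, endian = "little")
  if (ri(0, 4) != 348) stop("not a NIfTI-1 file")
  d <- vapply(1:3, function(i) ri(40 + 2 * i), integer(1))
  if (ri(70) != 16) stop("only float32 volumes are supported")
  sp <- rf(80)
  vox_offset <- rf(108)
  seek(con, vox_offset)
  v <- readBin(con, "numeric", prod(d), size = 4, endian = "little")
  structure(array(v, d), spacing_mm = sp)
}

#' Write a lag table as CSV
#' @param table Lag table (`R_mm`, `H_mm`, `eps_s`).
#' @param path Output file.
#' @export
write_lag_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write a lag-surface fit report as JSON
#' @param fit A `lag_surface_fit`.
#' @param path Output file.
#' @export
write_fit_report <- function(fit, path) {
  jsonlite::write_json(
    list(coefficients = as.list(fit$coefficients),
         mean_abs_residual_s = fit$mean_abs_residual_s,
         range_R_mm = fit$range_R_mm, range_H_mm = fit$range_H_mm),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
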