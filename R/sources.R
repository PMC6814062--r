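#' Heat-source parameters
#'
#' `alpha` is the fraction of the post-focal beam power crossing the inner
#' cortical facet that is deposited there (the "acoustic oven" term); `beta`
#' is the soft-tissue amplitude absorption coefficient (Np/m) at the
#' operating frequency, by default derived from the medium attenuation
#' assuming absorption-dominated attenuation.
#'
#' `efficiency` and the default `alpha` are the two semi-empirical constants
#' of the thermal model. `efficiency` is the fraction of the free-field beam
#' intensity that actually thermalizes in situ: it lumps together the
#' absorbed (vs scattered) fraction of the gel/muscle attenuation, water-path
#' and transducer-drive differences from the ideal lossless bowl, and heat
#' lost to the finite, bath-cooled specimen; it scales both source terms.
#' The pair is identified once from two printed operating-point anchors of
#' the source experiment: the converged duty cycle (~0.18 at 60 W holding
#' +6 degC, fixing the focal-ROI gain) and the intracortical sensor reading
#' at optimal focus (~5.4 degC at a 6 degC cavity elevation, fixing the
#' wall-to-cavity split). See [calibrate_sources()] and the methods
#' vignette.
#'
#' @param alpha Cortical facet absorption fraction (0-1): share of the
#'   post-focal beam power crossing the facet that is deposited there.
#' @param beta_Npm Tissue absorption coefficient (Np/m); `NULL` derives it
#'   from `medium` and `frequency_Hz`.
#' @param efficiency In-situ thermalization efficiency applied to both
#'   source terms; 1 = every watt of the free-field beam heats tissue.
#' @param deposition_layers Number of innermost cortical voxel layers that
#'   receive the oven term (default 3: the full default shell).
#' @param medium,frequency_Hz Used to derive `beta_Npm` when it is `NULL`.
#' @return Object of class `source_params`.
#' @export
source_params <- function(alpha = 0.253, beta_Npm = NULL,
                          efficiency = 0.291,
                          deposition_layers = 3L,
                          medium = medium_spec(), frequency_Hz = 1e6) {
  stopifnot(alpha >= 0, alpha <= 1, efficiency > 0, efficiency <= 1)
  if (is.null(beta_Npm)) beta_Npm <- .alpha_np(medium, frequency_Hz)
  stopifnot(beta_Npm >= 0)
  structure(list(alpha = alpha, beta_Npm = beta_Npm,
                 efficiency = efficiency,
                 deposition_layers = deposition_layers),
            class = "source_params")
}

.empty_source <- function(map) {
  structure(list(q = array(0, dim(map$labels)), map = map,
                 provenance = character()),
            class = "heat_source_map")
}

#' Direct absorption heat source
#'
#' Volumetric power density `q = 2 beta I` in soft-tissue and tumour voxels
#' (plane-wave absorption of the focused beam), scaled by the in-situ
#' `efficiency`; zero in cortical bone and water.
#'
#' @param I An `intensity_field` aligned with `map`.
#' @param map A `tissue_map` (see [build_tissue_map()]).
#' @param params A [source_params].
#' @return Object of class `heat_source_map` with `q` in W/m^3.
#' @export
direct_absorption_source <- function(I, map, params) {
  A <- if (inherits(I, "intensity_field")) I$I else I
  stopifnot(all(dim(A) == dim(map$labels)))
  q <- array(0, dim(A))
  soft <- map$labels %in% .soft_codes()
  q[soft] <- 2 * params$beta_Npm * params$efficiency * A[soft]
  structure(list(q = q, map = map, provenance = "tumoral"),
            class = "heat_source_map")
}

#' "Acoustic oven" cortical heat source
#'
#' The incident free-field intensity is averaged over the exposed inner
#' cortical facet (this uniformization is the oven effect) and a fraction
#' `alpha * efficiency` of the beam power crossing the facet is deposited
#' uniformly in the cortical shell behind it — the facet voxels grown
#' `deposition_layers - 1` voxels outward through the cortex (bone
#' attenuation at 1 MHz is of the order of 10 dB/cm, so a few-mm shell
#' absorbs through its whole depth, not in a surface sheet):
#' `q = alpha * efficiency * sum(I_v * dA) / (N_dep * voxel volume)`.
#'
#' @param I An `intensity_field` aligned with the facet's map.
#' @param facet Voxel set from [inner_cortical_facet()].
#' @param map A `tissue_map` (see [build_tissue_map()]).
#' @param params A [source_params].
#' @return `heat_source_map`; attributes `incident_power_W` and
#'   `deposited_power_W` expose the bookkeeping.
#' @export
oven_effect_source <- function(I, facet, map, params) {
  A <- if (inherits(I, "intensity_field")) I$I else I
  stopifnot(all(dim(A) == dim(map$labels)))
  out <- .empty_source(map)
  out$provenance <- "cortical"
  if (!length(facet)) {
    warning("empty cortical facet: zero oven source")
    attr(out$q, "incident_power_W") <- 0
    return(out)
  }
  dA <- attr(facet, "area_mm2") * 1e-6              # m^2 per facet voxel
  P_inc <- sum(A[facet]) * dA
  vol <- (map$spacing_mm * 1e-3)^3
  dep_set <- .grow_into_cortex(map, facet, params$deposition_layers)
  dep <- params$alpha * params$efficiency * P_inc
  out$q[dep_set] <- dep / (length(dep_set) * vol)
  attr(out, "incident_power_W") <- P_inc
  attr(out, "deposited_power_W") <- dep
  out
}

# dilate the facet voxel set outward through the cortical shell
# (6-neighbourhood, layers - 1 dilation passes restricted to cortex)
.grow_into_cortex <- function(map, facet, layers) {
  set <- as.integer(facet)
  if (layers <= 1L) return(set)
  d <- dim(map$labels)
  cort <- map$labels == TISSUE_CODES[["cortical"]]
  for (l in seq_len(layers - 1L)) {
    idx <- arrayInd(set, d)
    nb <- do.call(rbind, lapply(1:3, function(ax) {
      out <- rbind(idx, idx)
      out[seq_len(nrow(idx)), ax] <- idx[, ax] + 1L
      out[nrow(idx) + seq_len(nrow(idx)), ax] <- idx[, ax] - 1L
      out
    }))
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    set <- union(set, lin[cort[lin]])
  }
  sort(set)
}

#' Combine heat sources
#'
#' Voxel-wise sum with provenance union.
#'
#' @param a,b `heat_source_map` objects on the same grid.
#' @return `heat_source_map`.
#' @export
combine_sources <- function(a, b) {
  if (!all(dim(a$q) == dim(b$q)) ||
      !isTRUE(all.equal(a$map$spacing_mm, b$map$spacing_mm)))
    stop("heat-source grids do not match")
  structure(list(q = a$q + b$q, map = a$map,
                 provenance = union(a$provenance, b$provenance)),
            class = "heat_source_map")
}

#' Total source power
#' @param src A `heat_source_map`.
#' @return Watts.
#' @export
total_source_power <- function(src) {
  sum(src$q) * (src$map$spacing_mm * 1e-3)^3
}
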