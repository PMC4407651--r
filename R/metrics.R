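#' Isosurface area of a voxel mask
#'
#' Triangulated surface area by marching tetrahedra on a Gaussian-smoothed
#' copy of the mask (level 0.5). Voxel-face counting overestimates smooth
#' surfaces by up to ~50%; the smoothed triangulation is accurate to a few
#' percent for objects a few voxels across and larger. Structures thinner
#' than two voxels are below the method's (and the imaging rule's)
#' resolution and are not reliably measured.
#'
#' @param mask 3D logical array.
#' @param voxel_size_um Voxel edge length (micrometres); the default 1
#'   returns area in voxel units.
#' @param sigma Gaussian pre-smoothing width in voxels.
#' @return Surface area in um^2 (or voxel^2 for `voxel_size_um = 1`).
#' @export
#' @examples
#' # digitised sphere of radius 10 voxels vs 4*pi*r^2
#' d <- 26; ctr <- (d + 1) / 2
#' g <- expand.grid(1:d, 1:d, 1:d)
#' mask <- array(rowSums((g - ctr)^2) <= 100, c(d, d, d))
#' surface_area(mask) / (4 * pi * 100)
surface_area <- function(mask, voxel_size_um = 1, sigma = 0.8) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) return(0)
  sm <- smoothed_padded(mask, sigma)
  cpp_mtetra(sm, dim(sm), 0.5, FALSE)$area * voxel_size_um^2
}

#' Pore-population metrics of a three-phase volume
#'
#' Counts, volumes and surface areas of air-filled pores (AFPs) and
#' water-filled pores (WFPs), each defined as a single connected region
#' (26-connectivity) of air or water. Surface areas are triangulated
#' isosurface areas of the whole phase mask; solid-contact and
#' fluid-contact interface areas (voxel-face estimates) are logged
#' separately, with the air-water interface counted in both phases'
#' totals.
#'
#' @param volume A labelled, noise-filtered [phase_volume()].
#' @param check_filtered Warn if the volume still contains sub-resolution
#'   specks (the noise rule of [filter_noise()] should run first).
#' @return Object of class `pore_metrics` (a one-row data frame):
#'   potential, WFP/AFP totals and counts, mean AFP volume and area,
#'   water-filled porosity and the largest-WFP water fraction.
#' @export
compute_metrics <- function(volume, check_filtered = TRUE) {
  stopifnot(inherits(volume, "phase_volume"))
  d <- dim(volume$labels)
  vox_mm <- volume$voxel_size_um / 1e3
  vox_vol <- vox_mm^3
  out <- list(potential_kpa = volume$potential_kpa)
  for (ph in c("wfp", "afp")) {
    code <- if (ph == "wfp") PHASE_WATER else PHASE_AIR
    mask <- volume$labels == code
    if (any(mask)) {
      lab <- cpp_label_components(mask, d, 26L)
      ncomp <- attr(lab, "n_components")
      sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
      if (check_filtered && any(sizes < 8)) {
        warning("volume contains sub-resolution objects; run filter_noise() first")
        check_filtered <- FALSE
      }
      area <- surface_area(mask, volume$voxel_size_um) / 1e6  # mm^2
      out[[paste0(ph, "_count")]] <- ncomp
      out[[paste0(ph, "_total_volume_mm3")]] <- sum(mask) * vox_vol
      out[[paste0(ph, "_total_surface_area_mm2")]] <- area
      if (ph == "afp") {
        out$afp_mean_volume_mm3 <- sum(mask) * vox_vol / ncomp
        out$afp_mean_surface_area_mm2 <- area / ncomp
      } else {
        out$largest_wfp_fraction <- max(sizes) / sum(sizes)
      }
    } else {
      out[[paste0(ph, "_count")]] <- 0L
      out[[paste0(ph, "_total_volume_mm3")]] <- 0
      out[[paste0(ph, "_total_surface_area_mm2")]] <- 0
      if (ph == "afp") {
        out$afp_mean_volume_mm3 <- 0
        out$afp_mean_surface_area_mm2 <- 0
      } else out$largest_wfp_fraction <- NA_real_
    }
  }
  out$water_filled_porosity <- sum(volume$labels == PHASE_WATER) / prod(d)
  out$soil_volume_mm3 <- sum(volume$labels == PHASE_SOIL) * vox_vol
  out$sample_volume_mm3 <- prod(d) * vox_vol
  iface <- cpp_interface_faces(volume$labels, d) * vox_mm^2
  out$wfp_solid_contact_area_mm2 <- iface[PHASE_WATER + 1, PHASE_SOIL + 1]
  out$wfp_fluid_contact_area_mm2 <- iface[PHASE_WATER + 1, PHASE_AIR + 1]
  out$afp_solid_contact_area_mm2 <- iface[PHASE_AIR + 1, PHASE_SOIL + 1]
  res <- as.data.frame(out)
  class(res) <- c("pore_metrics", class(res))
  res
}

#' Metrics across a drainage series
#'
#' One [compute_metrics()] row per potential plus the total percent change
#' in WFP volume from the first to the last potential.
#'
#' @param volumes List of [phase_volume()]s sharing geometry, ordered by
#'   decreasing potential.
#' @param ... Passed to [compute_metrics()].
#' @return Data frame of class `pore_metrics_series` with attribute
#'   `wfp_volume_change_pct`.
#' @export
metrics_series <- function(volumes, ...) {
  dims <- vapply(volumes, function(v) dim(v$labels), integer(3))
  if (nrow(unique(t(dims))) != 1L)
    stop("volumes in a series must share the same grid")
  rows <- do.call(rbind, lapply(volumes, compute_metrics, ...))
  first <- rows$wfp_total_volume_mm3[1]
  last <- rows$wfp_total_volume_mm3[nrow(rows)]
  attr(rows, "wfp_volume_change_pct") <-
    if (first > 0) 100 * (first - last) / first else 0
  class(rows) <- c("pore_metrics_series", "data.frame")
  rows
}

#' Write a metrics series as CSV
#'
#' One row per (sample, potential); units are embedded in the headers.
#'
#' @param metrics A data frame from [metrics_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  write.csv(as.data.frame(metrics), path, row.names = FALSE)
  invisible(path)
}
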