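#' Write a volume as a multi-page TIFF stack with a JSON sidecar
#'
#' Phase labels are stored as 8-bit pages (0 = soil, 1 = water, 2 = air);
#' greyscale volumes as 16-bit pages with the original dynamic range
#' recorded in the sidecar. The sidecar (same path with extension
#' `.json`) carries the voxel size, potential and calibration metadata;
#' a volume cannot be read back without it.
#'
#' @param volume A [phase_volume()] or [greyscale_volume()].
#' @param path Output TIFF path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  d <- if (inherits(volume, "phase_volume")) dim(volume$labels)
       else dim(volume$intensities)
  if (inherits(volume, "phase_volume")) {
    pages <- lapply(seq_len(d[3]), function(k)
      volume$labels[, , k] / 255)
    meta <- list(kind = "labels", voxel_size_um = volume$voxel_size_um,
                 potential_kpa = volume$potential_kpa, dim = d)
    bits <- 8L
  } else if (inherits(volume, "greyscale_volume")) {
    rng <- range(volume$intensities)
    den <- if (diff(rng) > 0) diff(rng) else 1
    pages <- lapply(seq_len(d[3]), function(k)
      (volume$intensities[, , k] - rng[1]) / den)
    meta <- list(kind = "grey", voxel_size_um = volume$voxel_size_um,
                 grey_min = rng[1], grey_max = rng[2],
                 water_ref_grey = volume$water_ref_grey,
                 soil_ref_grey = volume$soil_ref_grey, dim = d)
    bits <- 16L
  } else stop("volume must be a phase_volume or greyscale_volume")
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path)

#' Read a volume written by [write_volume()]
#'
#' @param path TIFF path; the JSON sidecar must sit next to it.
#' @return A [phase_volume()] or [greyscale_volume()], losslessly matching
#'   what was written.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing sidecar metadata (", sp, "); voxel size is never defaulted")
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- simplify2array(pages)
  if (identical(meta$kind, "labels")) {
    labels <- array(as.integer(round(arr * 255)), dim = dim(arr))
    phase_volume(labels, meta$voxel_size_um,
                 ifelse(is.null(meta$potential_kpa) ||
                          is.na(meta$potential_kpa), NA_real_,
                        meta$potential_kpa))
  } else if (identical(meta$kind, "grey")) {
    grey <- arr * (meta$grey_max - meta$grey_min) + meta$grey_min
    greyscale_volume(grey, meta$voxel_size_um,
                     water_ref_grey = meta$water_ref_grey,
                     soil_ref_grey = meta$soil_ref_grey)
  } else stop("unknown volume kind in sidecar: ", meta$kind)
}

#' Three-phase threshold segmentation calibrated on reference greys
#'
#' Places the air/water cut halfway between the air reference grey (by
#' default the lowest mode of the intensity histogram) and the water
#' reference, and the water/soil cut halfway between the water and soil
#' references; every voxel is labelled.
#'
#' @param grey A [greyscale_volume()] with reference greys set.
#' @param air_ref_grey Air reference grey; default is the lowest mode of
#'   the histogram below the water reference.
#' @return A [phase_volume()].
#' @export
segment_threshold <- function(grey, air_ref_grey = NULL) {
  stopifnot(inherits(grey, "greyscale_volume"))
  if (is.na(grey$water_ref_grey) || is.na(grey$soil_ref_grey))
    stop("reference greys must be set before segmentation")
  if (grey$water_ref_grey >= grey$soil_ref_grey)
    stop("reference greys equal or inverted: water must attenuate less than soil")
  if (is.null(air_ref_grey)) {
    lows <- grey$intensities[grey$intensities < grey$water_ref_grey]
    if (length(lows) < 2) {
      air_ref_grey <- min(grey$intensities)
    } else {
      dens <- density(lows)
      air_ref_grey <- dens$x[which.max(dens$y)]
    }
  }
  if (air_ref_grey >= grey$water_ref_grey)
    stop("air reference grey must lie below the water reference")
  cut_aw <- (air_ref_grey + grey$water_ref_grey) / 2
  cut_ws <- (grey$water_ref_grey + grey$soil_ref_grey) / 2
  labels <- array(PHASE_SOIL, dim(grey$intensities))
  labels[grey$intensities < cut_ws] <- PHASE_WATER
  labels[grey$intensities < cut_aw] <- PHASE_AIR
  phase_volume(labels, grey$voxel_size_um)
}

#' Noise-object exclusion for segmented volumes
#'
#' Applies the resolution-based exclusion rule: in 3D mode any connected
#' non-soil object (26-connectivity) whose bounding box is under 2 voxels
#' in any axis or whose volume is under `8e-6` mm^3 is relabelled to the
#' majority phase of its face neighbours (ties resolved toward water); in
#' 2D mode the per-slice analogue removes objects under 0.02 mm
#' equivalent-circle diameter.
#'
#' @param volume A [phase_volume()].
#' @param mode `"3D"` (default) or `"2D"`.
#' @param min_volume_mm3 3D volume threshold.
#' @param min_diameter_mm 2D diameter threshold.
#' @return A [phase_volume()] with attribute `n_removed` (objects removed
#'   per phase).
#' @export
filter_noise <- function(volume, mode = c("3D", "2D"),
                         min_volume_mm3 = 8e-6, min_diameter_mm = 0.02) {
  stopifnot(inherits(volume, "phase_volume"))
  mode <- match.arg(mode)
  labels <- volume$labels
  d <- dim(labels)
  vox_mm <- volume$voxel_size_um / 1e3
  removed <- c(water = 0L, air = 0L)
  if (mode == "3D") {
    for (ph in c(PHASE_WATER, PHASE_AIR)) {
      mask <- labels == ph
      if (!any(mask)) next
      lab <- cpp_label_components(mask, d, 26L)
      ncomp <- attr(lab, "n_components")
      if (ncomp == 0) next
      dim(lab) <- d
      for (ci in seq_len(ncomp)) {
        sel <- which(lab == ci)
        nvox <- length(sel)
        coord <- arrayInd(sel, d)
        bbox <- apply(coord, 2, function(x) diff(range(x)) + 1L)
        vol_mm3 <- nvox * vox_mm^3
        if (any(bbox < 2) || vol_mm3 < min_volume_mm3) {
          labels[sel] <- majority_neighbour_phase(labels, sel, d)
          removed[ifelse(ph == PHASE_WATER, "water", "air")] <-
            removed[ifelse(ph == PHASE_WATER, "water", "air")] + 1L
        }
      }
    }
  } else {
    for (k in seq_len(d[3])) {
      slice <- labels[, , k, drop = FALSE]
      for (ph in c(PHASE_WATER, PHASE_AIR)) {
        mask <- slice == ph
        if (!any(mask)) next
        lab <- cpp_label_components(mask, dim(mask), 26L)
        ncomp <- attr(lab, "n_components")
        dim(lab) <- dim(mask)
        for (ci in seq_len(ncomp)) {
          sel <- which(lab == ci)
          diam_mm <- 2 * sqrt(length(sel) / pi) * vox_mm
          if (diam_mm < min_diameter_mm) {
            sel3 <- sel + (k - 1L) * prod(d[1:2])
            labels[sel3] <- majority_neighbour_phase(labels, sel3, d)
            removed[ifelse(ph == PHASE_WATER, "water", "air")] <-
              removed[ifelse(ph == PHASE_WATER, "water", "air")] + 1L
          }
        }
      }
    }
  }
  out <- phase_volume(labels, volume$voxel_size_um, volume$potential_kpa)
  attr(out, "n_removed") <- removed
  out
}

# majority phase among face neighbours of a voxel set, excluding the set
# itself; ties broken toward water (never invent solid from a tie)
majority_neighbour_phase <- function(labels, sel, d) {
  coord <- arrayInd(sel, d)
  counts <- c(0, 0, 0)  # soil, water, air
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  inset <- array(FALSE, d)
  inset[sel] <- TRUE
  for (t in 1:6) {
    nb <- sweep(coord, 2, offs[t, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    idx <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
    idx <- idx[!inset[idx]]
    if (length(idx))
      counts <- counts + tabulate(labels[idx] + 1L, nbins = 3L)
  }
  best <- max(counts)
  if (counts[PHASE_WATER + 1L] == best) return(PHASE_WATER)
  which.max(counts) - 1L
}

#' Export a phase isosurface as an ASCII STL mesh
#'
#' Triangulates the (smoothed) boundary of one phase with marching
#' tetrahedra and writes an ASCII STL file, in voxel-size physical units
#' (micrometres).
#'
#' @param volume A [phase_volume()].
#' @param phase `"water"`, `"air"` or `"soil"`.
#' @param path Output `.stl` path.
#' @param sigma Gaussian pre-smoothing width in voxels.
#' @return `path`, invisibly.
#' @export
write_phase_stl <- function(volume, phase = c("water", "air", "soil"), path,
                            sigma = 0.8) {
  phase <- match.arg(phase)
  code <- c(soil = PHASE_SOIL, water = PHASE_WATER, air = PHASE_AIR)[phase]
  mask <- volume$labels == code
  sm <- smoothed_padded(mask, sigma)
  res <- cpp_mtetra(sm, dim(sm), 0.5, TRUE)
  v <- res$vertices * volume$voxel_size_um
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", phase), con)
  ntri <- ncol(v) / 3
  for (t in seq_len(ntri)) {
    a <- v[, 3 * t - 2]; b <- v[, 3 * t - 1]; cc <- v[, 3 * t]
    nrm <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
             (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
             (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    nn <- sqrt(sum(nrm^2))
    if (nn > 0) nrm <- nrm / nn
    writeLines(c(sprintf("facet normal %g %g %g", nrm[1], nrm[2], nrm[3]),
                 "  outer loop",
                 sprintf("    vertex %g %g %g", a[1], a[2], a[3]),
                 sprintf("    vertex %g %g %g", b[1], b[2], b[3]),
                 sprintf("    vertex %g %g %g", cc[1], cc[2], cc[3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", phase), con)
  invisible(path)
}

# pad a mask by one voxel of background and Gaussian-smooth it
smoothed_padded <- function(mask, sigma) {
  d <- dim(mask)
  pad <- array(0, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.numeric(mask)
  sm <- cpp_gauss3(pad, dim(pad), sigma)
  dim(sm) <- dim(pad)
  sm
}
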