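#' Three-phase labelled voxel volume
#'
#' The central geometric container: a 3D integer array of phase labels
#' (0 = soil, 1 = water, 2 = air) together with the voxel edge length and,
#' optionally, the matric potential at which the configuration holds.
#'
#' @param labels 3D integer array with values in \{0, 1, 2\}.
#' @param voxel_size_um Voxel edge length in micrometres (> 0).
#' @param potential_kpa Matric potential in kPa (non-positive) or `NA`.
#' @return An object of class `phase_volume`.
#' @export
#' @examples
#' v <- phase_volume(array(1L, c(4, 4, 4)), voxel_size_um = 10.17)
#' porosity(v)
phase_volume <- function(labels, voxel_size_um, potential_kpa = NA_real_) {
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  if (!all(labels %in% c(PHASE_SOIL, PHASE_WATER, PHASE_AIR)))
    stop("labels must be drawn from {0 = soil, 1 = water, 2 = air}")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      is.na(voxel_size_um) || voxel_size_um <= 0)
    stop("voxel_size_um must be a single positive number")
  if (!is.na(potential_kpa) && potential_kpa > 0)
    stop("potential_kpa must be non-positive (matric potential)")
  structure(list(labels = labels,
                 voxel_size_um = as.numeric(voxel_size_um),
                 potential_kpa = as.numeric(potential_kpa)),
            class = "phase_volume")
}

#' Greyscale voxel volume with phase-calibration references
#'
#' Holds a reconstructed greyscale volume and the grey values of the two
#' reference objects (pore water and finely sieved soil) used to calibrate
#' three-phase threshold segmentation. Water attenuates less than mineral
#' soil, so `water_ref_grey < soil_ref_grey` is enforced.
#'
#' @param intensities 3D numeric array of grey values.
#' @param voxel_size_um Voxel edge length in micrometres.
#' @param water_ref_grey,soil_ref_grey Reference grey values.
#' @return An object of class `greyscale_volume`.
#' @export
greyscale_volume <- function(intensities, voxel_size_um,
                             water_ref_grey = NA_real_,
                             soil_ref_grey = NA_real_) {
  if (length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array")
  if (!is.numeric(voxel_size_um) || voxel_size_um <= 0)
    stop("voxel_size_um must be positive")
  if (!is.na(water_ref_grey) && !is.na(soil_ref_grey) &&
      water_ref_grey >= soil_ref_grey)
    stop("water_ref_grey must be below soil_ref_grey")
  structure(list(intensities = intensities,
                 voxel_size_um = as.numeric(voxel_size_um),
                 water_ref_grey = as.numeric(water_ref_grey),
                 soil_ref_grey = as.numeric(soil_ref_grey)),
            class = "greyscale_volume")
}

#' @export
print.phase_volume <- function(x, ...) {
  d <- dim(x$labels)
  fr <- phase_fractions(x)
  cat(sprintf("phase_volume %d x %d x %d, voxel %.3g um\n", d[1], d[2], d[3],
              x$voxel_size_um))
  cat(sprintf("  potential: %s kPa\n",
              ifelse(is.na(x$potential_kpa), "unset", x$potential_kpa)))
  cat(sprintf("  soil %.3f | water %.3f | air %.3f\n",
              fr["soil"], fr["water"], fr["air"]))
  invisible(x)
}

#' @export
print.greyscale_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("greyscale_volume %d x %d x %d, voxel %.3g um, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$voxel_size_um,
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Phase volume fractions
#'
#' @param volume A [phase_volume()].
#' @return Named numeric vector with fractions of soil, water and air voxels
#'   (summing to 1).
#' @export
phase_fractions <- function(volume) {
  stopifnot(inherits(volume, "phase_volume"))
  n <- length(volume$labels)
  c(soil = sum(volume$labels == PHASE_SOIL) / n,
    water = sum(volume$labels == PHASE_WATER) / n,
    air = sum(volume$labels == PHASE_AIR) / n)
}

#' Porosity (pore fraction: water + air)
#'
#' @param volume A [phase_volume()].
#' @return Pore voxel fraction in \[0, 1\].
#' @export
porosity <- function(volume) {
  fr <- phase_fractions(volume)
  unname(fr["water"] + fr["air"])
}

#' Water fraction of the pore space
#'
#' @param volume A [phase_volume()].
#' @return Water voxels / pore voxels (1 for a saturated volume; NaN if the
#'   volume has no pore space).
#' @export
water_saturation <- function(volume) {
  fr <- phase_fractions(volume)
  unname(fr["water"] / (fr["water"] + fr["air"]))
}

#' Volumetric water content
#'
#' @param volume A [phase_volume()].
#' @return Water voxels / total voxels.
#' @export
water_content <- function(volume) {
  unname(phase_fractions(volume)["water"])
}

#' Label connected components of a voxel mask
#'
#' @param mask 3D logical array.
#' @param connectivity 6 (face) or 26 (face/edge/corner).
#' @param wrap If TRUE, opposite domain faces are identified (periodic
#'   topology), as needed for components of a periodic unit cell.
#' @return Integer array of component labels (0 = background) with attribute
#'   `n_components`.
#' @export
label_components <- function(mask, connectivity = 26, wrap = FALSE) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L,
            connectivity %in% c(6, 26))
  lab <- cpp_label_components(mask, dim(mask), as.integer(connectivity), wrap)
  dim(lab) <- dim(mask)
  lab
}

#' Local thickness (maximal inscribed sphere radius) of a pore mask
#'
#' Computes the Euclidean distance transform of the mask and propagates
#' each maximal inscribed sphere over the voxels it covers, the standard
#' local-thickness construction that underlies the capillary-bundle
#' reading of the Young-Laplace law.
#'
#' @param mask 3D logical array (`TRUE` = pore).
#' @return Numeric array of sphere radii in voxels (0 outside the mask).
#'   Clearances are measured against solid inside the image only (the
#'   domain boundary is open).
#' @export
local_thickness <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  lt <- cpp_local_thickness(mask, dim(mask))
  dim(lt) <- dim(mask)
  lt
}
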