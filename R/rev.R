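#' Extract cubic REV subsamples at seeded-random origins
#'
#' Draws `n` cubic subsamples of the given physical side length from random
#' origins, fully inside the volume. Origins are persisted in the result so
#' the same coordinates can be reused across the matric potentials of one
#' sample; overlap between cubes is permitted.
#'
#' @param volume A [phase_volume()].
#' @param n Number of cubes.
#' @param side_mm Cube side length in millimetres.
#' @param seed Integer seed for the origins.
#' @param origins Optional integer matrix (n x 3) of voxel origins to reuse
#'   (from a previous call at another potential); overrides `seed`.
#' @return List of `rev_sample` objects (a [phase_volume()] restricted to a
#'   cube, with `origin`, `side_mm`, `level` and `sample_id` fields).
#' @export
#' @examples
#' v <- phase_volume(array(1L, c(40, 40, 40)), voxel_size_um = 100)
#' cubes <- extract_subsamples(v, n = 2, side_mm = 2, seed = 1)
#' subsample_manifest(cubes)
extract_subsamples <- function(volume, n, side_mm, seed = 1L,
                               origins = NULL) {
  stopifnot(inherits(volume, "phase_volume"))
  d <- dim(volume$labels)
  side_vox <- round(side_mm * 1e3 / volume$voxel_size_um)
  if (any(side_vox > d))
    stop(sprintf("a %.3g mm cube (%d voxels) does not fit in the volume",
                 side_mm, side_vox))
  if (is.null(origins)) {
    set.seed(seed)
    origins <- cbind(sample.int(d[1] - side_vox + 1L, n, replace = TRUE),
                     sample.int(d[2] - side_vox + 1L, n, replace = TRUE),
                     sample.int(d[3] - side_vox + 1L, n, replace = TRUE))
  }
  lapply(seq_len(nrow(origins)), function(i) {
    o <- origins[i, ]
    rev_sample(volume, origin = o, side_vox = side_vox, level = 0L,
               sample_id = i)
  })
}

rev_sample <- function(volume, origin, side_vox, level, sample_id,
                       labels = NULL) {
  if (is.null(labels))
    labels <- volume$labels[origin[1]:(origin[1] + side_vox - 1L),
                            origin[2]:(origin[2] + side_vox - 1L),
                            origin[3]:(origin[3] + side_vox - 1L)]
  out <- phase_volume(labels, volume$voxel_size_um, volume$potential_kpa)
  out$origin <- as.integer(origin)
  out$side_mm <- side_vox * volume$voxel_size_um / 1e3
  out$level <- as.integer(level)
  out$sample_id <- sample_id
  class(out) <- c("rev_sample", class(out))
  out
}

#' Side length and volume of a REV sample
#'
#' @param s A `rev_sample`.
#' @return Named vector: `side_mm`, `volume_mm3`.
#' @export
rev_geometry <- function(s) {
  stopifnot(inherits(s, "rev_sample"))
  c(side_mm = s$side_mm, volume_mm3 = s$side_mm^3)
}

#' Dyadic REV volume series
#'
#' Builds the nested series of concentric cubes with nominal volumes
#' `V_j = V_0 / 2^j` for `j = 0 .. j_max`, each level centred on its
#' parent. Side lengths are rounded to whole voxels and the achieved side
#' is recorded; the series is truncated with a warning if a level would
#' fall below 4 voxels per side.
#'
#' @param s A `rev_sample` (level 0).
#' @param j_max Deepest level (default 8, giving a 256-fold volume range).
#' @return List of `rev_sample` objects, levels `0..j_max`, each carrying
#'   `nominal_volume_mm3`.
#' @export
dyadic_series <- function(s, j_max = 8L) {
  stopifnot(inherits(s, "rev_sample"))
  d0 <- dim(s$labels)[1]
  v0 <- s$side_mm^3
  out <- list()
  for (j in 0:j_max) {
    side <- max(1L, round(d0 * 2^(-j / 3)))
    if (side < 4L) {
      warning(sprintf("dyadic series truncated at j = %d (sub-cube below 4 voxels)",
                      j - 1L))
      break
    }
    lo <- floor((d0 - side) / 2) + 1L
    sub <- s$labels[lo:(lo + side - 1L), lo:(lo + side - 1L),
                    lo:(lo + side - 1L)]
    sj <- rev_sample(s, origin = s$origin + lo - 1L, side_vox = side,
                     level = j, sample_id = s$sample_id, labels = sub)
    sj$voxel_size_um <- s$voxel_size_um
    sj$nominal_volume_mm3 <- v0 / 2^j
    out[[j + 1L]] <- sj
  }
  out
}

#' Mirror-reflect a sample into a truly periodic volume
#'
#' Reflects the cube in the x-, y- and z-axes, producing a 2x2x2 mirrored
#' volume that is periodic by construction (opposite faces identical) and
#' exactly preserves phase fractions.
#'
#' @param s A `rev_sample` or [phase_volume()].
#' @return A [phase_volume()] with doubled sides.
#' @export
reflect_volume <- function(s) {
  lab <- if (inherits(s, "phase_volume")) s$labels else s
  d <- dim(lab)
  lab2 <- lab[c(1:d[1], d[1]:1), c(1:d[2], d[2]:1), c(1:d[3], d[3]:1)]
  if (inherits(s, "phase_volume"))
    phase_volume(lab2, s$voxel_size_um, s$potential_kpa)
  else lab2
}

#' Manifest of a list of REV samples
#'
#' @param samples List of `rev_sample` objects.
#' @return Data frame: sample_id, origin, level j, side (mm), achieved
#'   voxels per side — the per-parent manifest written by the pipeline.
#' @export
subsample_manifest <- function(samples) {
  do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s$sample_id, origin_x = s$origin[1],
               origin_y = s$origin[2], origin_z = s$origin[3],
               j = s$level, side_mm = s$side_mm,
               side_voxels = dim(s$labels)[1])
  }))
}
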