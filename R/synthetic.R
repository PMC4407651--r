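#' Specification for a synthetic three-phase soil volume
#'
#' Describes a sand-like (grain packing) or clay-like (aggregate packing
#' plus planar cracks) synthetic medium. Defaults are chosen so that, with
#' the default drainage schedule, sand-like media drain progressively over
#' the -5 to -40 kPa range while clay-like media keep a population of
#' micropores below the -75 kPa Young-Laplace radius (the bimodal
#' micropore/macropore contrast of a structured clay).
#'
#' @param texture `"sand_like"` or `"clay_like"`.
#' @param grid_shape Integer vector of 3 grid dimensions (each >= 16).
#' @param voxel_size_um Voxel edge length in micrometres. Defaults place
#'   the sand pore population (6 um voxels) across the drainage window of
#'   the default schedule, and the clay micropores (0.5 um voxels) below
#'   the -75 kPa critical radius so they stay water filled.
#' @param target_porosity Target pore fraction, strictly in (0, 1).
#' @param grain_radius_range Grain radius range in voxels (sand).
#' @param aggregate_radius_range Aggregate radius range in voxels (clay).
#' @param crack_count Number of planar cracks (clay). Cracks are vertical
#'   full-extent slabs (desiccation-crack style), so they connect to the
#'   air-entry face.
#' @param crack_aperture_range Crack aperture range in voxels (clay),
#'   minimum 2 so every crack is resolvable.
#' @param min_separation_factor Minimum centre separation as a fraction of
#'   the radius sum during sequential packing. 1 is a hard-sphere packing
#'   (which jams near 38% solid); values below 1 permit the partial
#'   interpenetration needed to reach realistic solid fractions.
#' @param rng_seed Integer seed; fixed seed gives bit-identical volumes.
#' @return An object of class `synthetic_spec`.
#' @export
#' @examples
#' spec <- synthetic_spec("sand_like", c(32, 32, 32), target_porosity = 0.45)
synthetic_spec <- function(texture = c("sand_like", "clay_like"),
                           grid_shape = c(64, 64, 64),
                           voxel_size_um = if (match.arg(texture) == "sand_like") 6 else 0.5,
                           target_porosity = if (match.arg(texture) == "sand_like") 0.45 else 0.5,
                           grain_radius_range = c(4, 7),
                           aggregate_radius_range = c(3.5, 5.5),
                           crack_count = 2,
                           crack_aperture_range = c(9, 13),
                           min_separation_factor = if (match.arg(texture) == "sand_like") 0.75 else 0.7,
                           rng_seed = 1L) {
  texture <- match.arg(texture)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("grid_shape must be 3 integers, each >= 16")
  if (!(target_porosity > 0 && target_porosity < 1))
    stop("target_porosity must lie strictly in (0, 1)")
  if (crack_aperture_range[1] < 2)
    stop("crack apertures below 2 voxels are not resolvable")
  if (crack_count < 0) stop("crack_count must be >= 0")
  structure(list(texture = texture, grid_shape = grid_shape,
                 voxel_size_um = voxel_size_um,
                 target_porosity = target_porosity,
                 grain_radius_range = grain_radius_range,
                 aggregate_radius_range = aggregate_radius_range,
                 crack_count = as.integer(crack_count),
                 crack_aperture_range = crack_aperture_range,
                 min_separation_factor = min_separation_factor,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

#' Matric-potential schedule for quasi-static drainage
#'
#' @param potentials_kpa Strictly decreasing non-positive potentials; the
#'   first entry must be 0 (saturation). Default is the seven-step vacuum
#'   series 0, -5, -10, -20, -40, -60, -75 kPa.
#' @param surface_tension Air-water surface tension (N m^-1).
#' @param contact_angle_deg Contact angle in degrees (0 = perfectly wetting).
#' @return An object of class `drainage_schedule`.
#' @export
drainage_schedule <- function(potentials_kpa = c(0, -5, -10, -20, -40, -60, -75),
                              surface_tension = water_constants()$sigma,
                              contact_angle_deg = 0) {
  if (potentials_kpa[1] != 0)
    stop("the first potential must be 0 (saturation)")
  if (any(potentials_kpa > 0))
    stop("matric potentials must be non-positive")
  if (any(diff(potentials_kpa) >= 0))
    stop("potentials must be strictly decreasing")
  structure(list(potentials_kpa = as.numeric(potentials_kpa),
                 surface_tension = surface_tension,
                 contact_angle_deg = contact_angle_deg),
            class = "drainage_schedule")
}

# paint a sphere into a logical array; returns modified array
paint_sphere <- function(solid, centre, radius) {
  d <- dim(solid)
  lo <- pmax(1L, floor(centre - radius))
  hi <- pmin(d, ceiling(centre + radius))
  if (any(lo > hi)) return(solid)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  dx2 <- (ix - centre[1])^2
  dy2 <- (iy - centre[2])^2
  dz2 <- (iz - centre[3])^2
  sub <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
  solid[ix, iy, iz] <- solid[ix, iy, iz] | sub
  solid
}

# Random sequential addition of spheres until the non-crack solid fraction
# reaches `target_solid`. When placements keep getting rejected the sampled
# radius range shrinks (down to 1.5 voxels), mimicking a polydisperse grain
# population filling the remaining voids. Signals an error naming the
# achieved porosity if the target stays unreachable.
rsa_pack <- function(d, radius_range, target_solid, sep_factor,
                     exclude = NULL, max_attempts = 200000L) {
  solid <- array(FALSE, d)
  centres <- matrix(numeric(0), ncol = 3)
  radii <- numeric(0)
  n_out <- if (is.null(exclude)) prod(d) else sum(!exclude)
  frac <- 0
  recount <- function() {
    if (is.null(exclude)) sum(solid) / n_out else sum(solid & !exclude) / n_out
  }
  attempts <- 0L
  rejected <- 0L
  rr <- radius_range
  while (frac < target_solid && attempts < max_attempts) {
    attempts <- attempts + 1L
    r <- runif(1, rr[1], rr[2])
    ctr <- runif(3, 1, d)
    if (nrow(centres) > 0) {
      dd <- sqrt(colSums((t(centres) - ctr)^2))
      if (any(dd < sep_factor * (radii + r))) {
        rejected <- rejected + 1L
        if (rejected %% 400L == 0L && rr[1] > 1.5)
          rr <- pmax(rr * 0.85, 1.5)
        next
      }
    }
    cand <- paint_sphere(solid, ctr, r)
    newfrac <- if (is.null(exclude)) sum(cand) / n_out
               else sum(cand & !exclude) / n_out
    if (newfrac > target_solid + 0.02) {
      # placing this grain would overshoot the porosity tolerance;
      # try smaller grains instead
      rejected <- rejected + 1L
      rr <- pmax(rr * 0.7, 1.5)
      next
    }
    centres <- rbind(centres, ctr)
    radii <- c(radii, r)
    solid <- cand
    frac <- newfrac
  }
  if (frac < target_solid)
    stop(sprintf(paste0("target porosity unreachable: achieved porosity %.3f ",
                        "after %d placement attempts"),
                 1 - frac, attempts))
  solid
}

#' Generate a sand-like three-phase volume
#'
#' Random sequential addition of spherical grains (with a minimum
#' centre-separation constraint) until the target porosity is reached; the
#' pore space starts fully water filled.
#'
#' @param spec A [synthetic_spec()] with `texture = "sand_like"`.
#' @return A [phase_volume()] at saturation (potential 0 kPa).
#' @export
#' @examples
#' v <- generate_sand_like(synthetic_spec("sand_like", c(32, 32, 32),
#'                                        rng_seed = 1))
#' abs(porosity(v) - 0.45) < 0.03
generate_sand_like <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$texture != "sand_like")
    stop("spec$texture must be 'sand_like'")
  d <- spec$grid_shape
  if (2 * spec$grain_radius_range[1] > min(d))
    stop("grain_radius_range too large for the grid")
  set.seed(spec$rng_seed)
  solid <- rsa_pack(d, spec$grain_radius_range,
                    target_solid = 1 - spec$target_porosity,
                    sep_factor = spec$min_separation_factor)
  check_achieved_porosity(1 - sum(solid) / prod(d), spec$target_porosity)
  labels <- array(PHASE_WATER, d)
  labels[solid] <- PHASE_SOIL
  phase_volume(labels, spec$voxel_size_um, potential_kpa = 0)
}

check_achieved_porosity <- function(achieved, target, tol = 0.03) {
  if (abs(achieved - target) > tol)
    stop(sprintf("achieved porosity %.3f outside +/- %.2f of target %.3f",
                 achieved, tol, target))
  invisible(achieved)
}

#' Generate a clay-like three-phase volume
#'
#' A dense packing of small spherical aggregates leaves a network of thin
#' inter-aggregate micropores; `crack_count` full-extent planar slab voids
#' of sampled aperture are then carved as macropores/cracks. The pore-radius
#' histogram of the result is bimodal: a micropore mode from the packing
#' and a macropore mode from the cracks.
#'
#' @param spec A [synthetic_spec()] with `texture = "clay_like"`.
#' @return A [phase_volume()] at saturation (potential 0 kPa).
#' @export
generate_clay_like <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$texture != "clay_like")
    stop("spec$texture must be 'clay_like'")
  d <- spec$grid_shape
  if (2 * spec$aggregate_radius_range[1] > min(d))
    stop("aggregate_radius_range too large for the grid")
  set.seed(spec$rng_seed)
  # carve cracks first so the packing target can account for their volume
  crack <- array(FALSE, d)
  if (spec$crack_count > 0) {
    axes <- sample(1:2, spec$crack_count, replace = TRUE)
    taken <- vector("list", 3)
    for (ci in seq_len(spec$crack_count)) {
      ax <- axes[ci]
      w <- round(runif(1, spec$crack_aperture_range[1],
                       spec$crack_aperture_range[2]))
      w <- max(2L, as.integer(w))
      for (try in 1:200) {
        pos <- sample(2:(d[ax] - w - 1), 1)
        span <- pos:(pos + w - 1)
        # keep slabs on the same axis separated so they stay distinct
        if (!any(unlist(taken[[ax]]) %in% (pos - 2):(pos + w + 1))) break
      }
      taken[[ax]] <- c(taken[[ax]], list(span))
      idx <- list(1:d[1], 1:d[2], 1:d[3])
      idx[[ax]] <- span
      crack[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
    }
  }
  crack_frac <- sum(crack) / prod(d)
  # one-voxel compacted skin on the crack walls (the cutan analogue):
  # micropores never open directly into a crack, keeping the micropore
  # and macropore radius populations distinct
  near_crack <- array(FALSE, d)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    src <- lapply(d, seq_len); dst <- src
    if (s > 0) { src[[ax]] <- 1:(d[ax] - 1); dst[[ax]] <- 2:d[ax] }
    else       { src[[ax]] <- 2:d[ax];       dst[[ax]] <- 1:(d[ax] - 1) }
    near_crack[dst[[1]], dst[[2]], dst[[3]]] <-
      near_crack[dst[[1]], dst[[2]], dst[[3]]] |
      crack[src[[1]], src[[2]], src[[3]]]
  }
  # pack so that pores outside the cracks hit the residual porosity
  # budget; void plugging (below) removes some pore volume, so the
  # packing target is corrected over a few attempts
  target_solid <- (1 - spec$target_porosity) / (1 - crack_frac)
  correction <- 0
  for (attempt in 1:4) {
    solid <- rsa_pack(d, spec$aggregate_radius_range,
                      target_solid = min(max(target_solid - correction, 0.05),
                                         0.95),
                      sep_factor = spec$min_separation_factor,
                      exclude = crack)
    solid[crack] <- FALSE
    solid[near_crack & !solid & !crack] <- TRUE
    # plug inter-aggregate voids wider than the micropore band so the
    # pore-radius distribution stays bimodal (micropores vs cracks); the
    # clearance is measured with cracks closed so plugs never bulge into
    # a crack and narrow it locally
    dt <- sqrt(cpp_edt_sq(!solid & !crack, d))
    dim(dt) <- d
    solid[!solid & !crack & dt > 2.5] <- TRUE
    achieved <- 1 - sum(solid) / prod(d)
    if (abs(achieved - spec$target_porosity) <= 0.015) break
    correction <- correction + (spec$target_porosity - achieved)
  }
  check_achieved_porosity(1 - sum(solid) / prod(d), spec$target_porosity)
  labels <- array(PHASE_WATER, d)
  labels[solid] <- PHASE_SOIL
  phase_volume(labels, spec$voxel_size_um, potential_kpa = 0)
}

#' Generate a synthetic volume (dispatch on texture)
#'
#' @param spec A [synthetic_spec()].
#' @return A [phase_volume()] at saturation.
#' @export
generate_volume <- function(spec) {
  switch(spec$texture,
         sand_like = generate_sand_like(spec),
         clay_like = generate_clay_like(spec))
}

#' Young-Laplace critical pore radius for a matric potential
#'
#' `r_c = 2 * sigma * cos(theta) / |P|`: pores with inscribed radius at or
#' above `r_c` drain at capillary pressure `|P|`.
#'
#' @param potential_kpa Matric potential (kPa, <= 0; 0 gives `Inf`).
#' @param schedule A [drainage_schedule()] supplying surface tension and
#'   contact angle.
#' @return Critical radius in micrometres.
#' @export
critical_radius_um <- function(potential_kpa, schedule = drainage_schedule()) {
  if (potential_kpa > 0) stop("potential must be non-positive")
  if (potential_kpa == 0) return(Inf)
  p_pa <- abs(potential_kpa) * 1e3
  2 * schedule$surface_tension *
    cos(schedule$contact_angle_deg * pi / 180) / p_pa * 1e6
}

#' Quasi-static drainage to a matric potential
#'
#' Morphological invasion-percolation drainage on the drying branch: air
#' occupies every pore voxel whose local pore radius (maximal inscribed
#' sphere) is at least the Young-Laplace critical radius and that is
#' face-connected to the entry face through voxels meeting the same
#' criterion. Air assigned at a less negative potential never reverts.
#'
#' @param volume A [phase_volume()]; air only from a previous (less
#'   negative) drainage step.
#' @param potential_kpa Target matric potential (kPa, <= 0).
#' @param schedule A [drainage_schedule()].
#' @param entry_axis Axis (1-3) of the face air enters from.
#' @param entry_side `"high"` (default: the top face) or `"low"`.
#' @return A [phase_volume()] at `potential_kpa`.
#' @export
apply_drainage <- function(volume, potential_kpa,
                           schedule = drainage_schedule(),
                           entry_axis = 3, entry_side = c("high", "low")) {
  stopifnot(inherits(volume, "phase_volume"))
  entry_side <- match.arg(entry_side)
  if (potential_kpa > 0) stop("potential must be non-positive")
  if (potential_kpa == 0) {
    out <- volume
    out$potential_kpa <- 0
    return(out)
  }
  rc_um <- critical_radius_um(potential_kpa, schedule)
  rc_vox <- rc_um / volume$voxel_size_um
  if (rc_vox < 1)
    warning(sprintf(paste0("critical radius %.2f um is below one voxel; ",
                           "step acts as full drainage of connected pores"),
                    rc_um))
  pore <- volume$labels != PHASE_SOIL
  prev_air <- volume$labels == PHASE_AIR
  lt <- local_thickness(pore)
  air <- cpp_invade(lt, pore, prev_air, rc_vox,
                    as.integer(entry_axis) - 1L,
                    ifelse(entry_side == "low", 0L, 1L), dim(pore))
  labels <- volume$labels
  labels[pore] <- PHASE_WATER
  dim(air) <- dim(pore)
  labels[air] <- PHASE_AIR
  phase_volume(labels, volume$voxel_size_um, potential_kpa)
}

#' Drain a saturated volume over a full matric-potential schedule
#'
#' @param volume A saturated [phase_volume()].
#' @param schedule A [drainage_schedule()].
#' @param ... Passed to [apply_drainage()].
#' @return List of [phase_volume()]s, one per potential, in schedule order.
#' @export
drainage_series <- function(volume, schedule = drainage_schedule(), ...) {
  out <- vector("list", length(schedule$potentials_kpa))
  cur <- volume
  for (i in seq_along(schedule$potentials_kpa)) {
    cur <- suppressWarnings(
      apply_drainage(cur, schedule$potentials_kpa[i], schedule, ...))
    out[[i]] <- cur
  }
  names(out) <- as.character(schedule$potentials_kpa)
  out
}

#' Pore-radius histogram of a phase volume
#'
#' Histogram of local-thickness radii over pore voxels, used to verify the
#' bimodal (micropore plus crack) structure of clay-like media.
#'
#' @param volume A [phase_volume()].
#' @param bin_width Bin width in voxels.
#' @return Data frame with bin mid-points (voxels) and voxel counts.
#' @export
pore_radius_histogram <- function(volume, bin_width = 1) {
  pore <- volume$labels != PHASE_SOIL
  lt <- local_thickness(pore)
  r <- lt[pore]
  breaks <- seq(0, ceiling(max(r) / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- hist(r, breaks = breaks, plot = FALSE)
  data.frame(radius_voxels = h$mids, count = h$counts)
}

#' Count full-extent planar void slabs in a volume
#'
#' Detects maximal runs of grid planes that are entirely pore, scanning all
#' three axes; each run is one planar crack.
#'
#' @param volume A [phase_volume()].
#' @return Integer count of planar slab voids.
#' @export
count_planar_voids <- function(volume) {
  pore <- volume$labels != PHASE_SOIL
  d <- dim(pore)
  total <- 0L
  for (ax in 1:3) {
    full <- vapply(seq_len(d[ax]), function(i) {
      idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
      all(switch(ax, pore[i, , ], pore[, i, ], pore[, , i]))
    }, logical(1))
    runs <- rle(full)
    total <- total + sum(runs$values)
  }
  total
}
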