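#' Flow domain of a REV sample
#'
#' Prepares the water domain for the cell problem: water voxels are fluid;
#' soil and air are rigid no-slip obstacles (the non-wetting phase is taken
#' as stationary). Water components not face-connected to either boundary
#' face in the driving direction are retained but flagged — enclosed by
#' no-slip they self-consistently carry zero net flow.
#'
#' @param volume A [phase_volume()] or `rev_sample`.
#' @param direction Driving direction 1-3 used for the percolation flag.
#' @return List: `mask` (logical array, TRUE = water), `percolating`
#'   (logical), `n_isolated` (water components not spanning-connected),
#'   `empty` (no water at all).
#' @export
flow_domain <- function(volume, direction = 3) {
  stopifnot(inherits(volume, "phase_volume"))
  mask <- volume$labels == PHASE_WATER
  if (!any(mask))
    return(list(mask = mask, percolating = FALSE, n_isolated = 0L,
                empty = TRUE))
  lab <- label_components(mask, connectivity = 6)
  d <- dim(mask)
  lo <- switch(direction, lab[1, , ], lab[, 1, ], lab[, , 1])
  hi <- switch(direction, lab[d[1], , ], lab[, d[2], ], lab[, , d[3]])
  spanning <- intersect(setdiff(unique(as.vector(lo)), 0L),
                        setdiff(unique(as.vector(hi)), 0L))
  ncomp <- attr(lab, "n_components")
  list(mask = mask, percolating = length(spanning) > 0,
       n_isolated = ncomp - length(spanning), empty = FALSE)
}

#' Solve the Stokes homogenization cell problem on a voxel fluid mask
#'
#' Solves, on the water domain scaled to the unit cell,
#' `-laplacian(nu_k) + grad(pi_k) = e_k`, `div(nu_k) = 0`, with no-slip on
#' all solid/air interfaces, and on the outer boundary either the
#' mirror-symmetry conditions (zero pressure correction and tangential
#' velocity on faces normal to the driving direction; zero normal velocity
#' and normal gradients elsewhere) or fully periodic conditions. The
#' symmetric form on a sample is discretely identical to the periodic form
#' on its mirror reflection.
#'
#' @param mask 3D logical array, TRUE = fluid (water).
#' @param direction Driving direction, 1-3 or `"x"/"y"/"z"`.
#' @param boundary `"symmetric"` (default) or `"periodic"`.
#' @param tol Relative residual tolerance of the pressure Schur-complement
#'   solve (default 1e-8).
#' @param maxit Outer iteration cap.
#' @param fields If TRUE, return the corrector velocity and pressure fields.
#' @return Object of class `cell_solution`: nondimensional (voxel-unit)
#'   cell-averaged corrector velocity `mean_v` for all three components,
#'   residual norms, iteration count, and optionally the fields.
#' @export
#' @examples
#' # plane Poiseuille slab, aperture 8 of 16 cells
#' mask <- array(FALSE, c(16, 16, 16)); mask[, 5:12, ] <- TRUE
#' sol <- solve_cell_problem(mask, direction = 1)
#' # mean velocity ~ phi * a^2 / 12 in voxel units
#' c(sol$mean_v[1], 0.5 * 8^2 / 12)
solve_cell_problem <- function(mask, direction = 3,
                               boundary = c("symmetric", "periodic"),
                               tol = 1e-8, maxit = 600L, fields = FALSE) {
  boundary <- match.arg(boundary)
  if (is.character(direction))
    direction <- match(direction, c("x", "y", "z"))
  stopifnot(is.logical(mask), length(dim(mask)) == 3L,
            direction %in% 1:3, tol > 0)
  if (all(mask))
    stop("all-fluid mask with no solid and no air: net force unbalanced, no steady solution")
  lab <- label_components(mask, connectivity = 6,
                          wrap = boundary == "periodic")
  ncomp <- attr(lab, "n_components")
  d <- dim(mask)
  # pressure nullspace groups: components with no Dirichlet pressure
  # (periodic: all, under periodic topology; symmetric: those not touching
  # the driving-axis faces)
  grp <- array(0L, d)
  if (ncomp > 0) {
    if (boundary == "periodic") {
      grp <- lab
    } else {
      lo <- switch(direction, lab[1, , ], lab[, 1, ], lab[, , 1])
      hi <- switch(direction, lab[d[1], , ], lab[, d[2], ], lab[, , d[3]])
      touching <- union(setdiff(unique(as.vector(lo)), 0L),
                        setdiff(unique(as.vector(hi)), 0L))
      enclosed <- setdiff(seq_len(ncomp), touching)
      if (length(enclosed)) {
        remap <- integer(ncomp)
        remap[enclosed] <- seq_along(enclosed)
        sel <- lab > 0L
        grp[sel] <- remap[lab[sel]]
      }
    }
  }
  res <- cpp_stokes_solve(array(as.integer(mask), d), d,
                          as.integer(direction) - 1L,
                          ifelse(boundary == "periodic", 1L, 0L),
                          tol, as.integer(maxit), 5000L,
                          min(1e-10, tol * 1e-2),
                          as.integer(grp), fields)
  if (!res$converged && res$n_unknowns > 0) {
    err <- simpleError(sprintf(
      "cell problem did not converge in %d iterations (rel. residual %.3g)",
      res$iterations, res$rel_residual))
    attr(err, "residual_history") <- res$residual_history
    stop(err)
  }
  structure(list(direction = direction, boundary = boundary,
                 mean_v = res$mean_v, iterations = res$iterations,
                 rel_residual = res$rel_residual, div_inf = res$div_inf,
                 mom_rel = res$mom_rel, n_unknowns = res$n_unknowns,
                 dim = d,
                 velocity = if (fields) res$velocity else NULL,
                 pressure = if (fields) res$pressure else NULL),
            class = "cell_solution")
}

#' @export
print.cell_solution <- function(x, ...) {
  cat(sprintf("cell_solution dir %d (%s), %d unknowns, %d iterations, rel res %.2e\n",
              x$direction, x$boundary, x$n_unknowns, x$iterations,
              x$rel_residual))
  cat(sprintf("  mean corrector velocity (voxel units): %.4g %.4g %.4g\n",
              x$mean_v[1], x$mean_v[2], x$mean_v[3]))
  invisible(x)
}

#' Assemble the permeability tensor and hydraulic conductivity
#'
#' Converts nondimensional cell-problem solutions to physical units:
#' `K_jk = d^2 <e_j . nu_k> / mu` with `d` the voxel edge length (so that
#' for a fixed voxel grid `K` scales with the square of the REV side), and
#' hydraulic conductivity `K_h = rho g K_kk` in cm/s.
#'
#' @param solutions List of `cell_solution` objects (one per direction),
#'   all from the same geometry.
#' @param voxel_size_um Voxel edge length in micrometres.
#' @param constants Physical constants, see [water_constants()].
#' @param percolating Optional logical connectivity flag to carry through.
#' @return Object of class `conductivity_result`: `K` (m^3 s kg^-1 tensor,
#'   rows = velocity component, columns = driving direction), `K_h_cm_s`
#'   (named vector, diagonal entries), `L_y_mm`.
#' @export
assemble_conductivity <- function(solutions, voxel_size_um,
                                  constants = water_constants(),
                                  percolating = NA) {
  if (inherits(solutions, "cell_solution")) solutions <- list(solutions)
  dims <- vapply(solutions, function(s) s$dim, integer(3))
  if (nrow(unique(t(dims))) != 1L)
    stop("solutions come from inconsistent domains")
  d_m <- voxel_size_um * 1e-6
  K <- matrix(0, 3, 3)
  solved <- logical(3)
  for (s in solutions) {
    K[, s$direction] <- d_m^2 * s$mean_v / constants$mu
    solved[s$direction] <- TRUE
  }
  diagK <- diag(K)
  diagK[solved] <- pmax(diagK[solved], 0)  # clip solver-level negatives
  diag(K) <- diagK
  kh <- constants$rho * constants$g * diag(K) * 100
  structure(list(K = K, solved = solved,
                 K_h_cm_s = setNames(kh, c("x", "y", "z")),
                 L_y_mm = dims[1, 1] * voxel_size_um / 1e3,
                 voxel_size_um = voxel_size_um,
                 percolating = percolating),
            class = "conductivity_result")
}

#' @export
print.conductivity_result <- function(x, ...) {
  cat(sprintf("conductivity_result (L_y = %.3g mm)\n", x$L_y_mm))
  for (a in which(x$solved))
    cat(sprintf("  K_h %s = %.4g cm/s\n", c("x", "y", "z")[a],
                x$K_h_cm_s[a]))
  invisible(x)
}

#' Darcy velocity under an applied pressure gradient and gravity
#'
#' `u = -K (grad p0 - rho g e_z)`.
#'
#' @param result A `conductivity_result`.
#' @param pressure_gradient Numeric length-3 gradient of the applied
#'   pressure (Pa/m).
#' @param constants See [water_constants()].
#' @return Average velocity vector (m/s).
#' @export
darcy_velocity <- function(result, pressure_gradient = c(0, 0, 0),
                           constants = water_constants()) {
  stopifnot(inherits(result, "conductivity_result"),
            all(is.finite(result$K)))
  drive <- pressure_gradient - c(0, 0, constants$rho * constants$g)
  as.vector(-result$K %*% drive)
}

#' Hydraulic conductivity of a phase volume in one call
#'
#' Runs [flow_domain()], [solve_cell_problem()] per requested direction and
#' [assemble_conductivity()].
#'
#' @param volume A [phase_volume()] or `rev_sample`.
#' @param directions Integer vector of driving directions (default 3 = z).
#' @param ... Passed to [solve_cell_problem()].
#' @return A `conductivity_result`.
#' @export
hydraulic_conductivity <- function(volume, directions = 3, ...) {
  fd <- flow_domain(volume, direction = directions[1])
  if (fd$empty) {
    sols <- lapply(directions, function(a)
      structure(list(direction = a, boundary = "symmetric",
                     mean_v = c(0, 0, 0), iterations = 0L,
                     rel_residual = 0, div_inf = 0, mom_rel = 0,
                     n_unknowns = 0L, dim = dim(volume$labels)),
                class = "cell_solution"))
  } else {
    sols <- lapply(directions, function(a)
      solve_cell_problem(fd$mask, direction = a, ...))
  }
  assemble_conductivity(sols, volume$voxel_size_um,
                        percolating = fd$percolating)
}
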