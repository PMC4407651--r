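test_that("flow_domain isolates water and flags non-percolating pockets", {
  # fully water-saturated straight channel: mask equals the pore mask
  mask <- channel_mask(5, len = 16)
  lab <- array(0L, dim(mask)); lab[mask] <- 1L
  fd <- flow_domain(phase_volume(lab, 10), direction = 3)
  expect_identical(fd$mask, mask)
  expect_true(fd$percolating)
  # isolated droplet: retained but flagged non-percolating
  lab2 <- array(0L, c(12, 12, 12)); lab2[5:7, 5:7, 5:7] <- 1L
  fd2 <- flow_domain(phase_volume(lab2, 10), direction = 3)
  expect_false(fd2$percolating)
  expect_identical(fd2$n_isolated, 1L)
  # half-drained channel: air core is a no-slip obstacle, mask = annulus
  lab3 <- lab
  core <- channel_mask(2, margin = 10, len = 16)
  lab3[core] <- 2L
  fd3 <- flow_domain(phase_volume(lab3, 10), direction = 3)
  expect_identical(fd3$mask, mask & !core)
  # empty water phase
  fd4 <- flow_domain(phase_volume(array(0L, c(8, 8, 8)), 10))
  expect_true(fd4$empty)
})

test_that("plane Poiseuille flow matches the closed form within 5%", {
  n <- 32; a <- 16
  sol <- solve_cell_problem(slab_mask(n, a), direction = 1, tol = 1e-9)
  expect_lt(rel_err(sol$mean_v[1], poiseuille_mean(n, a)), 0.05)
  expect_lt(sol$div_inf, 1e-7)
  # transverse components carry no net flow
  expect_equal(sol$mean_v[2], 0)
  expect_equal(sol$mean_v[3], 0)
})

test_that("square-duct flow matches the series solution within 5%", {
  a <- 32
  mask <- duct_mask(a, w = 4, len = 8)
  sol <- solve_cell_problem(mask, direction = 3, tol = 1e-9)
  phi <- a^2 / prod(dim(mask)[1:2])
  expect_lt(rel_err(sol$mean_v[3], phi * duct_series_coef() * a^2), 0.05)
})

test_that("discretisation error decreases under grid refinement", {
  errs <- vapply(c(8, 16, 32), function(a) {
    sol <- solve_cell_problem(slab_mask(2 * a, a), direction = 1, tol = 1e-9)
    rel_err(sol$mean_v[1], poiseuille_mean(2 * a, a))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("degenerate masks are handled as specified", {
  empty <- array(FALSE, c(8, 8, 8))
  sol <- solve_cell_problem(empty, direction = 1)
  expect_equal(sol$mean_v, c(0, 0, 0))
  expect_error(solve_cell_problem(array(TRUE, c(8, 8, 8)), 1),
               "all-fluid")
  expect_error(solve_cell_problem(slab_mask(8, 4), 1, tol = -1), "tol")
})

test_that("symmetry-boundary solves equal periodic solves on the reflection", {
  v <- generate_sand_like(synthetic_spec("sand_like", c(16, 16, 16),
                                         target_porosity = 0.45,
                                         grain_radius_range = c(3, 5),
                                         rng_seed = 7))
  mask <- v$labels == 1L
  refl <- reflect_volume(mask)
  for (k in 1:3) {
    s1 <- solve_cell_problem(mask, k, tol = 1e-10)
    s2 <- solve_cell_problem(refl, k, boundary = "periodic", tol = 1e-10)
    expect_lt(rel_err(s1$mean_v[k], s2$mean_v[k]), 1e-8)
  }
})

test_that("permeability assembles with the documented physical scaling", {
  n <- 24; a <- 12
  sol <- solve_cell_problem(slab_mask(n, a), direction = 1, tol = 1e-9)
  cst <- water_constants()
  res1 <- assemble_conductivity(list(sol), voxel_size_um = 10)
  res2 <- assemble_conductivity(list(sol), voxel_size_um = 20)
  # doubling the physical length at fixed nondimensional geometry: K x4
  expect_equal(res2$K[1, 1] / res1$K[1, 1], 4)
  # Poiseuille slab: K = phi a^2 / (12 mu) with a in metres
  a_m <- a * 10e-6
  expect_lt(rel_err(res1$K[1, 1], (a / n) * a_m^2 / (12 * cst$mu)), 0.05)
  # K_h = rho g K in cm/s
  expect_equal(res1$K_h_cm_s[["x"]],
               cst$rho * cst$g * res1$K[1, 1] * 100)
  # zero solutions give a zero tensor
  zero <- sol; zero$mean_v <- c(0, 0, 0)
  expect_true(all(assemble_conductivity(list(zero), 10)$K == 0))
  # inconsistent domains are rejected
  other <- solve_cell_problem(slab_mask(16, 8), direction = 1)
  expect_error(assemble_conductivity(list(sol, other), 10), "inconsistent")
})

test_that("Darcy velocity follows u = -K (grad p - rho g e_z)", {
  sol <- solve_cell_problem(slab_mask(16, 8), direction = 3, tol = 1e-9)
  res <- assemble_conductivity(list(sol), 10)
  cst <- water_constants()
  # hydrostatic gradient balances gravity exactly
  expect_equal(darcy_velocity(res, c(0, 0, cst$rho * cst$g)), c(0, 0, 0))
  # zero applied gradient: gravity-driven definition
  u <- darcy_velocity(res, c(0, 0, 0))
  expect_equal(u[3], res$K[3, 3] * cst$rho * cst$g)
  # zero conductivity: no flow
  res0 <- res; res0$K <- matrix(0, 3, 3)
  expect_equal(darcy_velocity(res0, c(10, 0, 0)), c(0, 0, 0))
})

test_that("the discrete tensor is PSD-like: diagonal >= 0, exact adjoint symmetry", {
  v <- generate_sand_like(synthetic_spec("sand_like", c(24, 24, 24),
                                         rng_seed = 9))
  mask <- v$labels == 1L
  sols <- lapply(1:3, function(k)
    solve_cell_problem(mask, k, boundary = "periodic", tol = 1e-9))
  K <- assemble_conductivity(sols, 6)$K
  expect_true(all(diag(K) >= 0))
  asym <- max(abs(K - t(K))[row(K) != col(K)]) / mean(diag(K))
  expect_lt(asym, 1e-6)
})

test_that("domain monotonicity: removing fluid never increases conductivity", {
  set.seed(21)
  v <- generate_sand_like(synthetic_spec("sand_like", c(24, 24, 24),
                                         target_porosity = 0.5,
                                         grain_radius_range = c(3, 5),
                                         rng_seed = 31))
  B <- v$labels == 1L
  A <- B
  A[sample(which(B), round(0.15 * sum(B)))] <- FALSE
  kb <- solve_cell_problem(B, 3, tol = 1e-9)$mean_v[3]
  ka <- solve_cell_problem(A, 3, tol = 1e-9)$mean_v[3]
  expect_lte(ka, kb * (1 + 1e-6))
})
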