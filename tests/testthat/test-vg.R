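test_that("retention curve limits and a frozen high-precision value", {
  p <- vg_params(0.458, 0.052, 1.65)
  expect_equal(vg_theta(0, p), 0.458)                     # h = 0 -> theta_s
  expect_lt(vg_theta(1e12, p), 1e-6)                      # h -> Inf -> theta_r = 0
  # independent 40-digit evaluation of theta at h = 100 cm
  expect_equal(vg_theta(100, p), 0.15295081021969766, tolerance = 1e-12)
  expect_error(vg_theta(-1, p), "non-negative")
  expect_error(vg_params(0.4, -0.1, 1.5), "alpha")
  expect_error(vg_params(0.4, 0.05, 0.9), "n must")
  expect_equal(p$m, 1 - 1 / p$n)
})

test_that("relative conductivity limits, monotonicity, frozen value", {
  p <- vg_params(0.446, 0.051, 1.98)
  expect_equal(vg_relative_k(0, p), 1)
  h <- seq(0, 2000, by = 5)
  kr <- vg_relative_k(h, p)
  expect_true(all(diff(kr) <= 0))
  expect_true(all(kr >= 0 & kr <= 1))
  th <- vg_theta(h, p)
  expect_true(all(diff(th) <= 0))
  # independent 40-digit evaluation at h = 50 cm
  expect_equal(vg_relative_k(50, p), 0.0029463621719737957,
               tolerance = 1e-12)
})

test_that("head conversion is self-inverse and uses the flow constants", {
  expect_equal(water_constants()$kpa_to_cm, 1e5 / (1e3 * 9.8))
  p <- c(0, -5, -75)
  expect_equal(potential_from_head(head_from_potential(p)), -abs(p))
  expect_equal(head_from_potential(-1), 10.20408, tolerance = 1e-6)
})

test_that("noiseless round-trip fitting recovers the generator", {
  h <- head_from_potential(c(0, -5, -10, -20, -40, -60, -75))
  presets <- soil_presets()
  for (i in seq_len(nrow(presets))) {
    truth <- vg_params(presets$theta_s[i], presets$alpha_cm[i],
                       presets$n[i], Ksat = presets$Ksat_cm_s[i])
    wrc <- data.frame(head_cm = h, theta = vg_theta(h, truth))
    kd <- data.frame(head_cm = h,
                     K_cm_s = truth$Ksat * vg_relative_k(h, truth))
    fit <- fit_vg(wrc, kd)
    expect_lt(rel_err(fit$theta_s, truth$theta_s), 1e-4)
    expect_lt(rel_err(fit$alpha, truth$alpha), 1e-4)
    expect_lt(rel_err(fit$n, truth$n), 1e-4)
    expect_equal(fit$Ksat, truth$Ksat)   # taken from the h = 0 conductivity
  }
})

test_that("fitting degrades gracefully under water-content noise", {
  set.seed(42)
  truth <- vg_params(0.494, 0.032, 1.75)
  h <- head_from_potential(c(0, -5, -10, -20, -40, -60, -75))
  errs <- replicate(100, {
    th <- pmin(pmax(vg_theta(h, truth) + rnorm(length(h), 0, 0.01), 1e-4), 1)
    fit <- fit_vg(data.frame(head_cm = h, theta = th),
                  alpha_grid = c(0.01, 0.03, 0.1),
                  n_grid = c(1.3, 1.8, 2.5))
    rel_err(fit$n, truth$n)
  })
  expect_lt(median(errs), 0.05)
})

test_that("degenerate fitting inputs are rejected", {
  h3 <- c(0, 51, 102)
  expect_error(fit_vg(data.frame(head_cm = h3, theta = c(0.4, 0.3, 0.2))),
               "4 distinct")
  h <- head_from_potential(c(0, -5, -10, -20, -40))
  expect_error(fit_vg(data.frame(head_cm = h, theta = rep(0.4, 5))),
               "flat")
  expect_error(fit_vg(data.frame(head_cm = h, theta = seq(0.5, 0.1, -0.1)),
                      k = data.frame(head_cm = h, K_cm_s = c(1, 1, 1, -1, 1))),
               "positive")
})

test_that("convergence statistics summarise the dyadic ensemble", {
  # identical K at all levels: zero SD, converged from the second level on
  df <- data.frame(j = rep(0:3, each = 3), K_h_cm_s = 1e-3,
                   volume_mm3 = rep(54.9 / 2^(0:3), each = 3))
  cs <- convergence_stats(df)
  expect_equal(cs$sd_K_h, rep(0, 4))
  expect_true(all(cs$converged[-1]))
  expect_equal(cs$volume_mm3, 54.9 / 2^(0:3))
  # a single result in a level is skipped with a warning; all-single errors
  expect_warning(convergence_stats(
    data.frame(j = c(0, 0, 1), K_h_cm_s = c(1, 2, 3))), "fewer than 2")
  expect_error(suppressWarnings(convergence_stats(
    data.frame(j = 0:2, K_h_cm_s = 1:3))), "no level")
})

test_that("a truly periodic medium has scale-independent conductivity", {
  # one 8^3 unit cell vs its 3x tiling: periodic solves must agree
  cell <- duct_mask(4, w = 2, len = 8)[, , 1:8]
  tiled <- array(FALSE, c(24, 24, 24))
  for (i in 0:2) for (j in 0:2) for (k in 0:2)
    tiled[i * 8 + 1:8, j * 8 + 1:8, k * 8 + 1:8] <- cell
  k1 <- solve_cell_problem(cell, 3, boundary = "periodic", tol = 1e-10)
  k3 <- solve_cell_problem(tiled, 3, boundary = "periodic", tol = 1e-10)
  expect_lt(rel_err(k3$mean_v[3], k1$mean_v[3]), 1e-7)
})
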