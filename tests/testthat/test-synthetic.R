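test_that("sand-like generation hits the porosity target, reproducibly", {
  spec <- synthetic_spec("sand_like", c(64, 64, 64), target_porosity = 0.45,
                         rng_seed = 1)
  v <- generate_sand_like(spec)
  expect_s3_class(v, "phase_volume")
  expect_gte(porosity(v), 0.42)
  expect_lte(porosity(v), 0.48)
  # pore space starts fully water filled
  expect_true(all(v$labels %in% c(0L, 1L)))
  expect_identical(generate_sand_like(spec)$labels, v$labels)
})

test_that("degenerate sand specs fail loudly", {
  expect_error(synthetic_spec("sand_like", c(8, 8, 8)), "grid_shape")
  expect_error(synthetic_spec("sand_like", target_porosity = 1.2),
               "target_porosity")
  big <- synthetic_spec("sand_like", c(16, 16, 16),
                        grain_radius_range = c(20, 30))
  expect_error(generate_sand_like(big), "too large")
  # unreachable porosity names the achieved value
  hard <- synthetic_spec("sand_like", c(24, 24, 24), target_porosity = 0.05,
                         min_separation_factor = 1)
  expect_error(generate_sand_like(hard), "achieved porosity")
})

test_that("clay-like media carry the requested planar cracks", {
  spec <- synthetic_spec("clay_like", c(64, 64, 64), target_porosity = 0.52,
                         crack_count = 3, crack_aperture_range = c(5, 7),
                         rng_seed = 3)
  v <- generate_clay_like(spec)
  expect_equal(count_planar_voids(v), 3)
  expect_identical(generate_clay_like(spec)$labels, v$labels)
})

test_that("clay pore-radius histogram is bimodal; crack-free clay is not", {
  v <- generate_clay_like(synthetic_spec("clay_like", c(64, 64, 64),
                                         rng_seed = 2))
  h <- pore_radius_histogram(v)
  occupied <- which(h$count > 0)
  # two populations separated by at least one empty bin
  gaps <- which(diff(occupied) > 1)
  expect_gte(length(gaps), 1)
  lower <- h$count[occupied[occupied <= occupied[gaps[1]]]]
  upper <- h$count[occupied[occupied > occupied[gaps[1]]]]
  expect_gt(max(lower), 0)
  expect_gt(max(upper), 0)

  v0 <- generate_clay_like(synthetic_spec("clay_like", c(64, 64, 64),
                                          target_porosity = 0.35,
                                          crack_count = 0, rng_seed = 2))
  h0 <- pore_radius_histogram(v0)
  occ0 <- which(h0$count > 0)
  expect_true(all(diff(occ0) == 1))  # single contiguous mode
})

test_that("Young-Laplace critical radius behaves", {
  sch <- drainage_schedule()
  expect_identical(critical_radius_um(0, sch), Inf)
  expect_equal(critical_radius_um(-5, sch), 2 * 0.072 / 5000 * 1e6)
  expect_error(critical_radius_um(5, sch), "non-positive")
  expect_error(drainage_schedule(c(-5, -10)), "first potential")
  expect_error(drainage_schedule(c(0, -10, -5)), "strictly decreasing")
})

test_that("a straight channel drains exactly at its Young-Laplace radius", {
  mask <- channel_mask(r = 5, len = 40)
  labels <- array(0L, dim(mask))
  labels[mask] <- 1L
  v <- phase_volume(labels, voxel_size_um = 10)
  sch <- drainage_schedule()
  p_rc3 <- -2 * sch$surface_tension / (3 * 10e-6) / 1e3
  p_rc7 <- -2 * sch$surface_tension / (7 * 10e-6) / 1e3
  drained <- apply_drainage(v, p_rc3, sch)
  expect_true(all(drained$labels[mask] == 2L))     # entirely air
  held <- apply_drainage(v, p_rc7, sch)
  expect_true(all(held$labels[mask] == 1L))        # entirely water
  # potential 0 leaves the volume saturated and unchanged
  same <- apply_drainage(v, 0, sch)
  expect_identical(same$labels, v$labels)
  expect_error(apply_drainage(v, 5, sch), "non-positive")
})

test_that("drainage over the seven-potential schedule is physical", {
  sch <- drainage_schedule()
  v <- generate_sand_like(synthetic_spec("sand_like", c(48, 48, 48),
                                         rng_seed = 4))
  series <- drainage_series(v, sch)
  theta <- vapply(series, water_content, numeric(1))
  expect_true(all(diff(theta) <= 0))               # water never increases
  soil0 <- series[[1]]$labels == 0L
  for (s in series) {
    expect_identical(s$labels == 0L, soil0)        # solid invariant
    counts <- tabulate(s$labels + 1L, 3L)
    expect_identical(sum(counts), length(s$labels))  # phase partition
  }
  # air is cumulative along the drying branch
  for (i in 2:length(series))
    expect_true(all(series[[i]]$labels[series[[i - 1]]$labels == 2L] == 2L))
})

test_that("clay retains more water than sand at -75 kPa at matched porosity", {
  sch <- drainage_schedule()
  sand <- generate_sand_like(synthetic_spec("sand_like", c(48, 48, 48),
                                            target_porosity = 0.48,
                                            rng_seed = 11))
  clay <- generate_clay_like(synthetic_spec("clay_like", c(48, 48, 48),
                                            target_porosity = 0.48,
                                            crack_aperture_range = c(7, 9),
                                            rng_seed = 11))
  expect_lt(abs(porosity(sand) - porosity(clay)), 0.05)
  s75 <- drainage_series(sand, sch)[["-75"]]
  c75 <- drainage_series(clay, sch)[["-75"]]
  expect_gt(water_saturation(c75), water_saturation(s75))
})
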