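test_that("a digitised water cube yields exact volume and one component", {
  lab <- array(0L, c(16, 16, 16))
  lab[4:13, 4:13, 4:13] <- 1L
  m <- compute_metrics(phase_volume(lab, 10.17), check_filtered = FALSE)
  expect_equal(m$wfp_count, 1L)
  expect_equal(m$wfp_total_volume_mm3, (10 * 0.01017)^3)
  expect_equal(m$afp_count, 0L)
  expect_equal(m$largest_wfp_fraction, 1)
})

test_that("isosurface area of a digitised sphere is within 3% of 4 pi r^2", {
  mask <- sphere_mask(20)
  expect_lt(abs(surface_area(mask) / (4 * pi * 20^2) - 1), 0.03)
})

test_that("a fully saturated volume has porosity-equal water-filled porosity", {
  v <- generate_sand_like(synthetic_spec("sand_like", c(24, 24, 24),
                                         rng_seed = 6))
  m <- compute_metrics(v, check_filtered = FALSE)
  expect_equal(m$afp_count, 0L)
  expect_equal(m$water_filled_porosity, porosity(v))
})

test_that("phase volumes are conserved at every potential", {
  v <- generate_sand_like(synthetic_spec("sand_like", c(32, 32, 32),
                                         rng_seed = 8))
  series <- drainage_series(v)
  tab <- metrics_series(series, check_filtered = FALSE)
  expect_equal(tab$wfp_total_volume_mm3 + tab$afp_total_volume_mm3 +
                 tab$soil_volume_mm3, tab$sample_volume_mm3,
               tolerance = 1e-12)
  # drainage makes water non-increasing and air non-decreasing
  expect_true(all(diff(tab$wfp_total_volume_mm3) <= 0))
  expect_true(all(diff(tab$afp_total_volume_mm3) >= 0))
  expect_gte(attr(tab, "wfp_volume_change_pct"), 0)
})

test_that("a single volume yields one row with zero percent change", {
  v <- generate_sand_like(synthetic_spec("sand_like", c(16, 16, 16),
                                         rng_seed = 2))
  tab <- metrics_series(list(v), check_filtered = FALSE)
  expect_equal(nrow(tab), 1L)
  expect_equal(attr(tab, "wfp_volume_change_pct"), 0)
  v2 <- phase_volume(array(1L, c(8, 8, 8)), 10)
  expect_error(metrics_series(list(v, v2)), "same grid")
})

test_that("WFP surface area can rise while WFP volume falls (thin films)", {
  # thick water block vs a thinner sheet spread over more soil surface
  block <- array(0L, c(24, 24, 12))
  block[8:17, 8:17, 4:9] <- 1L     # 10 x 10 x 6 = 600 voxels
  sheet <- array(0L, c(24, 24, 12))
  sheet[3:22, 3:22, 4:5] <- 1L     # 20 x 20 x 2 = 800 -> trim to < 600
  sheet[3:12, 3:8, 4:5] <- 0L      # now 800 - 120 = 680... still > 600
  sheet[13:22, 3:8, 4:5] <- 0L     # 560 voxels < 600
  mb <- compute_metrics(phase_volume(block, 10), check_filtered = FALSE)
  ms <- compute_metrics(phase_volume(sheet, 10), check_filtered = FALSE)
  expect_lt(ms$wfp_total_volume_mm3, mb$wfp_total_volume_mm3)
  expect_gt(ms$wfp_total_surface_area_mm2, mb$wfp_total_surface_area_mm2)
})

test_that("solid- and fluid-contact interface areas are logged separately", {
  lab <- array(0L, c(12, 12, 12))
  lab[4:9, 4:9, 4:6] <- 1L
  lab[4:9, 4:9, 7:9] <- 2L
  m <- compute_metrics(phase_volume(lab, 10), check_filtered = FALSE)
  expect_gt(m$wfp_solid_contact_area_mm2, 0)
  expect_gt(m$wfp_fluid_contact_area_mm2, 0)
  expect_gt(m$afp_solid_contact_area_mm2, 0)
  # the water-air interface belongs to both phases' totals
  expect_equal(m$wfp_fluid_contact_area_mm2, 6 * 6 * (10e-3)^2)
})

test_that("metrics warn on unfiltered volumes", {
  lab <- array(0L, c(12, 12, 12))
  lab[6, 6, 6] <- 1L
  expect_warning(compute_metrics(phase_volume(lab, 10.17)),
                 "filter_noise")
})
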