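test_that("labelled volumes round-trip through TIFF + sidecar", {
  v <- generate_sand_like(synthetic_spec("sand_like", c(16, 16, 16),
                                         rng_seed = 2))
  path <- file.path(withr::local_tempdir(), "v.tif")
  write_volume(v, path)
  v2 <- read_volume(path)
  expect_identical(v2$labels, v$labels)
  expect_equal(v2$voxel_size_um, v$voxel_size_um)
  expect_equal(v2$potential_kpa, v$potential_kpa)
})

test_that("greyscale volumes preserve their dynamic range", {
  set.seed(1)
  g <- greyscale_volume(array(rnorm(16^3, 120, 40), c(16, 16, 16)),
                        voxel_size_um = 10.17,
                        water_ref_grey = 100, soil_ref_grey = 170)
  path <- file.path(withr::local_tempdir(), "g.tif")
  write_volume(g, path)
  g2 <- read_volume(path)
  expect_equal(range(g2$intensities), range(g$intensities))
  expect_lt(max(abs(g2$intensities - g$intensities)),
            diff(range(g$intensities)) / 65535 * 1.01)
})

test_that("reading without sidecar metadata is refused", {
  td <- withr::local_tempdir()
  v <- phase_volume(array(1L, c(8, 8, 8)), 10)
  path <- file.path(td, "v.tif")
  write_volume(v, path)
  file.remove(sub("\\.tif$", ".json", path))
  expect_error(read_volume(path), "sidecar")
  expect_error(read_volume(file.path(td, "absent.tif")), "no such file")
})

test_that("reference-calibrated segmentation recovers noisy phases", {
  truth <- generate_sand_like(synthetic_spec("sand_like", c(24, 24, 24),
                                             rng_seed = 5))
  labels <- truth$labels
  labels[1:8, 1:8, 1:8][labels[1:8, 1:8, 1:8] == 1L] <- 2L  # add some air
  grey <- array(0, dim(labels))
  grey[labels == 0L] <- 160; grey[labels == 1L] <- 100; grey[labels == 2L] <- 40
  # noiseless three-level image: exact recovery
  g0 <- greyscale_volume(grey, 10.17, water_ref_grey = 100,
                         soil_ref_grey = 160)
  expect_identical(segment_threshold(g0, air_ref_grey = 40)$labels, labels)
  # Gaussian noise at 10% of the class separation: >= 99% agreement
  set.seed(7)
  gn <- greyscale_volume(grey + rnorm(length(grey), 0, 6), 10.17,
                         water_ref_grey = 100, soil_ref_grey = 160)
  seg <- segment_threshold(gn, air_ref_grey = 40)
  expect_gte(mean(seg$labels == labels), 0.99)
  # inverted references are an error
  expect_error(greyscale_volume(grey, 10.17, water_ref_grey = 170,
                                soil_ref_grey = 100), "below")
  gb <- g0; gb$water_ref_grey <- 160; gb$soil_ref_grey <- 160
  expect_error(segment_threshold(gb), "inverted")
})

test_that("noise filtering removes sub-resolution objects and nothing else", {
  lab <- array(0L, c(16, 16, 16))
  lab[6, 6, 6] <- 1L                 # isolated water voxel: below both rules
  lab[10:12, 10:12, 10:12] <- 1L     # 3x3x3 water pore: retained
  v <- phase_volume(lab, voxel_size_um = 10.17)
  f <- filter_noise(v)
  expect_identical(f$labels[6, 6, 6], 0L)
  expect_true(all(f$labels[10:12, 10:12, 10:12] == 1L))
  expect_identical(attr(f, "n_removed")[["water"]], 1L)
  # (3 x 0.01017 mm)^3 comfortably exceeds the 8e-6 mm^3 volume rule
  expect_gt((3 * 10.17e-3)^3, 8e-6)
  # clean two-phase slab: no-op
  slab <- array(0L, c(12, 12, 12)); slab[, , 7:12] <- 1L
  vs <- phase_volume(slab, 10.17)
  expect_identical(filter_noise(vs)$labels, slab)
})

test_that("noise filtering is idempotent and conserves total volume", {
  set.seed(3)
  lab <- array(sample(0:2, 18^3, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
               c(18, 18, 18))
  v <- phase_volume(lab, 10.17)
  f1 <- filter_noise(v)
  f2 <- filter_noise(f1)
  expect_identical(f1$labels, f2$labels)
  expect_identical(length(f1$labels), length(lab))
  # soil may only grow by absorbing sub-threshold pore specks
  expect_true(all(f1$labels[lab == 0L] %in% 0:2))
})

test_that("2D mode applies the per-slice diameter rule", {
  lab <- array(0L, c(20, 20, 3))
  lab[5, 5, 2] <- 1L                       # diameter ~0.011 mm < 0.02 mm
  lab[10:16, 10:16, 2] <- 1L               # diameter ~0.09 mm: retained
  v <- phase_volume(lab, voxel_size_um = 10.17)
  f <- filter_noise(v, mode = "2D")
  expect_identical(f$labels[5, 5, 2], 0L)
  expect_true(all(f$labels[10:16, 10:16, 2] == 1L))
})

test_that("phase isosurfaces export as ASCII STL", {
  v <- phase_volume(array(c(0L, 1L)[1 + (slab_mask(12, 4))], c(12, 12, 12)),
                    10)
  path <- file.path(withr::local_tempdir(), "w.stl")
  write_phase_stl(v, "water", path)
  lines <- readLines(path)
  expect_match(lines[1], "^solid water")
  expect_gt(sum(grepl("^facet normal", lines)), 100)
  expect_match(lines[length(lines)], "^endsolid")
})
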