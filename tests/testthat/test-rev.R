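test_that("subsample cubes have the documented physical volume", {
  big <- phase_volume(array(1L, c(128, 128, 128)), voxel_size_um = 38)
  subs <- extract_subsamples(big, n = 6, side_mm = 3.8, seed = 1)
  expect_length(subs, 6)
  vols <- vapply(subs, function(s) rev_geometry(s)["volume_mm3"], numeric(1))
  expect_equal(signif(vols[1], 3), 54.9)
  # same seed -> identical origins; persisted origins reusable
  subs2 <- extract_subsamples(big, n = 6, side_mm = 3.8, seed = 1)
  expect_identical(subsample_manifest(subs), subsample_manifest(subs2))
  orig <- do.call(rbind, lapply(subs, `[[`, "origin"))
  subs3 <- extract_subsamples(big, n = 6, side_mm = 3.8, origins = orig)
  expect_identical(subsample_manifest(subs), subsample_manifest(subs3))
})

test_that("oversized subsample requests fail", {
  small <- phase_volume(array(1L, c(20, 20, 20)), voxel_size_um = 100)
  expect_error(extract_subsamples(small, 1, side_mm = 3.8), "does not fit")
})

test_that("the dyadic series halves volumes down to the 0.2 mm^3 level", {
  big <- phase_volume(array(1L, c(128, 128, 128)), voxel_size_um = 38)
  s0 <- extract_subsamples(big, 1, side_mm = 3.8, seed = 2)[[1]]
  ser <- dyadic_series(s0, j_max = 8)
  expect_length(ser, 9)
  v0 <- rev_geometry(s0)["volume_mm3"]
  noms <- vapply(ser, `[[`, numeric(1), "nominal_volume_mm3")
  expect_equal(noms, v0 / 2^(0:8), ignore_attr = TRUE)
  expect_equal(round(noms[9], 1), 0.2)
  # j = 0 is the identity; j = 1 side scales by 2^(-1/3) (whole voxels)
  expect_identical(ser[[1]]$labels, s0$labels)
  expect_equal(dim(ser[[2]]$labels)[1],
               round(dim(s0$labels)[1] * 2^(-1 / 3)))
  # strict nesting: every level is contained in the previous one
  for (j in 2:9) {
    expect_true(all(dim(ser[[j]]$labels) < dim(ser[[j - 1]]$labels)))
    expect_true(all(ser[[j]]$origin >= ser[[j - 1]]$origin))
  }
})

test_that("a too-deep dyadic series truncates with a warning", {
  small <- phase_volume(array(1L, c(16, 16, 16)), voxel_size_um = 100)
  s0 <- extract_subsamples(small, 1, side_mm = 1.6, seed = 1)[[1]]
  expect_warning(ser <- dyadic_series(s0, j_max = 8), "truncated")
  expect_lt(length(ser), 9)
  expect_gte(min(vapply(ser, function(s) dim(s$labels)[1], integer(1))), 4)
})

test_that("reflection builds a periodic volume and preserves fractions", {
  v <- generate_sand_like(synthetic_spec("sand_like", c(16, 16, 16),
                                         rng_seed = 3))
  r <- reflect_volume(v)
  expect_identical(dim(r$labels), 2L * dim(v$labels))
  expect_equal(phase_fractions(r), phase_fractions(v))
  # opposite boundary faces are identical voxel-by-voxel
  expect_identical(r$labels[1, , ], r$labels[32, , ])
  expect_identical(r$labels[, 1, ], r$labels[, 32, ])
  expect_identical(r$labels[, , 1], r$labels[, , 32])
  # uniform volume reflects to a uniform volume of 8x the voxel count
  u <- phase_volume(array(1L, c(8, 8, 8)), 10)
  ru <- reflect_volume(u)
  expect_true(all(ru$labels == 1L))
  expect_identical(length(ru$labels), 8L * length(u$labels))
})
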