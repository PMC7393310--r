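test_that("smoothing preserves constants in the interior and conserves impulse mass", {
  img <- unit_volume(c(31L, 31L, 31L), value = 3.0)
  sm <- gaussian_smooth(img, 5)
  # kernel radius is 9 voxels at 5 mm FWHM on a 1 mm grid, so voxels at
  # least 10 from every face are untouched by the zero padding
  interior <- sm$data[11:21, 11:21, 11:21]
  expect_true(all(abs(interior - 3.0) < 1e-6))

  imp <- unit_volume(c(31L, 31L, 31L))
  imp$data[16, 16, 16] <- 1
  sm <- gaussian_smooth(imp, 5)
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)
  expect_error(gaussian_smooth(img, -1), "positive")
})

test_that("smoothed impulse matches a direct dense-convolution oracle", {
  imp <- unit_volume(c(25L, 25L, 25L))
  imp$data[13, 13, 13] <- 1
  sm <- gaussian_smooth(imp, 5)

  # oracle: explicit triple-loop convolution with the sampled 3D kernel
  sigma <- 5 / (2 * sqrt(2 * log(2)))
  r <- ceiling(4 * sigma)
  k1 <- dnorm(-r:r, sd = sigma); k1 <- k1 / sum(k1)
  expected <- array(0, dim(imp$data))
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    expected[13 + dx, 13 + dy, 13 + dz] <-
      k1[dx + r + 1] * k1[dy + r + 1] * k1[dz + r + 1]
  }
  expect_equal(sm$data, expected, tolerance = 1e-12)
})

test_that("sphere mask matches the integer-lattice counting oracle", {
  img <- unit_volume(c(21L, 21L, 21L))
  # oracle: enumerate integer offsets with dx^2+dy^2+dz^2 <= r^2
  lattice_count <- function(r) {
    m <- floor(r)
    sum(outer(outer((-m:m)^2, (-m:m)^2, "+"), (-m:m)^2, "+") <= r^2)
  }
  for (diam in c(5, 2.5, 7.5, 0.5)) {
    idx <- sphere_mask(c(0, 0, 0), diam, img)
    expect_equal(length(idx), lattice_count(diam / 2))
  }
  expect_equal(length(sphere_mask(c(0, 0, 0), 5, img)), 81L)
  expect_equal(length(sphere_mask(c(0, 0, 0), 0.5, img)), 1L)
})

test_that("sphere mask flags out-of-grid and clipped spheres", {
  img <- unit_volume(c(21L, 21L, 21L))
  expect_error(sphere_mask(c(1000, 0, 0), 5, img), "outside")
  expect_error(sphere_mask(c(10, 0, 0), 5, img), "clipped")
  idx <- sphere_mask(c(10, 0, 0), 5, img, allow_clipped = TRUE)
  expect_lt(length(idx), 81L)
  expect_gt(length(idx), 0L)
})

test_that("region means round-trip painted fixture images", {
  atlas <- lattice_atlas(6L)
  cfg <- simulation_config(n = 8L, seed = 21L)
  cohort <- generate_cohort(cfg, atlas)
  dir <- withr::local_tempdir()
  paths <- generate_volume_images(cohort, atlas, dir)
  expect_length(paths, 8L)

  img <- read_volume(paths[1])
  exact <- extract_region_means(img, atlas, smooth_fwhm_mm = 0)
  expect_equal(unname(exact), unname(cohort$volumes$raw[1, ]),
               tolerance = 1e-12)
  smoothed <- extract_region_means(img, atlas, smooth_fwhm_mm = 5)
  expect_true(all(abs(smoothed / cohort$volumes$raw[1, ] - 1) < 0.01))
})

test_that("extraction is translation-equivariant", {
  atlas <- lattice_atlas(4L)
  cfg <- simulation_config(n = 8L, seed = 5L)
  cohort <- generate_cohort(cfg, atlas)
  dir <- withr::local_tempdir()
  p <- generate_volume_images(cohort, atlas, dir, participants = 1L)
  img <- read_volume(p)
  base <- extract_region_means(img, atlas, smooth_fwhm_mm = 0)

  shift <- c(3, -2, 4)
  shifted_img <- sb_volume(img$data, {
    a <- img$affine; a[1:3, 4] <- a[1:3, 4] + shift; a
  })
  shifted_atlas <- as.data.frame(atlas)
  shifted_atlas[, c("x", "y", "z")] <-
    sweep(as.matrix(shifted_atlas[, c("x", "y", "z")]), 2, shift, "+")
  shifted_atlas <- validate_atlas(shifted_atlas, strict = FALSE)
  expect_equal(extract_region_means(shifted_img, shifted_atlas,
                                    smooth_fwhm_mm = 0), base)
})

test_that("zscore_columns matches its definition and rejects degenerate input", {
  expect_equal(as.vector(zscore_columns(matrix(c(1, 3)))), c(-1, 1))
  expect_error(zscore_columns(matrix(c(5, 5, 5))), "zero-variance")
  expect_error(zscore_columns(matrix(1, 1, 1)), "at least 2 rows")

  set.seed(1)
  m <- matrix(rnorm(200), 50, 4)
  z <- zscore_columns(m)
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_true(all(abs(colMeans(z^2) - 1) < 1e-12))
})

test_that("extract_cohort is deterministic and shape-stable", {
  atlas <- lattice_atlas(4L)
  cohort <- generate_cohort(simulation_config(n = 8L, seed = 9L), atlas)
  dir <- withr::local_tempdir()
  paths <- generate_volume_images(cohort, atlas, dir, participants = 1:3)
  vols <- extract_cohort(c(paths, paths[1]), atlas, smooth_fwhm_mm = 0,
                         participant_ids = c("a", "b", "c", "a2"))
  expect_equal(dim(vols$raw), c(4L, 4L))
  expect_equal(unname(vols$raw["a", ]), unname(vols$raw["a2", ]))
  expect_equal(unname(vols$raw[1:3, ]),
               unname(cohort$volumes$raw[1:3, ]), tolerance = 1e-12)
})

test_that("region-volume CSV round-trips", {
  atlas <- lattice_atlas(4L)
  cohort <- generate_cohort(simulation_config(n = 10L, seed = 2L), atlas)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_region_volumes(cohort$volumes, tmp)
  back <- read_region_volumes(tmp)
  expect_equal(back$raw, cohort$volumes$raw, tolerance = 1e-12)
})
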