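test_that("qmap is zero at the beam center, radially symmetric and correct", {
  g <- mini_geometry(32L, pixel = 75e-6, center = c(16, 16))
  qm <- qmap(g)
  expect_equal(qm[17, 17], 0)  # 0-based (16,16) = beam center
  # equal radius -> equal q
  expect_equal(qm[17, 21], qm[21, 17])
  expect_equal(qm[17, 13], qm[17, 21])
  # r = 100 px with experiment defaults: 4*pi*sin(arctan(0.0075/0.130)/2)/0.729
  gbig <- detector_geometry(shape = c(128L, 128L), beam_center = c(5, 5),
                            panel_mask = matrix(TRUE, 128, 128))
  qbig <- qmap(gbig)
  expect_equal(qbig[6, 106], 0.4966255, tolerance = 1e-6)
})

test_that("q grows monotonically with radial pixel distance", {
  g <- mini_geometry(48L, center = c(0, 0))
  qm <- qmap(g)
  row0 <- qm[1, ]  # along increasing radius
  expect_true(all(diff(row0) > 0))
  diag0 <- diag(qm)
  expect_true(all(diff(diag0) > 0))
})

test_that("geometry constructor validates its inputs", {
  expect_error(detector_geometry(distance = 0), "distance")
  expect_error(detector_geometry(pixel_size = -1), "pixel_size")
  expect_error(detector_geometry(wavelength = 0), "wavelength")
  g <- detector_geometry(shape = c(16L, 16L))
  expect_false(any(g$panel_mask[9:16, ]))  # lower panel dead by default
  expect_true(all(g$panel_mask[1:8, ]))
})

test_that("crop_patch returns the exact requested window and zero-fills masked pixels", {
  set.seed(2)
  img <- matrix(rpois(64 * 64, 5), 64, 64)
  mask <- matrix(TRUE, 64, 64); mask[33:64, ] <- FALSE
  p <- diffraction_pattern(img, mask, "t")
  patch <- crop_patch(p, c(8L, 8L), c(16L, 24L))
  expect_equal(dim(patch), c(16L, 24L))
  expect_equal(patch, img[9:24, 9:32])
  # a crop straddling the dead panel zero-fills it
  patch2 <- crop_patch(p, c(24L, 0L), c(16L, 16L))
  expect_true(all(patch2[9:16, ] == 0))
  expect_equal(patch2[1:8, ], img[25:32, 1:16])
  # identity crop
  small <- diffraction_pattern(matrix(1:12, 3, 4))
  expect_equal(crop_patch(small, c(0L, 0L), c(3L, 4L)), small$intensity)
  # bounds errors
  expect_error(crop_patch(p, c(60L, 0L), c(16L, 16L)), "out of bounds")
  expect_error(crop_patch(p, c(-1L, 0L), c(4L, 4L)), "out of bounds")
})

test_that("default crop anchor hugs the live panel next to the beam center", {
  g <- toy_geometry(c(64L, 64L))          # live rows 0..31, center (31.5, 31.5)
  a <- default_crop_anchor(g, c(32L, 16L))
  expect_equal(a[1], 0L)                   # pushed against the live panel edge
  expect_equal(a[2], 24L)                  # centered on the beam column
  expect_error(default_crop_anchor(g, c(64L, 16L)), "does not fit")
})

test_that("patch standardization matches (x - mu)/sigma with the published stats", {
  st <- norm_stats()                       # mu = 0.342, sigma = 2.336
  expect_equal(normalize_patch(matrix(0.342), st), matrix(0))
  expect_equal(normalize_patch(matrix(0.342 + 2.336), st), matrix(1))
  ident <- norm_stats(0, 1)
  x <- matrix(rnorm(20), 4, 5)
  expect_equal(normalize_patch(x, ident), x)
  expect_error(norm_stats(0, 0), "sigma")
})

test_that("stats computed from a pool standardize that pool to mean 0, sd 1", {
  set.seed(11)
  patches <- lapply(1:20, function(i) matrix(rexp(64, 0.3), 8, 8))
  st <- compute_norm_stats(patches)
  z <- unlist(lapply(patches, normalize_patch, stats = st))
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-10)
  # masked pixels are excluded from the statistics
  mask <- matrix(TRUE, 8, 8); mask[1, ] <- FALSE
  stm <- compute_norm_stats(patches, mask)
  vals <- unlist(lapply(patches, function(p) p[mask]))
  expect_equal(stm$mu, mean(vals))
})

test_that("pattern archives round-trip losslessly and validate their groups", {
  g <- mini_geometry(16L)
  set.seed(3)
  pats <- lapply(1:4, function(i)
    diffraction_pattern(matrix(rpois(256, 2), 16, 16), g$panel_mask,
                        sprintf("p%03d", i)))
  f <- tempfile(fileext = ".rds")
  write_patterns(pats, f, labels = c(1L, 0L, 0L, 1L),
                 true_size_nm = c(60, NA, NA, 70), geometry = g)
  back <- read_patterns(f)
  expect_length(back$patterns, 4)
  for (i in 1:4) {
    expect_identical(back$patterns[[i]]$intensity, pats[[i]]$intensity)
    expect_identical(back$patterns[[i]]$id, pats[[i]]$id)
  }
  expect_identical(back$labels, c(1L, 0L, 0L, 1L))
  expect_equal(back$true_size_nm, c(60, NA, NA, 70))

  # empty archive is valid
  f2 <- tempfile(fileext = ".rds")
  write_patterns(list(), f2)
  expect_length(read_patterns(f2)$patterns, 0)

  # missing group is named in the error
  broken <- readRDS(f); broken$mask <- NULL
  f3 <- tempfile(fileext = ".rds"); saveRDS(broken, f3)
  expect_error(read_patterns(f3), "mask")
  expect_error(read_patterns(tempfile()), "no such file")
})

test_that("geometry YAML round-trips", {
  g <- toy_geometry()
  f <- tempfile(fileext = ".yaml")
  write_geometry_yaml(g, f)
  g2 <- read_geometry_yaml(f)
  expect_equal(g2$distance, g$distance)
  expect_equal(g2$pixel_size, g$pixel_size)
  expect_equal(g2$beam_center, g$beam_center)
  expect_identical(g2$panel_mask, g$panel_mask)
  cfg <- yaml::read_yaml(f); cfg$distance_m <- NULL
  f2 <- tempfile(fileext = ".yaml"); yaml::write_yaml(cfg, f2)
  expect_error(read_geometry_yaml(f2), "distance_m")
})
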