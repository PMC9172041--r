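test_that("angular averaging reproduces an isotropic radial profile", {
  g <- mini_geometry(48L)
  qm <- qmap(g)
  f <- function(q) 100 * exp(-3 * q)
  p <- diffraction_pattern(f(qm), g$panel_mask, "iso")
  crv <- compute_psd(p, g, n_bins = 60)
  ok <- crv$occupancy > 0
  expect_lt(max(abs(crv$intensity[ok] - f(crv$q_centers[ok])) /
                  f(crv$q_centers[ok])), 0.02)
  # constant frame -> constant PSD
  pc <- diffraction_pattern(matrix(7, 48, 48), g$panel_mask, "const")
  cc <- compute_psd(pc, g, n_bins = 40)
  expect_true(all(abs(cc$intensity[cc$occupancy > 0] - 7) < 1e-12))
  expect_error(compute_psd(list(), g), "empty selection")
})

test_that("the angular average is rotation invariant for isotropic patterns", {
  g <- mini_geometry(40L, center = c(19.5, 19.5))
  qm <- qmap(g)
  img <- 50 * sphere_intensity(qm, 30) + 2
  p1 <- diffraction_pattern(img, id = "a")
  p2 <- diffraction_pattern(t(img)[, 40:1], id = "rot90")  # 90-degree rotation
  c1 <- compute_psd(p1, g, n_bins = 50)
  c2 <- compute_psd(p2, g, n_bins = 50)
  expect_equal(c1$intensity, c2$intensity, tolerance = 1e-10)
})

test_that("extremum detection returns an alternating, pruned sequence", {
  # sampled cosine in log space: extrema at known phases
  q <- seq(0.01, 1, length.out = 200)
  y <- 10^(cos(2 * pi * 3 * q) - 1)  # maxima where cos = 1
  crv <- structure(list(q_centers = q, intensity = y,
                        occupancy = rep(1, 200)), class = "psd_curve")
  ext <- find_extrema(crv, smooth_window = 0, min_prominence = 0.01)
  expect_true(all(ext$type[c(TRUE, FALSE)] == ext$type[1]))  # alternating
  types <- rle(ext$type)$lengths
  expect_true(all(types == 1))
  maxq <- ext$q[ext$type == "max"]
  expect_true(all(vapply(maxq, function(x)
    min(abs(x - c(1 / 3, 2 / 3, 1))) < 0.02, logical(1))))
  # strictly monotone curve -> empty
  mono <- structure(list(q_centers = q, intensity = exp(-q),
                         occupancy = rep(1, 200)), class = "psd_curve")
  expect_equal(nrow(find_extrema(mono)), 0)
  short <- structure(list(q_centers = q[1:3], intensity = y[1:3],
                          occupancy = rep(1, 3)), class = "psd_curve")
  expect_error(find_extrema(short), "5 usable bins")
})

test_that("PSD contrast is the mean max-min difference over the first pairs", {
  # piecewise-linear log curve with extrema exactly at
  # maxima {-1, -1.5, -2} and minima {-1.6, -2.1, -2.6}
  logv <- c(0, -3, -1, -1.6, -1.5, -2.1, -2, -2.6, -2.4)
  q <- seq_along(logv) / 10
  crv <- structure(list(q_centers = q, intensity = 10^logv,
                        occupancy = rep(1, length(q))), class = "psd_curve")
  res <- psd_contrast(crv, n_pairs = 3, smooth_window = 0,
                      min_prominence = 0)
  expect_equal(res$contrast, 0.6, tolerance = 1e-10)
  expect_equal(res$maxima$value, c(-1, -1.5, -2), tolerance = 1e-10)
  expect_equal(res$minima$value, c(-1.6, -2.1, -2.6), tolerance = 1e-10)

  # constant-amplitude oscillation -> contrast equals that amplitude
  logv2 <- c(0, -2, -1, rep(c(-2, -1), 3), -2.5)
  crv2 <- structure(list(q_centers = seq_along(logv2) / 10,
                         intensity = 10^logv2,
                         occupancy = rep(1, length(logv2))),
                    class = "psd_curve")
  res2 <- psd_contrast(crv2, n_pairs = 3, smooth_window = 0,
                       min_prominence = 0)
  expect_equal(res2$contrast, 1, tolerance = 1e-10)

  # insufficient extrema is a descriptive error
  mono <- structure(list(q_centers = q, intensity = exp(-q),
                         occupancy = rep(1, length(q))), class = "psd_curve")
  expect_error(psd_contrast(mono), "contrast undefined")
})

test_that("contrast on the normalized log curve ignores intensity scaling", {
  g <- toy_geometry()
  set.seed(4)
  s <- simulate_pattern(quiet_sim(), g, TRUE, noiseless = TRUE)
  crv <- compute_psd(s$pattern, g, n_bins = 120)
  scaled <- crv
  scaled$intensity <- crv$intensity * 137.5
  c1 <- psd_contrast(crv)
  c2 <- psd_contrast(scaled)
  expect_equal(c1$contrast, c2$contrast, tolerance = 1e-10)
})

test_that("sphere sizes are recovered from noiseless patterns", {
  g <- toy_geometry()
  cfg <- quiet_sim()
  set.seed(55)
  s <- simulate_pattern(cfg, g, TRUE, noiseless = TRUE)
  est <- estimate_size(s$pattern, g)
  expect_equal(est$method, "form_factor_fit")
  expect_lt(abs(est$diameter_nm - s$true_size_nm) / s$true_size_nm, 0.02)
  # fringe-spacing route: asymptotic minima spacing pi/R
  est2 <- estimate_size(s$pattern, g, method = "fringe_spacing")
  expect_lt(abs(est2$diameter_nm - s$true_size_nm) / s$true_size_nm, 0.10)
})

test_that("doubling the radius halves the fringe spacing", {
  g <- mini_geometry(64L, pixel = 2.0e-4)
  qm <- qmap(g)
  dq <- numeric(2)
  for (i in 1:2) {
    R <- 20 * i
    p <- diffraction_pattern(1e4 * sphere_intensity(qm, R), id = "s")
    ext <- find_extrema(compute_psd(p, g, n_bins = 150))
    mins <- ext$q[ext$type == "min"]
    dq[i] <- mean(diff(mins))
  }
  expect_equal(dq[1] / dq[2], 2, tolerance = 0.12)
})

test_that("size filtering keeps the inclusive 55-84 nm band and drops unknowns", {
  sel <- selection("s", c("a", "b", "c", "d", "e"))
  sizes <- c(a = 50, b = 60, c = 84, d = 90, e = NA)
  kept <- size_filter(sel, sizes)
  expect_setequal(kept$ids, c("b", "c"))
  expect_equal(kept$name, "s+size")
  expect_length(size_filter(selection("empty", character(0)), sizes), 0)
  expect_error(size_filter(sel, sizes, low = 90, high = 60), "invalid")
  # boundary values are kept (inclusive bounds)
  expect_true("c" %in% size_filter(sel, sizes, 55, 84)$ids)
})

test_that("background is read off the high-q plateau and subtraction clamps", {
  g <- mini_geometry(48L)
  qm <- qmap(g)
  img <- 1000 * sphere_intensity(qm, 40) + 3.5
  p <- diffraction_pattern(img, g$panel_mask, "bg")
  qmax <- max(qm)
  est <- estimate_background(p, c(0.7 * qmax, qmax), g)
  expect_equal(est, 3.5, tolerance = 0.02)
  crv <- compute_psd(p, g, n_bins = 80)
  est2 <- estimate_background(crv, c(0.7 * qmax, qmax))
  expect_equal(est2, 3.5, tolerance = 0.02)
  # zero-background pattern
  p0 <- diffraction_pattern(1000 * sphere_intensity(qm, 40),
                            g$panel_mask, "nobg")
  expect_lt(estimate_background(p0, c(0.7 * qmax, qmax), g), 0.05)
  expect_error(estimate_background(crv, c(10, 20)), "no occupied bins")
  sub <- subtract_background(p, 5)
  expect_true(all(sub$intensity >= 0))
  expect_equal(sub$intensity[img - 5 > 0], (img - 5)[img - 5 > 0])
})

test_that("Poisson background estimates are unbiased over repeated frames", {
  g <- mini_geometry(24L)
  cfg <- quiet_sim(mean_photon_scale = 50, background_level = 2)
  qmax <- max(qmap(g))
  set.seed(77)
  frames <- replicate(100, simulate_pattern(cfg, g, TRUE)$pattern,
                      simplify = FALSE)
  crv <- compute_psd(frames, g, n_bins = 60)
  est <- estimate_background(crv, c(0.85 * qmax, qmax))
  npix <- 100 * sum(qmap(g) >= 0.85 * qmax)
  se <- sqrt(2 / npix)
  # allow 3 SE plus the small residual form-factor tail in the window
  expect_lt(abs(est - 2), 3 * se + 0.05)
})
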