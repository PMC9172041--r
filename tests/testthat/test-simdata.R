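test_that("sphere form factor hits its analytic landmarks", {
  expect_equal(sphere_intensity(0, 35, 1), 1)
  # continuity at q -> 0
  expect_equal(sphere_intensity(1e-9, 35, 1), 1, tolerance = 1e-10)
  # first root of tan(x) = x is an intensity zero
  expect_equal(sphere_intensity(4.4934095 / 35, 35, 1), 0, tolerance = 1e-9)
  expect_equal(sphere_intensity(7.7252518 / 50, 50, 1), 0, tolerance = 1e-9)
  # closed form at qR = pi: (3/pi^2)^2
  expect_equal(sphere_intensity(pi / 35, 35, 1), (3 / pi^2)^2,
               tolerance = 1e-10)
  # i0 scales linearly
  expect_equal(sphere_intensity(0.1, 30, 7), 7 * sphere_intensity(0.1, 30, 1))
  expect_error(sphere_intensity(0.1, -1), "radius")
  expect_error(sphere_intensity(0.1, 0), "radius")
})

test_that("a one-particle non-single draw reproduces the single-hit expectation", {
  g <- mini_geometry(16L)
  cfg <- quiet_sim()
  set.seed(99)
  s1 <- simulate_pattern(cfg, g, TRUE, noiseless = TRUE)
  set.seed(99)
  s2 <- simulate_pattern(cfg, g, FALSE, noiseless = TRUE, n_particles = 1)
  expect_equal(s2$pattern$intensity, s1$pattern$intensity, tolerance = 1e-12)
  expect_equal(s1$label, 1L)
  expect_equal(s2$label, 0L)
})

test_that("fixed seed reproduces frames exactly", {
  g <- toy_geometry(c(32L, 32L))
  cfg <- sim_config(seed = 1)
  set.seed(123); a <- simulate_pattern(cfg, g, FALSE)
  set.seed(123); b <- simulate_pattern(cfg, g, FALSE)
  expect_identical(a$pattern$intensity, b$pattern$intensity)
  expect_identical(a$true_size_nm, b$true_size_nm)
})

test_that("Poisson sampling is unbiased against the noiseless expectation", {
  g <- mini_geometry(8L)
  cfg <- quiet_sim(mean_photon_scale = 50, background_level = 1)
  n <- 10000
  px <- c(3L, 6L)
  noisy <- numeric(n); expected <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(i); a <- simulate_pattern(cfg, g, TRUE)
    set.seed(i); b <- simulate_pattern(cfg, g, TRUE, noiseless = TRUE)
    noisy[i] <- a$pattern$intensity[px[1], px[2]]
    expected[i] <- b$pattern$intensity[px[1], px[2]]
  }
  se <- sqrt(mean(expected) / n)  # Poisson standard error of the mean
  expect_lt(abs(mean(noisy) - mean(expected)), 3 * se)
})

test_that("generated datasets have exact class counts, sizes and determinism", {
  g <- toy_geometry(c(32L, 32L))
  cfg <- sim_config(seed = 42)
  ds <- generate_dataset(cfg, g, 12, 88)
  expect_length(ds$patterns, 100)
  expect_equal(sum(ds$labels == 1L), 12)
  expect_equal(sum(ds$labels == 0L), 88)
  # ground-truth sizes follow the generation branch
  expect_true(all(!is.na(ds$true_size_nm[ds$labels == 1L])))
  expect_true(all(is.na(ds$true_size_nm[ds$labels == 0L])))
  # byte-identical on regeneration
  ds2 <- generate_dataset(cfg, g, 12, 88)
  expect_identical(lapply(ds$patterns, `[[`, "intensity"),
                   lapply(ds2$patterns, `[[`, "intensity"))
  expect_identical(ds$labels, ds2$labels)
  # degenerate all-non-single dataset
  ds0 <- generate_dataset(sim_config(seed = 7), g, 0, 10)
  expect_true(all(ds0$labels == 0L))
})

test_that("hit-stream label draws respect the configured class ratio", {
  cfg <- sim_config(single_fraction = 1 / 200, seed = 8)
  n <- 1e5
  lab <- sample_hit_labels(cfg, n)
  p <- 1 / 200
  sigma <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(lab) - p), 3 * sigma)
  # deterministic under the config seed
  expect_identical(lab, sample_hit_labels(cfg, n))
})

test_that("intensities are non-negative and dead pixels carry no signal", {
  g <- toy_geometry(c(32L, 32L))
  ds <- generate_dataset(sim_config(seed = 3), g, 3, 17)
  for (p in ds$patterns) {
    expect_true(all(p$intensity >= 0))
    expect_true(all(p$intensity[!g$panel_mask] == 0))
  }
})

test_that("simulated fringe minima land at the roots of tan(x) = x", {
  g <- toy_geometry()
  cfg <- quiet_sim()
  set.seed(21)
  s <- simulate_pattern(cfg, g, TRUE, noiseless = TRUE)
  R <- s$true_size_nm / 2
  crv <- compute_psd(s$pattern, g, n_bins = 150)
  ext <- find_extrema(crv)
  mins <- ext$q[ext$type == "min"]
  bw <- diff(crv$q_centers[1:2])
  for (root in c(4.4934095, 7.7252518)) {
    expect_lt(min(abs(mins - root / R)), bw)
  }
})

test_that("simulation config rejects invalid parameter combinations", {
  expect_error(sim_config(particle_radius_range = c(42, 27.5)), "ordered")
  expect_error(sim_config(particle_radius_range = c(-5, 10)), "ordered")
  expect_error(sim_config(single_fraction = 0), "single_fraction")
  expect_error(sim_config(single_fraction = 1), "single_fraction")
  expect_error(sim_config(multi_particle_count_range = c(1, 3)), ">= 2")
})
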