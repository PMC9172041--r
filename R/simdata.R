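#' Simulation configuration
#'
#' Parameters of the synthetic diffraction generator. The generator emulates
#' the statistical structure of an SPI hit stream: sphere-like particles with
#' concentric form-factor fringes, multi-particle frames with coherent
#' interference, Poisson photon noise, pulse-to-pulse fluence jitter, a flat
#' background and a heavily imbalanced single:non-single class ratio
#' (default 1:200).
#'
#' @param particle_radius_range Radius interval (nm) of the target particle
#'   population; default 27.5-42 nm (diameters 55-84 nm, the expected virus
#'   band).
#' @param single_fraction Probability that a random frame is a single hit.
#' @param fluence_jitter Log-normal sigma of the per-pulse incident-intensity
#'   factor (mean 1).
#' @param mean_photon_scale Expected photons per pixel at q -> 0 for a
#'   reference particle at nominal fluence.
#' @param background_level Flat background, photons per pixel.
#' @param multi_particle_count_range Integer interval (min >= 2) for the
#'   number of particles in a non-single hit.
#' @param displacement_range Interval (nm) for the magnitude of random
#'   inter-particle displacement vectors.
#' @param contaminant_fraction Fraction of single-hit particles drawn from
#'   sizes outside `particle_radius_range` (dust, droplets, wrong-size
#'   particles), so that size filtering has work to do.
#' @param contaminant_diameter_range Diameter interval (nm) from which
#'   contaminant sizes are drawn (excluding the target band, by rejection).
#' @param multi_contaminant_fraction Contaminant-size probability for the
#'   constituents of multi-particle frames. Aggregates and debris are more
#'   heterogeneous than the injected virus population, which is what makes
#'   non-single admixture smear the fringes of a selection-averaged PSD;
#'   default 0.5.
#' @param empty_fraction Fraction of non-single frames that carry essentially
#'   no particle signal (weak/blank frames surviving hit finding); they belong
#'   to the non-single class.
#' @param saturation_level Detector full-well in photons/pixel; recorded
#'   counts clip here, as on a real pnCCD. Bounds the brightness of large
#'   contaminants, whose scattering grows with the particle volume squared.
#' @param seed Integer seed for dataset generation.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(particle_radius_range = c(27.5, 42),
                       single_fraction = 1 / 200,
                       fluence_jitter = 0.5,
                       mean_photon_scale = 2000,
                       background_level = 0.5,
                       multi_particle_count_range = c(2L, 4L),
                       displacement_range = c(100, 600),
                       contaminant_fraction = 0.2,
                       contaminant_diameter_range = c(30, 130),
                       multi_contaminant_fraction = 0.5,
                       empty_fraction = 0.1,
                       saturation_level = 10000,
                       seed = 1L) {
  stopifnot(length(particle_radius_range) == 2L)
  if (particle_radius_range[1] <= 0 ||
      particle_radius_range[1] >= particle_radius_range[2])
    stop("particle_radius_range must be a positive, ordered interval")
  if (single_fraction <= 0 || single_fraction >= 1)
    stop("single_fraction must lie strictly between 0 and 1")
  multi_particle_count_range <- as.integer(multi_particle_count_range)
  if (multi_particle_count_range[1] < 2L)
    stop("multi_particle_count_range minimum must be >= 2")
  stopifnot(fluence_jitter >= 0, mean_photon_scale >= 0, background_level >= 0,
            displacement_range[1] > 0,
            displacement_range[1] <= displacement_range[2],
            contaminant_fraction >= 0, contaminant_fraction < 1,
            multi_contaminant_fraction >= 0, multi_contaminant_fraction <= 1,
            empty_fraction >= 0, empty_fraction < 1, saturation_level > 0)
  structure(list(particle_radius_range = as.numeric(particle_radius_range),
                 single_fraction = single_fraction,
                 fluence_jitter = fluence_jitter,
                 mean_photon_scale = mean_photon_scale,
                 background_level = background_level,
                 multi_particle_count_range = multi_particle_count_range,
                 displacement_range = as.numeric(displacement_range),
                 contaminant_fraction = contaminant_fraction,
                 contaminant_diameter_range = as.numeric(contaminant_diameter_range),
                 multi_contaminant_fraction = multi_contaminant_fraction,
                 empty_fraction = empty_fraction,
                 saturation_level = saturation_level,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Sphere form-factor intensity
#'
#' Scattered intensity of a uniform sphere of radius R:
#' `I(q) = i0 * [3 (sin(qR) - qR cos(qR)) / (qR)^3]^2`, continuous at q = 0
#' with I(0) = i0. Zeros fall at the roots of tan(x) = x (x = 4.4934, 7.7253,
#' ...), which produce the concentric fringes characteristic of single-particle
#' diffraction.
#'
#' @param q Momentum transfer (nm^-1), any shape.
#' @param radius Sphere radius (nm), positive scalar.
#' @param i0 Forward-scattering intensity (photons).
#' @return Intensity with the shape of `q`.
#' @export
#' @examples
#' sphere_intensity(0, 35)                   # 1 at the origin
#' sphere_intensity(4.4934095 / 35, 35)      # first zero
sphere_intensity <- function(q, radius, i0 = 1) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("radius must be a positive scalar")
  stopifnot(all(q >= 0), i0 >= 0)
  i0 * sphere_amplitude(q, radius)^2
}

# normalized sphere amplitude F(qR) = 3 (sin u - u cos u)/u^3, F(0) = 1.
# Series expansion near u = 0 avoids 0/0.
sphere_amplitude <- function(q, radius) {
  u <- q * radius
  f <- numeric(length(u))
  small <- u < 1e-4
  f[small] <- 1 - u[small]^2 / 10
  ub <- u[!small]
  f[!small] <- 3 * (sin(ub) - ub * cos(ub)) / ub^3
  dim(f) <- dim(u)
  f
}

# In-plane q components (nm^-1) for coherent interference phases.
# q_vec = (2 pi / lambda) (s - s0) with s the unit direction to the pixel.
qxy_maps <- function(geometry) {
  shape <- geometry$shape
  x <- ((seq_len(shape[1]) - 1) - geometry$beam_center[1]) * geometry$pixel_size
  y <- ((seq_len(shape[2]) - 1) - geometry$beam_center[2]) * geometry$pixel_size
  X <- matrix(x, shape[1], shape[2])
  Y <- matrix(y, shape[1], shape[2], byrow = TRUE)
  nrm <- sqrt(X^2 + Y^2 + geometry$distance^2)
  k <- 2 * pi / geometry$wavelength
  list(qx = k * X / nrm, qy = k * Y / nrm)
}

# Noiseless coherent expectation of a frame holding particles of the given
# radii (nm) at in-plane positions (nm). Amplitudes scale with particle
# volume relative to the band-center reference radius.
frame_expectation <- function(config, geometry, radii, positions,
                              fluence = 1) {
  qm <- qmap(geometry)
  if (length(radii) == 0) {
    ex <- matrix(config$background_level, geometry$shape[1], geometry$shape[2])
    ex[!geometry$panel_mask] <- 0
    return(ex)
  }
  r_ref <- mean(config$particle_radius_range)
  amp_re <- matrix(0, geometry$shape[1], geometry$shape[2])
  amp_im <- matrix(0, geometry$shape[1], geometry$shape[2])
  qv <- qxy_maps(geometry)
  for (j in seq_along(radii)) {
    a <- sqrt(config$mean_photon_scale) * (radii[j] / r_ref)^3 *
      sphere_amplitude(qm, radii[j])
    ph <- qv$qx * positions[j, 1] + qv$qy * positions[j, 2]
    amp_re <- amp_re + a * cos(ph)
    amp_im <- amp_im + a * sin(ph)
  }
  ex <- fluence * (amp_re^2 + amp_im^2) + config$background_level
  ex[!geometry$panel_mask] <- 0
  ex
}

# Draw one particle radius (nm). Target particles follow a peaked
# (truncated-normal) law inside the band - an aerosolized virus population
# is close to monodisperse - while contaminants (probability
# `contaminant_fraction`, or `multi_contaminant_fraction` for the
# constituents of multi-particle frames) are uniform over the contaminant
# diameter range excluding the band.
draw_radius <- function(config, contaminant_p = config$contaminant_fraction) {
  if (stats::runif(1) < contaminant_p) {
    lo <- config$contaminant_diameter_range[1]
    hi <- config$contaminant_diameter_range[2]
    band <- 2 * config$particle_radius_range
    repeat {
      d <- stats::runif(1, lo, hi)
      if (d < band[1] || d > band[2]) return(d / 2)
    }
  }
  lo <- config$particle_radius_range[1]
  hi <- config$particle_radius_range[2]
  m <- (lo + hi) / 2
  s <- (hi - lo) / 8
  repeat {
    r <- stats::rnorm(1, m, s)
    if (r >= lo && r <= hi) return(r)
  }
}

#' Simulate one diffraction pattern
#'
#' Draws one labeled frame from the generator. A single hit is one sphere's
#' form-factor intensity times a fluence factor plus flat background; a
#' non-single hit is the squared modulus of the coherent sum of K >= 2 sphere
#' amplitudes at random in-plane displacements (interference fringes crossing
#' the form-factor rings), or - with probability `empty_fraction` - a
#' background-only blank. Each pixel is Poisson-sampled and dead-panel pixels
#' carry no signal.
#'
#' Uses the current R random-number stream; seed with `set.seed()` (or via
#' `generate_dataset()`) for reproducibility.
#'
#' @param config A `sim_config`.
#' @param geometry A `detector_geometry`.
#' @param is_single Logical: generate the single-hit class?
#' @param id Identifier for the resulting pattern.
#' @param noiseless If `TRUE`, return the noise-free expectation instead of a
#'   Poisson sample.
#' @param n_particles Optional override of the particle count for the
#'   non-single branch (testing hook; `1` with zero displacement reproduces
#'   the single-hit expectation).
#' @return List with `pattern` (a `diffraction_pattern`), `true_size_nm`
#'   (diameter, `NA` for non-single frames) and `label` (1 = single).
#' @export
simulate_pattern <- function(config, geometry, is_single, id = "sim",
                             noiseless = FALSE, n_particles = NULL) {
  stopifnot(inherits(config, "sim_config"),
            inherits(geometry, "detector_geometry"))
  fluence <- if (config$fluence_jitter > 0)
    stats::rlnorm(1, meanlog = -config$fluence_jitter^2 / 2,
                  sdlog = config$fluence_jitter)
  else 1
  if (is_single) {
    r <- draw_radius(config)
    radii <- r
    positions <- matrix(0, 1, 2)
    true_size <- 2 * r
  } else if (is.null(n_particles) && stats::runif(1) < config$empty_fraction) {
    radii <- numeric(0)
    positions <- matrix(0, 0, 2)
    true_size <- NA_real_
  } else {
    k <- if (!is.null(n_particles)) as.integer(n_particles)
    else sample(config$multi_particle_count_range[1]:
                  config$multi_particle_count_range[2], 1)
    radii <- vapply(seq_len(k), function(i)
      draw_radius(config, config$multi_contaminant_fraction), numeric(1))
    positions <- matrix(0, k, 2)
    if (k > 1) {
      mag <- stats::runif(k - 1, config$displacement_range[1],
                          config$displacement_range[2])
      ang <- stats::runif(k - 1, 0, 2 * pi)
      positions[-1, ] <- cbind(mag * cos(ang), mag * sin(ang))
    }
    true_size <- NA_real_
  }
  ex <- frame_expectation(config, geometry, radii, positions, fluence)
  intensity <- if (noiseless) pmin(ex, config$saturation_level) else {
    out <- matrix(0, geometry$shape[1], geometry$shape[2])
    live <- geometry$panel_mask
    out[live] <- pmin(stats::rpois(sum(live), ex[live]),
                      config$saturation_level)
    out
  }
  list(pattern = diffraction_pattern(intensity, geometry$panel_mask, id),
       true_size_nm = true_size,
       label = as.integer(is_single))
}

#' Generate a labeled synthetic dataset
#'
#' Draws exactly `n_single` single-hit and `n_nonsingle` non-single frames
#' from the generator, shuffles their order (seeded), and records ground-truth
#' labels and particle diameters. Repeated calls with the same config seed are
#' byte-identical.
#'
#' @param config A `sim_config` (its `seed` drives all randomness).
#' @param geometry A `detector_geometry`.
#' @param n_single,n_nonsingle Class counts (>= 0).
#' @return Object of class `labeled_dataset`: list with `patterns` (list of
#'   `diffraction_pattern`), `labels` (0/1 integer vector), `true_size_nm`
#'   (diameter, nm; `NA` for non-singles), `geometry`, `config`.
#' @export
#' @examples
#' g <- detector_geometry(shape = c(32, 32), pixel_size = 2.7e-4,
#'                        beam_center = c(15.5, 15.5))
#' ds <- generate_dataset(sim_config(seed = 7), g, n_single = 2,
#'                        n_nonsingle = 8)
#' table(ds$labels)
generate_dataset <- function(config, geometry, n_single, n_nonsingle) {
  stopifnot(inherits(config, "sim_config"), n_single >= 0, n_nonsingle >= 0)
  n <- n_single + n_nonsingle
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  labels <- sample(rep(c(1L, 0L), c(n_single, n_nonsingle)))
  patterns <- vector("list", n)
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    s <- simulate_pattern(config, geometry, labels[i] == 1L,
                          id = sprintf("sim_%06d", i))
    patterns[[i]] <- s$pattern
    sizes[i] <- s$true_size_nm
  }
  structure(list(patterns = patterns, labels = labels, true_size_nm = sizes,
                 geometry = geometry, config = config),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d patterns: %d single, %d non-single (%dx%d px)\n",
              length(x$patterns), sum(x$labels == 1L), sum(x$labels == 0L),
              x$geometry$shape[1], x$geometry$shape[2]))
  invisible(x)
}

# Save/restore the global RNG state so seeded generators do not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Draw hit-stream class labels
#'
#' Emulates the label sequence of an experimental hit stream: each frame is a
#' single hit independently with probability `config$single_fraction`
#' (default 1/200). Deterministic under the config seed.
#'
#' @param config A `sim_config`.
#' @param n Number of frames.
#' @return Integer 0/1 vector of length `n`.
#' @export
sample_hit_labels <- function(config, n) {
  stopifnot(inherits(config, "sim_config"), n >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  stats::rbinom(n, 1L, config$single_fraction)
}

#' Compact toy geometry for examples and scaled runs
#'
#' A reduced detector preserving the structure of the experimental setup
#' (same distance and wavelength, half-dead two-panel layout, beam center on
#' the live-panel edge) but with a coarser pixel pitch so that a 64 x 64 frame
#' spans several form-factor fringes of a 27.5-42 nm-radius particle.
#'
#' @param shape Frame shape; default `c(64, 64)`.
#' @param pixel_size Pixel pitch in metres; default 2.7e-4.
#' @param dead_lower_panel Mask out the lower half (default `TRUE`).
#' @return A `detector_geometry`.
#' @export
toy_geometry <- function(shape = c(64L, 64L), pixel_size = 2.7e-4,
                         dead_lower_panel = TRUE) {
  shape <- as.integer(shape)
  mask <- matrix(TRUE, shape[1], shape[2])
  if (dead_lower_panel) mask[(shape[1] %/% 2 + 1L):shape[1], ] <- FALSE
  detector_geometry(distance = 0.130, pixel_size = pixel_size,
                    wavelength = 0.729, shape = shape,
                    beam_center = c(shape[1] / 2 - 0.5, shape[2] / 2 - 0.5),
                    panel_mask = mask)
}
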