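#' Detector geometry
#'
#' Flat-detector geometry mapping pixels to momentum transfer. Defaults follow
#' a pnCCD mounted 0.130 m downstream of the interaction region, 75 um square
#' pixels, 1.7 keV photons (wavelength 0.729 nm), with two 512 x 1024 panels of
#' which only the upper one is live.
#'
#' Pixel grids are row-major with 0-based pixel indices; the beam center is in
#' fractional pixel coordinates `(row, col)`.
#'
#' @param distance Sample-detector distance in metres.
#' @param pixel_size Pixel pitch in metres.
#' @param wavelength Photon wavelength in nanometres.
#' @param beam_center Numeric length-2, fractional `(row, col)` of the direct
#'   beam.
#' @param shape Integer length-2 frame shape `(rows, cols)`.
#' @param panel_mask Logical matrix of `shape`, `TRUE` = live pixel. Default:
#'   upper half live, lower half dead (single working panel).
#' @return Object of class `detector_geometry`.
#' @export
#' @examples
#' g <- detector_geometry(shape = c(64, 64), pixel_size = 2.7e-4,
#'                        beam_center = c(31.5, 31.5))
detector_geometry <- function(distance = 0.130,
                              pixel_size = 75e-6,
                              wavelength = 0.729,
                              shape = c(1024L, 1024L),
                              beam_center = (shape - 1) / 2,
                              panel_mask = NULL) {
  if (distance <= 0) stop("distance must be positive")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (wavelength <= 0) stop("wavelength must be positive")
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape > 0L), length(beam_center) == 2L)
  if (is.null(panel_mask)) {
    panel_mask <- matrix(TRUE, shape[1], shape[2])
    if (shape[1] >= 2L)  # lower panel dead by default, as in the experiment
      panel_mask[(shape[1] %/% 2 + 1L):shape[1], ] <- FALSE
  }
  stopifnot(is.logical(panel_mask), all(dim(panel_mask) == shape))
  structure(list(distance = distance, pixel_size = pixel_size,
                 wavelength = wavelength, shape = shape,
                 beam_center = as.numeric(beam_center),
                 panel_mask = panel_mask),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(paste0("<detector_geometry> %dx%d px, pixel %.1f um, ",
                     "D = %.3f m, lambda = %.3f nm, center (%.1f, %.1f), ",
                     "%d/%d live px\n"),
              x$shape[1], x$shape[2], x$pixel_size * 1e6, x$distance,
              x$wavelength, x$beam_center[1], x$beam_center[2],
              sum(x$panel_mask), length(x$panel_mask)))
  invisible(x)
}

#' Per-pixel momentum-transfer map
#'
#' Magnitude of the scattering vector for each pixel,
#' q = (4 pi / lambda) sin(theta) with scattering angle
#' 2 theta = arctan(r * pixel_size / distance), r the radial distance from the
#' beam center in pixels. q = 0 at the beam center and grows monotonically
#' with radius.
#'
#' @param geometry A `detector_geometry`.
#' @param shape Optional frame shape override `(rows, cols)`.
#' @return Numeric matrix of q in inverse nanometres.
#' @export
qmap <- function(geometry, shape = geometry$shape) {
  stopifnot(inherits(geometry, "detector_geometry"))
  shape <- as.integer(shape)
  r <- pixel_radius(geometry, shape)
  two_theta <- atan(r * geometry$pixel_size / geometry$distance)
  (4 * pi / geometry$wavelength) * sin(two_theta / 2)
}

# radial pixel distance from the beam center (matrix)
pixel_radius <- function(geometry, shape = geometry$shape) {
  dr <- (seq_len(shape[1]) - 1) - geometry$beam_center[1]
  dc <- (seq_len(shape[2]) - 1) - geometry$beam_center[2]
  sqrt(outer(dr^2, dc^2, `+`))
}

#' Diffraction pattern
#'
#' One detector frame: photon-count grid, validity mask and an identifier.
#'
#' @param intensity Numeric matrix of photon counts.
#' @param mask Logical matrix, `TRUE` = valid pixel; defaults to all valid.
#' @param id Pattern identifier string.
#' @return Object of class `diffraction_pattern`.
#' @export
diffraction_pattern <- function(intensity, mask = NULL, id = "pattern") {
  stopifnot(is.matrix(intensity))
  storage.mode(intensity) <- "double"
  if (is.null(mask)) mask <- matrix(TRUE, nrow(intensity), ncol(intensity))
  stopifnot(is.logical(mask), all(dim(mask) == dim(intensity)))
  if (any(!is.finite(intensity[mask])))
    stop("non-finite intensity on valid pixels")
  structure(list(intensity = intensity, mask = mask, id = as.character(id)),
            class = "diffraction_pattern")
}

#' @export
print.diffraction_pattern <- function(x, ...) {
  cat(sprintf("<diffraction_pattern> %s: %dx%d px, %d valid, %.0f photons\n",
              x$id, nrow(x$intensity), ncol(x$intensity), sum(x$mask),
              sum(x$intensity[x$mask])))
  invisible(x)
}

#' Write / read a pattern archive
#'
#' Serializes a list of diffraction patterns plus shared mask, labels,
#' ground-truth sizes and geometry into the package's native single-file
#' container (named groups `patterns`, `mask`, `ids`, optional `labels`,
#' `true_size_nm`, `geometry`). Round trips are lossless. `read_patterns()`
#' validates the container and names any missing group in its error.
#'
#' @param patterns List of `diffraction_pattern` objects (may be empty).
#' @param path Output file path.
#' @param labels Optional binary labels, one per pattern.
#' @param true_size_nm Optional ground-truth diameters (nm), one per pattern.
#' @param geometry Optional `detector_geometry` stored alongside.
#' @return `path` invisibly for the writer; for the reader a list with
#'   `patterns`, `mask`, and any stored `labels`, `true_size_nm`, `geometry`.
#' @export
write_patterns <- function(patterns, path, labels = NULL,
                           true_size_nm = NULL, geometry = NULL) {
  stopifnot(is.list(patterns))
  stopifnot(all(vapply(patterns, inherits, logical(1), "diffraction_pattern")))
  n <- length(patterns)
  if (!is.null(labels)) stopifnot(length(labels) == n, all(labels %in% 0:1))
  if (!is.null(true_size_nm)) stopifnot(length(true_size_nm) == n)
  if (n > 0) {
    shp <- dim(patterns[[1]]$intensity)
    arr <- array(0, c(n, shp[1], shp[2]))
    for (i in seq_len(n)) arr[i, , ] <- patterns[[i]]$intensity
    mask <- patterns[[1]]$mask
  } else {
    arr <- array(0, c(0L, 0L, 0L))
    mask <- matrix(TRUE, 0L, 0L)
  }
  obj <- list(format = "spihits-patterns", version = 1L,
              patterns = arr, mask = mask,
              ids = vapply(patterns, function(p) p$id, character(1)),
              labels = labels, true_size_nm = true_size_nm,
              geometry = geometry)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "spihits-patterns"))
    stop("not a spihits pattern archive: ", path)
  for (grp in c("patterns", "mask", "ids"))
    if (is.null(obj[[grp]]))
      stop("pattern archive is missing required group '", grp, "'")
  n <- dim(obj$patterns)[1]
  pats <- vector("list", n)
  for (i in seq_len(n))
    pats[[i]] <- diffraction_pattern(obj$patterns[i, , , drop = TRUE],
                                     obj$mask, obj$ids[i])
  list(patterns = pats, mask = obj$mask, labels = obj$labels,
       true_size_nm = obj$true_size_nm, geometry = obj$geometry)
}

#' Crop a patch from a frame
#'
#' Extracts the rectangular region handed to the classifier (default
#' 192 x 96 pixels). Pixels that are masked invalid are zero-filled in the
#' returned patch.
#'
#' @param pattern A `diffraction_pattern`.
#' @param anchor Integer `(row, col)` offset of the patch's top-left corner,
#'   0-based.
#' @param size Integer `(rows, cols)` patch size; default `c(192, 96)`.
#' @return Numeric matrix of exactly `size` pixels.
#' @export
crop_patch <- function(pattern, anchor = c(0L, 0L), size = c(192L, 96L)) {
  stopifnot(inherits(pattern, "diffraction_pattern"))
  anchor <- as.integer(anchor); size <- as.integer(size)
  stopifnot(length(anchor) == 2L, length(size) == 2L, all(size > 0L))
  dims <- dim(pattern$intensity)
  if (any(anchor < 0L) || anchor[1] + size[1] > dims[1] ||
      anchor[2] + size[2] > dims[2])
    stop(sprintf("crop [%d:%d, %d:%d] out of bounds for a %dx%d frame",
                 anchor[1], anchor[1] + size[1], anchor[2], anchor[2] + size[2],
                 dims[1], dims[2]))
  rows <- (anchor[1] + 1L):(anchor[1] + size[1])
  cols <- (anchor[2] + 1L):(anchor[2] + size[2])
  patch <- pattern$intensity[rows, cols, drop = FALSE]
  patch[!pattern$mask[rows, cols, drop = FALSE]] <- 0
  patch
}

#' Default crop anchor on the live panel
#'
#' Places a patch of `size` on the live panel as close to the beam center as
#' the panel boundary allows: the highest-signal region available to the
#' classifier.
#'
#' @param geometry A `detector_geometry`.
#' @param size Patch size `(rows, cols)`.
#' @return Integer `(row, col)` anchor, 0-based.
#' @export
default_crop_anchor <- function(geometry, size = c(192L, 96L)) {
  stopifnot(inherits(geometry, "detector_geometry"))
  size <- as.integer(size)
  live <- which(geometry$panel_mask, arr.ind = TRUE)
  if (nrow(live) == 0) stop("geometry has no live pixels")
  rlim <- range(live[, 1]) - 1L  # 0-based live row span
  clim <- range(live[, 2]) - 1L
  want <- round(geometry$beam_center - size / 2)
  a1 <- min(max(want[1], rlim[1]), rlim[2] - size[1] + 1L)
  a2 <- min(max(want[2], clim[1]), clim[2] - size[2] + 1L)
  if (a1 < rlim[1] || a2 < clim[1])
    stop("patch does not fit inside the live panel")
  as.integer(c(a1, a2))
}

#' Normalization statistics
#'
#' Mean/standard-deviation pair used to standardize patches before the CNN.
#' Computed from a training set with [compute_norm_stats()]; the published
#' real-data values (mu = 0.342, sigma = 2.336) are available as defaults for
#' runs on the original experiment's frames.
#'
#' @param mu Intensity mean.
#' @param sigma Intensity standard deviation (> 0).
#' @return Object of class `norm_stats`.
#' @export
norm_stats <- function(mu = 0.342, sigma = 2.336) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma)),
            class = "norm_stats")
}

#' @export
print.norm_stats <- function(x, ...) {
  cat(sprintf("<norm_stats> mu = %.4g, sigma = %.4g\n", x$mu, x$sigma))
  invisible(x)
}

#' Compute normalization statistics from patches
#'
#' Pooled mean and standard deviation over a list (or array) of patches,
#' excluding masked pixels when a mask is given.
#'
#' @param patches List of numeric matrices, or a 3-d array `(n, rows, cols)`.
#' @param mask Optional logical matrix; `FALSE` pixels are excluded.
#' @return A `norm_stats`.
#' @export
compute_norm_stats <- function(patches, mask = NULL) {
  if (is.array(patches) && length(dim(patches)) == 3L)
    patches <- lapply(seq_len(dim(patches)[1]),
                      function(i) patches[i, , , drop = TRUE])
  vals <- unlist(lapply(patches, function(p) {
    if (is.null(mask)) as.numeric(p) else as.numeric(p[mask])
  }), use.names = FALSE)
  n <- length(vals)
  mu <- mean(vals)
  sigma <- sqrt(sum((vals - mu)^2) / n)  # population sd over the pooled pixels
  norm_stats(mu, sigma)
}

#' Standardize a patch
#'
#' Elementwise `(x - mu) / sigma` with the training-set statistics.
#'
#' @param patch Numeric matrix (or array).
#' @param stats A `norm_stats`.
#' @return Standardized patch, same shape.
#' @export
normalize_patch <- function(patch, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  if (stats$sigma <= 0) stop("sigma must be positive")
  (patch - stats$mu) / stats$sigma
}

#' Read / write geometry as a YAML block
#'
#' Geometry serialization for configuration files: fields `distance_m`,
#' `pixel_um`, `wavelength_nm`, `shape`, `center_xy` and an optional
#' `dead_lower_panel` flag regenerating the default two-panel mask.
#'
#' @param geometry A `detector_geometry`.
#' @param path YAML file path.
#' @return `path` invisibly; `read_geometry_yaml()` returns the geometry.
#' @export
write_geometry_yaml <- function(geometry, path) {
  stopifnot(inherits(geometry, "detector_geometry"))
  lower_dead <- !any(geometry$panel_mask[(geometry$shape[1] %/% 2 + 1L):
                                           geometry$shape[1], ])
  yaml::write_yaml(list(
    distance_m = geometry$distance,
    pixel_um = geometry$pixel_size * 1e6,
    wavelength_nm = geometry$wavelength,
    shape = as.integer(geometry$shape),
    center_xy = geometry$beam_center,
    dead_lower_panel = lower_dead
  ), path)
  invisible(path)
}

#' @rdname write_geometry_yaml
#' @export
read_geometry_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  req <- c("distance_m", "pixel_um", "wavelength_nm", "shape", "center_xy")
  miss <- setdiff(req, names(cfg))
  if (length(miss)) stop("geometry YAML is missing field(s): ",
                         paste(miss, collapse = ", "))
  shape <- as.integer(cfg$shape)
  mask <- NULL
  if (isFALSE(cfg$dead_lower_panel)) mask <- matrix(TRUE, shape[1], shape[2])
  detector_geometry(distance = cfg$distance_m, pixel_size = cfg$pixel_um * 1e-6,
                    wavelength = cfg$wavelength_nm, shape = shape,
                    beam_center = as.numeric(cfg$center_xy), panel_mask = mask)
}
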