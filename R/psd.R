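#' Angular-averaged intensity (PSD) curve
#'
#' Azimuthally averages frame intensity into q bins: for each bin the mean
#' over all valid pixels of all patterns in the selection. This angular
#' average - the power spectral density (PSD) function of a selection - is the
#' basis of fringe-contrast scoring and sphere-size estimation.
#'
#' @param patterns A `diffraction_pattern`, a list of them, or a
#'   `labeled_dataset`.
#' @param geometry A `detector_geometry` (taken from the dataset if omitted).
#' @param n_bins Number of linear q bins (default 200).
#' @param q_range Optional `c(min, max)` in nm^-1; defaults to the live-panel
#'   q range.
#' @param normalize_frames If `TRUE`, each frame is divided by its total
#'   valid-pixel intensity before averaging, so every pattern contributes
#'   equally regardless of pulse fluence or particle brightness. The default
#'   (`FALSE`) is the plain photon average.
#' @return Object of class `psd_curve`: list with `q_centers`, `intensity`
#'   (NA where a bin holds no valid pixel) and `occupancy` (valid-pixel count
#'   per bin, summed over patterns).
#' @export
compute_psd <- function(patterns, geometry = NULL, n_bins = 200,
                        q_range = NULL, normalize_frames = FALSE) {
  if (inherits(patterns, "labeled_dataset")) {
    if (is.null(geometry)) geometry <- patterns$geometry
    patterns <- patterns$patterns
  }
  if (inherits(patterns, "diffraction_pattern")) patterns <- list(patterns)
  stopifnot(is.list(patterns), inherits(geometry, "detector_geometry"))
  if (length(patterns) == 0) stop("empty selection: no patterns to average")
  qm <- qmap(geometry, dim(patterns[[1]]$intensity))
  if (is.null(q_range)) {
    qlive <- qm[geometry$panel_mask]
    q_range <- c(min(qlive), max(qlive))
  }
  edges <- seq(q_range[1], q_range[2], length.out = n_bins + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  sums <- numeric(n_bins)
  counts <- numeric(n_bins)
  for (p in patterns) {
    ok <- p$mask & qm >= q_range[1] & qm <= q_range[2]
    bi <- findInterval(qm[ok], edges, rightmost.closed = TRUE)
    bi[bi < 1L] <- 1L; bi[bi > n_bins] <- n_bins
    v <- p$intensity[ok]
    if (normalize_frames) {
      tot <- sum(v)
      if (tot > 0) v <- v / tot
    }
    part <- rowsum(v, bi)
    sums[as.integer(rownames(part))] <- sums[as.integer(rownames(part))] + part[, 1]
    counts <- counts + tabulate(bi, n_bins)
  }
  intensity <- ifelse(counts > 0, sums / counts, NA_real_)
  structure(list(q_centers = centers, intensity = intensity,
                 occupancy = counts),
            class = "psd_curve")
}

#' @export
print.psd_curve <- function(x, ...) {
  ok <- x$occupancy > 0
  cat(sprintf("<psd_curve> %d bins (%d occupied), q in [%.3g, %.3g] nm^-1\n",
              length(x$q_centers), sum(ok), min(x$q_centers), max(x$q_centers)))
  invisible(x)
}

#' @export
plot.psd_curve <- function(x, log = "y", ...) {
  ok <- x$occupancy > 0 & x$intensity > 0
  graphics::plot(x$q_centers[ok], x$intensity[ok], type = "l", log = log,
                 xlab = expression(q ~ (nm^-1)), ylab = "mean intensity", ...)
  invisible(x)
}

#' Export a PSD curve as CSV
#' @param x A `psd_curve`.
#' @param path Output path (columns `q_nm_inv`, `intensity`, `occupancy`).
#' @return `path`, invisibly.
#' @export
write_psd_csv <- function(x, path) {
  stopifnot(inherits(x, "psd_curve"))
  utils::write.csv(data.frame(q_nm_inv = x$q_centers, intensity = x$intensity,
                              occupancy = x$occupancy),
                   path, row.names = FALSE)
  invisible(path)
}

# Normalized curve on the requested scale: divide by the maximum, optionally
# log10. Returns q, y restricted to usable bins.
normalized_curve <- function(curve, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  ok <- curve$occupancy > 0 & is.finite(curve$intensity)
  if (scale == "log") ok <- ok & curve$intensity > 0
  q <- curve$q_centers[ok]
  y <- curve$intensity[ok] / max(curve$intensity[ok])
  if (scale == "log") y <- log10(y)
  list(q = q, y = y)
}

#' Alternating extrema of a PSD curve
#'
#' Detects local minima and maxima on the smoothed, normalized log-intensity
#' curve (Savitzky-Golay smoothing, default 7-bin window) and prunes
#' oscillations whose amplitude is below a prominence threshold (default 2%
#' of the curve's range). The result is a strictly alternating sequence
#' ordered by q, starting at the first interior extremum; a monotone curve
#' yields an empty result.
#'
#' @param curve A `psd_curve`.
#' @param smooth_window Odd Savitzky-Golay window length in bins (0 or 1
#'   disables smoothing).
#' @param min_prominence Minimum adjacent extremum-to-extremum amplitude,
#'   as a fraction of the curve's full range.
#' @param scale `"log"` (default) or `"linear"` normalized curve.
#' @return Data frame with columns `q`, `value`, `type` (`"min"`/`"max"`).
#' @export
find_extrema <- function(curve, smooth_window = 7, min_prominence = 0.02,
                         scale = c("log", "linear")) {
  stopifnot(inherits(curve, "psd_curve"))
  nc <- normalized_curve(curve, scale)
  y <- nc$y; q <- nc$q
  if (length(y) < 5) stop("need at least 5 usable bins")
  if (smooth_window > 1) {
    w <- min(smooth_window, length(y) - (1 - length(y) %% 2))
    if (w %% 2 == 0) w <- w - 1
    if (w >= 5) y <- signal::sgolayfilt(y, p = 2, n = w)
  }
  n <- length(y)
  d <- diff(y)
  s <- sign(d)
  # carry flat segments forward so plateaus register one extremum
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  idx <- integer(0); type <- character(0)
  for (i in seq_len(n - 2)) {
    if (s[i] > 0 && s[i + 1] < 0) { idx <- c(idx, i + 1L); type <- c(type, "max") }
    if (s[i] < 0 && s[i + 1] > 0) { idx <- c(idx, i + 1L); type <- c(type, "min") }
  }
  if (length(idx) == 0)
    return(data.frame(q = numeric(0), value = numeric(0),
                      type = character(0)))
  # prune low-amplitude adjacent pairs until all steps clear the threshold
  thr <- min_prominence * diff(range(y))
  repeat {
    if (length(idx) < 2) break
    amp <- abs(diff(y[idx]))
    k <- which.min(amp)
    if (amp[k] >= thr) break
    drop <- c(k, k + 1L)
    # keep the outer-more-extreme endpoint when it can merge with a neighbour
    idx <- idx[-drop]; type <- type[-drop]
    # restore alternation after the removal
    j <- 1L
    while (j < length(idx)) {
      if (type[j] == type[j + 1L]) {
        better <- if (type[j] == "max") which.max(y[idx[j:(j + 1L)]])
                  else which.min(y[idx[j:(j + 1L)]])
        rm_at <- j + (2L - better)
        idx <- idx[-rm_at]; type <- type[-rm_at]
      } else j <- j + 1L
    }
  }
  data.frame(q = q[idx], value = y[idx], type = type,
             stringsAsFactors = FALSE)
}

#' PSD fringe contrast
#'
#' Fringe-visibility score of a selection's PSD curve: the mean difference
#' between local maxima and their following local minima over the first
#' `n_pairs` pairs, `C = (1/N) sum_i (I_max,i - I_min,i)`, computed by
#' default on the normalized log10 curve (so the score is invariant to
#' multiplying all intensities by a constant). Purer single-hit selections
#' keep deeper form-factor fringes and score higher.
#'
#' @param curve A `psd_curve`.
#' @param n_pairs Number of maximum/minimum pairs to average (default 3).
#' @param scale `"log"` (default) or `"linear"`.
#' @param ... Passed to [find_extrema()].
#' @return Object of class `psd_contrast`: list with `contrast`, `n_pairs`,
#'   `maxima` and `minima` data frames (q, value).
#' @export
psd_contrast <- function(curve, n_pairs = 3, scale = c("log", "linear"), ...) {
  scale <- match.arg(scale)
  ext <- find_extrema(curve, scale = scale, ...)
  maxima <- ext[ext$type == "max", , drop = FALSE]
  pairs_max <- numeric(0); pairs_min <- numeric(0)
  q_max <- numeric(0); q_min <- numeric(0)
  for (i in seq_len(nrow(maxima))) {
    nxt <- ext[ext$type == "min" & ext$q > maxima$q[i], , drop = FALSE]
    if (nrow(nxt) == 0) break
    pairs_max <- c(pairs_max, maxima$value[i]); q_max <- c(q_max, maxima$q[i])
    pairs_min <- c(pairs_min, nxt$value[1]);   q_min <- c(q_min, nxt$q[1])
    if (length(pairs_max) == n_pairs) break
  }
  if (length(pairs_max) < n_pairs)
    stop(sprintf("contrast undefined: %d max/min pair(s) found, %d required",
                 length(pairs_max), n_pairs))
  structure(list(contrast = mean(pairs_max - pairs_min), n_pairs = n_pairs,
                 scale = scale,
                 maxima = data.frame(q = q_max, value = pairs_max),
                 minima = data.frame(q = q_min, value = pairs_min)),
            class = "psd_contrast")
}

#' @export
print.psd_contrast <- function(x, ...) {
  cat(sprintf("<psd_contrast> C = %.3f over %d pairs (%s scale)\n",
              x$contrast, x$n_pairs, x$scale))
  invisible(x)
}

#' Write a contrast report as JSON
#' @param x A `psd_contrast`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_contrast_json <- function(x, path) {
  stopifnot(inherits(x, "psd_contrast"))
  jsonlite::write_json(list(contrast = x$contrast, n_pairs = x$n_pairs,
                            scale = x$scale, maxima = x$maxima,
                            minima = x$minima),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Estimate particle size from a diffraction pattern
#'
#' Two standard sphere-size estimators from a per-pattern PSD curve:
#' \describe{
#'   \item{`form_factor_fit`}{Least-squares fit of the sphere intensity
#'     `s * F^2(qR) + b` (free radius, scale and flat background) to the
#'     angular average (default).}
#'   \item{`fringe_spacing`}{Mean spacing of successive PSD minima; since
#'     the form-factor zeros are asymptotically pi/R apart, the diameter is
#'     `2 pi / mean(delta q)`.}
#' }
#' When the fit fails it falls back to fringe spacing; when no fringes are
#' detectable the size is undetermined (`NA` diameter), which downstream
#' filtering treats as "drop", not as an error.
#'
#' @param x A `diffraction_pattern` or a per-pattern `psd_curve`.
#' @param geometry Required when `x` is a pattern.
#' @param method `"form_factor_fit"` (default) or `"fringe_spacing"`.
#' @param n_bins Bins for the per-pattern PSD when `x` is a pattern.
#' @return Object of class `size_estimate`: list with `diameter_nm`,
#'   `fit_residual`, `method`.
#' @export
estimate_size <- function(x, geometry = NULL,
                          method = c("form_factor_fit", "fringe_spacing"),
                          n_bins = 200) {
  method <- match.arg(method)
  curve <- if (inherits(x, "psd_curve")) x
           else compute_psd(x, geometry, n_bins = n_bins)
  fringe <- fringe_diameter(curve)
  if (method == "fringe_spacing")
    return(size_estimate(fringe$diameter, fringe$residual, "fringe_spacing"))
  fit <- form_factor_fit(curve, start_diameter = fringe$diameter)
  if (!is.na(fit$diameter))
    return(size_estimate(fit$diameter, fit$residual, "form_factor_fit"))
  size_estimate(fringe$diameter, fringe$residual, "fringe_spacing")
}

size_estimate <- function(diameter, residual, method) {
  if (is.na(diameter)) method <- "undetermined"
  structure(list(diameter_nm = diameter, fit_residual = residual,
                 method = method),
            class = "size_estimate")
}

#' @export
print.size_estimate <- function(x, ...) {
  if (is.na(x$diameter_nm)) cat("<size_estimate> undetermined\n")
  else cat(sprintf("<size_estimate> D = %.2f nm (%s)\n",
                   x$diameter_nm, x$method))
  invisible(x)
}

# Diameter from the spacing of successive minima; NA when fewer than 2
# minima. The median spacing is used: it is robust to an occasional missed
# shallow minimum, which would double one apparent spacing.
fringe_diameter <- function(curve) {
  ext <- tryCatch(find_extrema(curve), error = function(e) NULL)
  if (is.null(ext)) return(list(diameter = NA_real_, residual = NA_real_))
  mins <- ext$q[ext$type == "min"]
  if (length(mins) < 2) return(list(diameter = NA_real_, residual = NA_real_))
  dq <- diff(mins)
  m <- stats::median(dq)
  list(diameter = 2 * pi / m, residual = stats::mad(dq) / m)
}

# least-squares sphere form-factor fit on the linear curve
form_factor_fit <- function(curve, start_diameter = NA) {
  ok <- curve$occupancy > 0 & is.finite(curve$intensity)
  q <- curve$q_centers[ok]; I <- curve$intensity[ok]
  if (length(q) < 10) return(list(diameter = NA_real_, residual = NA_real_))
  starts <- if (is.na(start_diameter)) seq(30, 130, by = 10) else
    start_diameter * c(1, 0.9, 1.1)
  best <- NULL
  for (d0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        I ~ s * spihits::sphere_intensity(q, r, 1) + b,
        start = list(s = max(I), r = d0 / 2, b = max(min(I), 1e-6)),
        lower = c(s = 0, r = 5, b = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, r = stats::coef(fit)[["r"]])
  }
  if (is.null(best)) return(list(diameter = NA_real_, residual = NA_real_))
  list(diameter = 2 * best$r, residual = best$rss)
}

#' Filter a selection by estimated particle size
#'
#' Keeps pattern ids whose estimated diameter lies inside the inclusive band
#' `[low, high]` (default 55-84 nm, the expected virus size range). Ids with
#' undetermined sizes (`NA`) are dropped.
#'
#' @param sel A `selection`.
#' @param sizes Named numeric vector of diameters (nm) indexed by pattern id.
#' @param low,high Inclusive diameter bounds in nm.
#' @param name Name for the filtered selection; default appends `"+size"`.
#' @return A `selection`.
#' @export
size_filter <- function(sel, sizes, low = 55, high = 84,
                        name = paste0(sel$name, "+size")) {
  stopifnot(inherits(sel, "selection"))
  if (low > high) stop("invalid size range: low > high")
  d <- sizes[sel$ids]
  keep <- !is.na(d) & d >= low & d <= high
  selection(name, sel$ids[keep])
}

#' Background level from the high-q region
#'
#' Estimates the flat background of a frame or PSD curve as the mean signal in
#' a high-q region where particle scattering is negligible.
#'
#' @param x A `psd_curve` or a `diffraction_pattern`.
#' @param q_high_region `c(min, max)` in nm^-1.
#' @param geometry Required when `x` is a pattern.
#' @return Mean intensity over the region (photons/pixel).
#' @export
estimate_background <- function(x, q_high_region, geometry = NULL) {
  stopifnot(length(q_high_region) == 2L, q_high_region[1] < q_high_region[2])
  if (inherits(x, "psd_curve")) {
    sel <- x$q_centers >= q_high_region[1] & x$q_centers <= q_high_region[2] &
      x$occupancy > 0
    if (!any(sel)) stop("q_high_region holds no occupied bins")
    sum(x$intensity[sel] * x$occupancy[sel]) / sum(x$occupancy[sel])
  } else if (inherits(x, "diffraction_pattern")) {
    stopifnot(inherits(geometry, "detector_geometry"))
    qm <- qmap(geometry, dim(x$intensity))
    sel <- x$mask & qm >= q_high_region[1] & qm <= q_high_region[2]
    if (!any(sel)) stop("q_high_region holds no valid pixels")
    mean(x$intensity[sel])
  } else stop("x must be a psd_curve or diffraction_pattern")
}

#' Subtract a flat background from a frame
#'
#' Subtracts `level` from every valid pixel, clamping at zero.
#'
#' @param pattern A `diffraction_pattern`.
#' @param level Background level (photons/pixel).
#' @return A `diffraction_pattern`.
#' @export
subtract_background <- function(pattern, level) {
  stopifnot(inherits(pattern, "diffraction_pattern"), level >= 0)
  intensity <- pmax(pattern$intensity - level, 0)
  intensity[!pattern$mask] <- 0
  diffraction_pattern(intensity, pattern$mask, pattern$id)
}
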