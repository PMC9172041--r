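# Ensemble inference with mirror test-time augmentation.

# Mean single-hit probability over models x mirror variants.
# patches: array (n, H, W). Returns numeric vector length n.
predict_patches <- function(models, patches, tta_mirror = TRUE,
                            batch = 128L) {
  n <- dim(patches)[1]
  hw <- dim(patches)[2:3]
  variants <- if (tta_mirror) list(
    identity,
    function(p) p[hw[1]:1, , drop = FALSE],
    function(p) p[, hw[2]:1, drop = FALSE],
    function(p) p[hw[1]:1, hw[2]:1, drop = FALSE]
  ) else list(identity)
  probs <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    acc <- numeric(length(idx))
    for (v in variants) {
      xb <- array(0, c(hw[1], hw[2], 1L, length(idx)))
      for (m in seq_along(idx))
        xb[, , 1L, m] <- v(patches[idx[m], , , drop = TRUE])
      for (mod in models) {
        fw <- net_forward(mod, xb, train = FALSE)
        acc <- acc + softmax_cols(fw$logits)[2L, ]
      }
    }
    probs[idx] <- acc / (length(variants) * length(models))
  }
  probs
}

#' Ensemble prediction over a pattern set
#'
#' Averages the single-hit softmax probability over all ensemble members and
#' (optionally) the four mirror variants of each patch - none, horizontal,
#' vertical, both - for `5 x 4 = 20` predictions per pattern with the default
#' five-member ensemble. A pattern is labeled single iff the averaged
#' probability strictly exceeds `threshold`; an exact tie at the threshold is
#' conservatively labeled non-single.
#'
#' @param ensemble A `hit_ensemble` from [hit_classifier()].
#' @param patterns A `labeled_dataset` or list of `diffraction_pattern`s.
#' @param geometry Geometry, when `patterns` is a bare list.
#' @param tta_mirror Use mirror test-time augmentation (default `TRUE`).
#' @param threshold Decision threshold (default 0.5).
#' @return Data frame with columns `id`, `probability`, `label`.
#' @export
ensemble_predict <- function(ensemble, patterns, geometry = NULL,
                             tta_mirror = TRUE, threshold = 0.5) {
  stopifnot(inherits(ensemble, "hit_ensemble"))
  if (inherits(patterns, "labeled_dataset")) {
    geometry <- patterns$geometry
    patterns <- patterns$patterns
  }
  stopifnot(is.list(patterns), inherits(geometry, "detector_geometry"))
  ds <- list(patterns = patterns, geometry = geometry)
  prep <- extract_patches(ds, ensemble$input_size, ensemble$anchor,
                          stats = ensemble$stats)
  probs <- predict_patches(ensemble$members, prep$patches, tta_mirror)
  data.frame(id = vapply(patterns, function(p) p$id, character(1)),
             probability = probs,
             label = as.integer(probs > threshold),
             stringsAsFactors = FALSE)
}

#' Single-model prediction without test-time augmentation
#'
#' The fast path: one forward pass per pattern through one ensemble member.
#'
#' @param model A `hit_cnn`, or a `hit_ensemble` (its first member is used).
#' @param patches Array `(n, rows, cols)` of standardized patches.
#' @return Numeric vector of single-hit probabilities.
#' @export
predict_single_model <- function(model, patches) {
  if (inherits(model, "hit_ensemble")) model <- model$members[[1]]
  stopifnot(inherits(model, "hit_cnn"))
  predict_patches(list(model), patches, tta_mirror = FALSE)
}

#' @describeIn hit_classifier Predict single-hit probabilities and labels for
#'   new patterns. `newdata` is a `labeled_dataset` or pattern list;
#'   `type = "selection"` returns the predicted single hits as a
#'   [selection()].
#' @param object A `hit_ensemble`.
#' @param newdata Patterns to classify.
#' @param geometry Geometry when `newdata` is a bare pattern list.
#' @param tta_mirror Mirror test-time augmentation (default `TRUE`).
#' @param threshold Decision threshold (default 0.5).
#' @param type `"response"` (data frame) or `"selection"`.
#' @param name Selection name for `type = "selection"`.
#' @param ... Unused.
#' @export
predict.hit_ensemble <- function(object, newdata, geometry = NULL,
                                 tta_mirror = TRUE, threshold = 0.5,
                                 type = c("response", "selection"),
                                 name = "predicted", ...) {
  type <- match.arg(type)
  res <- ensemble_predict(object, newdata, geometry, tta_mirror, threshold)
  if (type == "response") return(res)
  selection(name, res$id[res$label == 1L])
}

#' @export
print.hit_ensemble <- function(x, ...) {
  cat(sprintf("<hit_ensemble> %d members, %dx%d input, stats mu=%.4g sigma=%.4g\n",
              length(x$members), x$input_size[1], x$input_size[2],
              x$stats$mu, x$stats$sigma))
  cat(sprintf("  cross-validation F1 %.3f +/- %.3f\n",
              mean(x$val_metrics[, "f1"]), stats::sd(x$val_metrics[, "f1"])))
  invisible(x)
}

#' @describeIn hit_classifier Per-fold validation metrics reported as
#'   mean +/- sd over folds.
#' @export
summary.hit_ensemble <- function(object, ...) {
  m <- object$val_metrics
  out <- data.frame(
    metric = c("f1", "precision", "recall", "predicted_singles"),
    mean = c(mean(m[, "f1"]), mean(m[, "precision"]), mean(m[, "recall"]),
             sum(m[, "predicted_singles"])),
    sd = c(stats::sd(m[, "f1"]), stats::sd(m[, "precision"]),
           stats::sd(m[, "recall"]), NA)
  )
  class(out) <- c("summary.hit_ensemble", "data.frame")
  out
}

#' @export
print.summary.hit_ensemble <- function(x, ...) {
  cat("Cross-validation metrics (mean +/- sd over folds):\n")
  for (i in seq_len(nrow(x))) {
    if (x$metric[i] == "predicted_singles")
      cat(sprintf("  predicted single hits: %d\n", as.integer(x$mean[i])))
    else
      cat(sprintf("  %-9s %.3f +/- %.3f\n", x$metric[i], x$mean[i], x$sd[i]))
  }
  invisible(x)
}

#' @export
plot.hit_ensemble <- function(x, ...) {
  traces <- x$loss
  ylim <- range(unlist(traces))
  graphics::plot(NULL, xlim = c(1, length(traces[[1]])), ylim = ylim,
                 xlab = "epoch", ylab = "mean training loss", ...)
  for (f in seq_along(traces))
    graphics::lines(seq_along(traces[[f]]), traces[[f]], col = f)
  graphics::legend("topright", legend = paste("fold", seq_along(traces)),
                   col = seq_along(traces), lty = 1, bty = "n")
  invisible(x)
}

#' Write predictions as CSV
#' @param predictions Data frame from [ensemble_predict()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a selection as a JSON id list
#' @param sel A `selection`.
#' @param path JSON path.
#' @return `path` invisibly; the reader returns a `selection`.
#' @export
write_selection_json <- function(sel, path) {
  stopifnot(inherits(sel, "selection"))
  jsonlite::write_json(list(name = sel$name, ids = sel$ids), path,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_selection_json
#' @export
read_selection_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  selection(obj$name, obj$ids)
}
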