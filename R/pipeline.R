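#' Assemble a pipeline run configuration
#'
#' Bundles every stage's configuration for [run_pipeline()]: geometry,
#' simulation, training, inference, PSD and size-filter settings plus the
#' master seed, with validation up front so misconfiguration fails before any
#' compute. Can be loaded from a YAML file with [read_run_config()].
#'
#' @param geometry A `detector_geometry`.
#' @param sim A `sim_config`.
#' @param model A `model_config`.
#' @param train A `train_config`.
#' @param n_train_single,n_train_nonsingle Training-set class counts.
#' @param n_test_single,n_test_nonsingle Test-set class counts.
#' @param threshold Decision threshold.
#' @param tta_mirror Mirror test-time augmentation flag.
#' @param psd_bins PSD q-bin count.
#' @param psd_pairs Contrast pairs N.
#' @param psd_scale `"log"` or `"linear"` contrast scale.
#' @param size_low,size_high Size-filter band (nm).
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Output directory for artifacts (`NULL` = no files).
#' @return Object of class `run_config`.
#' @export
run_config <- function(geometry, sim = sim_config(), model = model_config(),
                       train = train_config(),
                       n_train_single = 100L, n_train_nonsingle = 19900L,
                       n_test_single = 100L, n_test_nonsingle = 1900L,
                       threshold = 0.5, tta_mirror = TRUE,
                       psd_bins = 200L, psd_pairs = 3L, psd_scale = "log",
                       size_low = 55, size_high = 84,
                       seed = 1L, out_dir = NULL) {
  if (missing(geometry) || !inherits(geometry, "detector_geometry"))
    stop("run_config requires a detector_geometry")
  stopifnot(inherits(sim, "sim_config"), inherits(model, "model_config"),
            inherits(train, "train_config"))
  if (size_low > size_high) stop("invalid size band: size_low > size_high")
  structure(list(geometry = geometry, sim = sim, model = model, train = train,
                 n_train_single = as.integer(n_train_single),
                 n_train_nonsingle = as.integer(n_train_nonsingle),
                 n_test_single = as.integer(n_test_single),
                 n_test_nonsingle = as.integer(n_test_nonsingle),
                 threshold = threshold, tta_mirror = tta_mirror,
                 psd_bins = as.integer(psd_bins),
                 psd_pairs = as.integer(psd_pairs), psd_scale = psd_scale,
                 size_low = size_low, size_high = size_high,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full synthetic classification workflow
#'
#' Executes the stages in order: simulate training and test sets, fit the
#' cross-validated ensemble, predict on the test set, estimate particle sizes
#' for the predicted singles, size-filter the selection, and compare the
#' resulting selections (predicted, size-filtered, ground truth) by
#' intersection-over-union and PSD contrast. All randomness derives from
#' `config$seed`; re-running the same config reproduces the selections
#' exactly. When `out_dir` is set, artifacts (predictions CSV, selection
#' JSONs, PSD CSVs, comparison CSV, run metadata) are written there.
#'
#' @param config A `run_config`.
#' @param verbose Print stage progress (default `TRUE`).
#' @return Object of class `pipeline_result`: list with the trained
#'   `ensemble`, `predictions`, selections, comparison matrix, PSD contrasts,
#'   test-set `metrics` and the `config`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed

  say("[simulate] training set: %d single / %d non-single",
      config$n_train_single, config$n_train_nonsingle)
  sim_tr <- config$sim; sim_tr$seed <- seed
  train_ds <- generate_dataset(sim_tr, config$geometry,
                               config$n_train_single,
                               config$n_train_nonsingle)
  say("[simulate] test set: %d single / %d non-single",
      config$n_test_single, config$n_test_nonsingle)
  sim_te <- config$sim; sim_te$seed <- seed + 1000L
  test_ds <- generate_dataset(sim_te, config$geometry,
                              config$n_test_single, config$n_test_nonsingle)

  say("[train] %d folds x %d iterations", config$train$n_folds,
      config$train$epochs * config$train$iterations_per_epoch)
  tr <- config$train; tr$seed <- seed
  ensemble <- hit_classifier(train_ds, config$model, tr)

  say("[predict] %d test patterns (tta=%s)", length(test_ds$patterns),
      config$tta_mirror)
  preds <- ensemble_predict(ensemble, test_ds, tta_mirror = config$tta_mirror,
                            threshold = config$threshold)
  ids <- preds$id
  sel_pred <- selection("predicted", ids[preds$label == 1L])
  sel_truth <- selection("truth", ids[test_ds$labels == 1L])
  met <- precision_recall_f1(confusion_counts(test_ds$labels, preds$label))

  say("[size] estimating sizes for %d predicted singles", length(sel_pred))
  sizes <- rep(NA_real_, length(sel_pred$ids))
  names(sizes) <- sel_pred$ids
  lookup <- match(sel_pred$ids, ids)
  for (i in seq_along(lookup)) {
    est <- estimate_size(test_ds$patterns[[lookup[i]]], config$geometry,
                         n_bins = config$psd_bins)
    sizes[i] <- est$diameter_nm
  }
  sel_size <- size_filter(sel_pred, sizes, config$size_low, config$size_high)

  say("[compare] IoU matrix + PSD contrast")
  sels <- list(sel_pred, sel_size, sel_truth)
  cmp <- comparison_matrix(sels)
  psd_contrasts <- lapply(sels, function(s) {
    if (length(s) == 0) return(NULL)
    curve <- compute_psd(test_ds$patterns[match(s$ids, ids)],
                         config$geometry, n_bins = config$psd_bins)
    tryCatch(psd_contrast(curve, config$psd_pairs, scale = config$psd_scale),
             error = function(e) NULL)
  })
  names(psd_contrasts) <- vapply(sels, function(s) s$name, character(1))

  result <- structure(list(ensemble = ensemble, predictions = preds,
                           selection_predicted = sel_pred,
                           selection_size_filtered = sel_size,
                           selection_truth = sel_truth,
                           sizes_nm = sizes, comparison = cmp,
                           psd_contrasts = psd_contrasts, metrics = met,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  test metrics: P=%.3f R=%.3f F1=%.3f\n",
              x$metrics["precision"], x$metrics["recall"], x$metrics["f1"]))
  cat(sprintf("  predicted singles: %d (size-filtered: %d; truth: %d)\n",
              length(x$selection_predicted), length(x$selection_size_filtered),
              length(x$selection_truth)))
  for (nm in names(x$psd_contrasts))
    if (!is.null(x$psd_contrasts[[nm]]))
      cat(sprintf("  PSD contrast [%s]: %.3f\n", nm,
                  x$psd_contrasts[[nm]]$contrast))
  invisible(x)
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_predictions_csv(result$predictions,
                        file.path(out_dir, "predictions.csv"))
  write_selection_json(result$selection_predicted,
                       file.path(out_dir, "selection_predicted.json"))
  write_selection_json(result$selection_size_filtered,
                       file.path(out_dir, "selection_size_filtered.json"))
  write_comparison_csv(result$comparison, file.path(out_dir, "comparison.csv"))
  meta <- list(seed = result$config$seed,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               metrics = as.list(result$metrics))
  jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file with blocks `geometry`, `sim`, `model`, `train`,
#' `inference`, `psd`, `size`, `data` and `seed`; absent blocks fall back to
#' package defaults, a missing geometry block is an error.
#'
#' @param path YAML config path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$geometry)) stop("config is missing the geometry block")
  g <- cfg$geometry
  geometry <- detector_geometry(
    distance = g$distance_m %||% 0.130,
    pixel_size = (g$pixel_um %||% 75) * 1e-6,
    wavelength = g$wavelength_nm %||% 0.729,
    shape = as.integer(g$shape %||% c(1024L, 1024L)),
    beam_center = as.numeric(g$center_xy %||%
                               ((as.integer(g$shape %||% 1024L) - 1) / 2)))
  sim <- do.call(sim_config, cfg$sim %||% list())
  model <- do.call(model_config, cfg$model %||% list())
  train <- do.call(train_config, cfg$train %||% list())
  inf <- cfg$inference %||% list()
  psd <- cfg$psd %||% list()
  size <- cfg$size %||% list()
  dat <- cfg$data %||% list()
  run_config(geometry = geometry, sim = sim, model = model, train = train,
             n_train_single = dat$n_train_single %||% 100L,
             n_train_nonsingle = dat$n_train_nonsingle %||% 19900L,
             n_test_single = dat$n_test_single %||% 100L,
             n_test_nonsingle = dat$n_test_nonsingle %||% 1900L,
             threshold = inf$threshold %||% 0.5,
             tta_mirror = inf$tta %||% TRUE,
             psd_bins = psd$bins %||% 200L,
             psd_pairs = psd$n_pairs %||% 3L,
             psd_scale = psd$scale %||% "log",
             size_low = size$low %||% 55, size_high = size$high %||% 84,
             seed = cfg$seed %||% 1L, out_dir = cfg$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
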