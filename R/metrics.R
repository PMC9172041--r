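#' Confusion counts from binary labels and predictions
#'
#' Tallies true/false positives and negatives for the single-hit (positive)
#' class.
#'
#' @param truth Binary vector of ground-truth labels (1 = single hit).
#' @param predicted Binary vector of predicted labels, same length.
#' @return An object of class `confusion_counts`: a list with integer fields
#'   `TP`, `FP`, `FN`, `TN`.
#' @export
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
confusion_counts <- function(truth, predicted) {
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  stopifnot(length(truth) == length(predicted))
  if (!all(truth %in% c(0L, 1L)) || !all(predicted %in% c(0L, 1L)))
    stop("labels must be binary (0 = non-single, 1 = single)")
  out <- list(
    TP = sum(truth == 1L & predicted == 1L),
    FP = sum(truth == 0L & predicted == 1L),
    FN = sum(truth == 1L & predicted == 0L),
    TN = sum(truth == 0L & predicted == 0L)
  )
  structure(out, class = "confusion_counts")
}

#' Precision, recall and F1 score
#'
#' Standard binary-classification metrics for the single-hit class:
#' P = TP/(TP+FP), R = TP/(TP+FN) and the F1 score, their harmonic mean
#' 2PR/(P+R). Under the heavy class imbalance typical of single-particle
#' imaging (roughly one single hit per two hundred frames) the F1 score is
#' the model-selection criterion of choice.
#'
#' Degenerate denominators follow the zero convention: precision (or recall)
#' is 0 when its denominator is 0, and F1 is 0 when P + R = 0.
#'
#' @param counts A `confusion_counts` object, or anything coercible via
#'   `confusion_counts()` when `predicted` is also given.
#' @param predicted Optional predicted labels; if supplied, `counts` is
#'   interpreted as the truth vector.
#' @return Named numeric vector with elements `precision`, `recall`, `f1`.
#' @export
#' @examples
#' precision_recall_f1(confusion_counts(c(1, 1, 0), c(1, 0, 0)))
precision_recall_f1 <- function(counts, predicted = NULL) {
  if (!is.null(predicted)) counts <- confusion_counts(counts, predicted)
  if (!inherits(counts, "confusion_counts"))
    counts <- structure(as.list(counts)[c("TP", "FP", "FN", "TN")],
                        class = "confusion_counts")
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' F1 score from precision and recall
#'
#' Harmonic mean of an already-computed precision/recall pair, as used when
#' working from published tables rather than raw counts.
#'
#' @param precision,recall Numeric scalars in \[0, 1\].
#' @return The F1 score.
#' @export
f1_score <- function(precision, recall) {
  stopifnot(precision >= 0, recall >= 0, precision <= 1, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Named selection of diffraction-pattern identifiers
#'
#' A `selection` is a named set of pattern identifiers (for example the frames
#' a classifier predicts to be single hits). Identifiers are de-duplicated and
#' stored as character.
#'
#' @param name Label for the selection.
#' @param ids Vector of pattern identifiers.
#' @return An object of class `selection` with fields `name` and `ids`.
#' @export
selection <- function(name, ids) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  ids <- unique(as.character(ids))
  structure(list(name = name, ids = ids), class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("<selection> %s: %d patterns\n", x$name, length(x$ids)))
  invisible(x)
}

#' @export
length.selection <- function(x) length(x$ids)

#' Intersection-over-union of two selections
#'
#' The overlap coefficient alpha = 100 |A intersect B| / |A union B|, in
#' percent, used to compare single-hit selections produced by different
#' classification routes. Callable either on two `selection` objects (the
#' intersection is computed from the id sets) or on raw set sizes plus an
#' intersection count.
#'
#' @param a,b Two `selection` objects, or two integer set sizes.
#' @param intersection Intersection count, required in the size form.
#' @return `alpha` in percent (full precision; round for table display).
#' @export
#' @examples
#' iou(selection("x", 1:4), selection("y", 3:6))   # 33.33...
#' iou(1098, 1085, 575)                            # Table-style size form
iou <- function(a, b, intersection = NULL) {
  if (inherits(a, "selection") && inherits(b, "selection")) {
    inter <- length(intersect(a$ids, b$ids))
    uni <- length(union(a$ids, b$ids))
  } else {
    stopifnot(is.numeric(a), is.numeric(b), !is.null(intersection))
    if (intersection > min(a, b))
      stop("intersection count exceeds the smaller set size")
    inter <- intersection
    uni <- a + b - intersection
  }
  if (uni == 0) stop("intersection-over-union is undefined for two empty sets")
  100 * inter / uni
}

#' Pairwise comparison matrix of selections
#'
#' For every pair of selections computes the intersection count and the
#' intersection-over-union alpha (percent). The result mirrors the layout of
#' published selection-comparison tables: a symmetric matrix with the set
#' sizes on the diagonal and 100% self-overlap.
#'
#' @param selections A list of `selection` objects with distinct names.
#' @return An object of class `selection_comparison`: list with `names`,
#'   `sizes`, integer matrix `counts` and numeric matrix `alpha` (percent).
#' @export
comparison_matrix <- function(selections) {
  stopifnot(is.list(selections), length(selections) >= 2L)
  stopifnot(all(vapply(selections, inherits, logical(1), "selection")))
  nm <- vapply(selections, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate selection names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  k <- length(selections)
  counts <- matrix(0L, k, k, dimnames = list(nm, nm))
  alpha <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    inter <- length(intersect(selections[[i]]$ids, selections[[j]]$ids))
    counts[i, j] <- inter
    # two empty sets have no defined overlap; recorded as NA in the matrix
    alpha[i, j] <- if (length(union(selections[[i]]$ids,
                                    selections[[j]]$ids)) == 0)
      NA_real_ else iou(selections[[i]], selections[[j]])
  }
  structure(list(names = nm,
                 sizes = vapply(selections, length, integer(1)),
                 counts = counts, alpha = alpha),
            class = "selection_comparison")
}

#' @export
print.selection_comparison <- function(x, digits = 0, ...) {
  cat("Selection comparison (intersection counts / alpha %):\n")
  k <- length(x$names)
  lab <- sprintf("%s (%d)", x$names, x$sizes)
  disp <- matrix("", k, k, dimnames = list(lab, lab))
  for (i in seq_len(k)) for (j in seq_len(k))
    disp[i, j] <- sprintf("%d / %s", x$counts[i, j],
                          fmt_alpha(x$alpha[i, j]))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Export a comparison matrix as CSV
#'
#' Writes one count row and one nearest-integer percentage row per selection,
#' following the conventional published layout.
#'
#' @param x A `selection_comparison`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(x, path) {
  stopifnot(inherits(x, "selection_comparison"))
  k <- length(x$names)
  rows <- vector("list", 2L * k)
  for (i in seq_len(k)) {
    rows[[2L * i - 1L]] <- c(sprintf("%s (%d)", x$names[i], x$sizes[i]),
                             as.character(x$counts[i, ]))
    rows[[2L * i]] <- c("", vapply(x$alpha[i, ], fmt_alpha, character(1)))
  }
  header <- c("selection", sprintf("%s (%d)", x$names, x$sizes))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  for (r in rows) writeLines(paste(r, collapse = ","), con)
  invisible(path)
}

# nearest-integer percent for table display; NA stays "NA"
fmt_alpha <- function(a) if (is.na(a)) "NA" else sprintf("%d%%", round(a))

#' Intersection-over-union across several selections
#'
#' Generalizes the pairwise alpha to k >= 2 selections:
#' alpha = 100 |intersection of all| / |union of all|.
#'
#' @param selections List of `selection` objects.
#' @return List with `count` (size of the common intersection) and `alpha`
#'   (percent).
#' @export
multiway_intersection <- function(selections) {
  stopifnot(is.list(selections), length(selections) >= 2L)
  stopifnot(all(vapply(selections, inherits, logical(1), "selection")))
  ids <- lapply(selections, function(s) s$ids)
  inter <- Reduce(intersect, ids)
  uni <- Reduce(union, ids)
  if (length(uni) == 0)
    stop("intersection-over-union is undefined when all sets are empty")
  list(count = length(inter), alpha = 100 * length(inter) / length(uni))
}

#' Train/test partition bookkeeping
#'
#' Given the total number of detector hits, the number of annotated single
#' hits among them, and the portion reserved for training, returns the
#' composition of the held-out test partition. Used to document how an
#' experiment's hit list splits into the training and evaluation sets.
#'
#' @param n_hits Total frames surviving hit finding.
#' @param n_singles Ground-truth single hits among them.
#' @param n_train Training frames (singles + non-singles).
#' @param n_train_singles Single hits allocated to training.
#' @return Named integer vector: `test_total`, `test_singles`,
#'   `test_nonsingles`, `train_nonsingles`.
#' @export
#' @examples
#' split_counts(191183, 1393, 20000, 100)
split_counts <- function(n_hits, n_singles, n_train, n_train_singles) {
  stopifnot(n_train <= n_hits, n_train_singles <= min(n_singles, n_train))
  test_total <- n_hits - n_train
  test_singles <- n_singles - n_train_singles
  c(test_total = test_total,
    test_singles = test_singles,
    test_nonsingles = test_total - test_singles,
    train_nonsingles = n_train - n_train_singles)
}
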