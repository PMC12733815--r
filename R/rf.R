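#' Train the random-forest refinement classifier
#'
#' A 100-tree random forest over the geometry features ([rf_features()])
#' that separates residual noise (class 0), single oysters (class 1) and
#' fused pairs (class 2) after measurement. The seed defaults to 42 so runs
#' are reproducible; tree construction otherwise uses the standard forest
#' defaults (Gini impurity, unlimited depth, bootstrap sampling).
#'
#' @param features data.frame with columns `pct_large`, `pct_width`,
#'   `pct_p1X`, `pct_p1Y`, `pct_p2X`, `pct_p2Y`.
#' @param class integer labels in \{0, 1, 2\}; at least two classes needed.
#' @param seed random seed; default 42.
#' @param ntree number of trees; default 100.
#' @return An `rf_refiner` wrapping the forest, with training accuracy and
#'   confusion matrix in `$meta`.
#' @export
train_rf <- function(features, class, seed = 42L, ntree = 100L) {
  x <- features[, c("pct_large", "pct_width", "pct_p1X", "pct_p1Y",
                    "pct_p2X", "pct_p2Y")]
  stopifnot(nrow(x) == length(class), all(is.finite(as.matrix(x))))
  levels <- sort(unique(as.integer(class)))
  if (length(levels) < 2L)
    stop("training data contains a single class (", levels,
         "); a classifier needs at least two")
  y <- factor(as.integer(class), levels = levels)
  set.seed(seed)
  forest <- randomForest::randomForest(x, y, ntree = ntree)
  pred <- as.integer(as.character(predict(forest, x)))
  structure(
    list(forest = forest, class_levels = levels,
         meta = list(seed = seed, ntree = ntree,
                     train_accuracy = mean(pred == as.integer(class)),
                     confusion = table(truth = as.integer(class),
                                       predicted = pred))),
    class = "rf_refiner")
}

#' @export
print.rf_refiner <- function(x, ...) {
  cat(sprintf("<rf_refiner %d trees, seed %d, train accuracy %.3f>\n",
              x$meta$ntree, x$meta$seed, x$meta$train_accuracy))
  invisible(x)
}

#' Predict refinement classes
#'
#' @param object an `rf_refiner`.
#' @param newdata geometry-feature rows ([rf_features()]).
#' @param ... unused.
#' @return Integer class labels.
#' @export
predict.rf_refiner <- function(object, newdata, ...) {
  x <- newdata[, c("pct_large", "pct_width", "pct_p1X", "pct_p1Y",
                   "pct_p2X", "pct_p2Y")]
  as.integer(as.character(predict(object$forest, x)))
}

#' Refine measurements: drop noise, split fused pairs
#'
#' Applies the refinement forest to measured groups. Class-0 groups are
#' dropped; class-1 groups are kept unchanged; each class-2 group (a fused
#' pair) is replaced by two measurement records whose length is half the
#' fused length along the longest dimension, width unchanged -- the split is
#' a bookkeeping operation on the measurement (no pixel re-segmentation),
#' whose purpose is to stop fused pairs from inflating the sample average.
#' Output order follows input order; split members carry the fused group's
#' id in `source_id`.
#'
#' @param model an `rf_refiner`.
#' @param measures measurement rows ([measure_groups()]), aligned 1:1 with
#'   `features`.
#' @param features geometry-feature rows for the same groups.
#' @return A data.frame with `id`, `length_mm`, `width_mm`, `final_class`
#'   (`"1"` or `"2-split"`) and `source_id`.
#' @export
refine <- function(model, measures, features) {
  stopifnot(nrow(measures) == nrow(features))
  empty <- data.frame(id = integer(), length_mm = numeric(),
                      width_mm = numeric(), final_class = character(),
                      source_id = integer())
  if (nrow(measures) == 0L) return(empty)
  cls <- predict(model, features)
  rows <- vector("list", nrow(measures))
  next_id <- max(measures$id) + 1L
  for (i in seq_len(nrow(measures))) {
    m <- measures[i, ]
    if (cls[i] == 0L) next
    if (cls[i] == 1L) {
      rows[[i]] <- data.frame(id = m$id, length_mm = m$length_mm,
                              width_mm = m$width_mm, final_class = "1",
                              source_id = m$id)
    } else {
      rows[[i]] <- data.frame(id = c(next_id, next_id + 1L),
                              length_mm = rep(m$length_mm / 2, 2L),
                              width_mm = rep(m$width_mm, 2L),
                              final_class = "2-split",
                              source_id = m$id)
      next_id <- next_id + 2L
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
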