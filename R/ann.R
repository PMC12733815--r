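#' Train the multilayer-perceptron group filter
#'
#' A small fully connected network (3 inputs -> 100 ReLU hidden units -> 3
#' softmax outputs) trained with full-batch Adam on categorical
#' cross-entropy for a fixed number of epochs. It classifies each segmented
#' pixel group as 0 (shadow, debris, the reference cap, or other non-oyster
#' noise), 1 (a single oyster) or 2 (two overlapping oysters or an oyster
#' with overlapped noise). Features are standardised (zero mean, unit
#' variance, fitted on the training set) before the network; the scaler is
#' stored with the model.
#'
#' Training is reproducible: the same seed and data give identical weights.
#'
#' @param features data.frame or matrix with columns `pct_mean`, `pct_std`,
#'   `pct_pixels`.
#' @param class integer labels in \{0, 1, 2\}; at least two classes must be
#'   present.
#' @param seed integer seed for weight initialisation.
#' @param epochs optimisation epochs (full-batch steps); default 200.
#' @param hidden hidden-layer width; default 100.
#' @param learning_rate Adam step size; default 0.01 (chosen so full-batch
#'   training converges within the fixed epoch budget).
#' @return An `ann_model` with weights, the feature scaler, the loss curve
#'   and the final training accuracy.
#' @export
train_ann <- function(features, class, seed = 1L, epochs = 200L,
                      hidden = 100L, learning_rate = 0.01) {
  x <- as.matrix(features[, c("pct_mean", "pct_std", "pct_pixels")])
  storage.mode(x) <- "double"
  y <- as.integer(class)
  stopifnot(nrow(x) == length(y), all(is.finite(x)))
  levels <- sort(unique(y))
  if (length(levels) < 2L)
    stop("training data contains a single class (", levels,
         "); a classifier needs at least two")
  n <- nrow(x); k <- length(levels); p <- ncol(x)

  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2L, ctr)^2))
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")

  yi <- match(y, levels)
  Y <- matrix(0, n, k); Y[cbind(seq_len(n), yi)] <- 1

  set.seed(seed)
  W1 <- matrix(stats::rnorm(hidden * p, sd = sqrt(2 / p)), hidden, p)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::rnorm(k * hidden, sd = sqrt(2 / hidden)), k, hidden)
  b2 <- numeric(k)

  adam <- list(); for (nm in c("W1", "b1", "W2", "b2"))
    adam[[nm]] <- list(m = 0, v = 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  loss_curve <- numeric(epochs)

  for (t in seq_len(epochs)) {
    Z1 <- xs %*% t(W1) + matrix(b1, n, hidden, byrow = TRUE)
    A1 <- pmax(Z1, 0)
    logits <- A1 %*% t(W2) + matrix(b2, n, k, byrow = TRUE)
    logits <- logits - apply(logits, 1L, max)
    P <- exp(logits); P <- P / rowSums(P)
    loss_curve[t] <- -mean(log(pmax(P[cbind(seq_len(n), yi)], 1e-12)))

    dL <- (P - Y) / n
    gW2 <- t(dL) %*% A1; gb2 <- colSums(dL)
    dA1 <- dL %*% W2
    dZ1 <- dA1 * (Z1 > 0)
    gW1 <- t(dZ1) %*% xs; gb1 <- colSums(dZ1)

    upd <- function(nm, g) {
      a <- adam[[nm]]
      a$m <- beta1 * a$m + (1 - beta1) * g
      a$v <- beta2 * a$v + (1 - beta2) * g^2
      adam[[nm]] <<- a
      (a$m / (1 - beta1^t)) / (sqrt(a$v / (1 - beta2^t)) + eps)
    }
    W1 <- W1 - learning_rate * upd("W1", gW1)
    b1 <- b1 - learning_rate * upd("b1", gb1)
    W2 <- W2 - learning_rate * upd("W2", gW2)
    b2 <- b2 - learning_rate * upd("b2", gb2)
  }

  model <- structure(
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
         centre = ctr, scale = scl, class_levels = levels,
         meta = list(seed = seed, epochs = epochs, hidden = hidden,
                     learning_rate = learning_rate,
                     loss_curve = loss_curve)),
    class = "ann_model")
  model$meta$train_accuracy <-
    mean(predict(model, features) == y)
  model
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf(
    "<ann_model %d-%d-%d, %d epochs, train accuracy %.3f>\n",
    ncol(x$W1), nrow(x$W1), nrow(x$W2), x$meta$epochs,
    x$meta$train_accuracy))
  invisible(x)
}

#' Predict group classes with the MLP filter
#'
#' @param object an `ann_model`.
#' @param newdata data.frame or matrix with columns `pct_mean`, `pct_std`,
#'   `pct_pixels`.
#' @param type `"class"` for hard labels, `"prob"` for the softmax matrix
#'   (rows sum to 1).
#' @param ... unused.
#' @return Integer class labels or a probability matrix.
#' @export
predict.ann_model <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata[, c("pct_mean", "pct_std", "pct_pixels")])
  storage.mode(x) <- "double"
  xs <- sweep(sweep(x, 2L, object$centre), 2L, object$scale, "/")
  n <- nrow(xs)
  A1 <- pmax(xs %*% t(object$W1) +
               matrix(object$b1, n, length(object$b1), byrow = TRUE), 0)
  logits <- A1 %*% t(object$W2) +
    matrix(object$b2, n, length(object$b2), byrow = TRUE)
  logits <- logits - apply(logits, 1L, max)
  P <- exp(logits); P <- P / rowSums(P)
  colnames(P) <- object$class_levels
  if (type == "prob") return(P)
  object$class_levels[max.col(P, ties.method = "first")]
}

#' Partition groups into kept oysters and removed noise
#'
#' Applies the MLP filter and removes every class-0 group (shadows, debris,
#' the reference cap). Class-1 and class-2 groups are kept -- fused pairs
#' (class 2) are resolved later by the refinement forest -- and their
#' predicted class travels with them.
#'
#' @param model an `ann_model`.
#' @param groups list of `pixel_group`, aligned 1:1 with `features` rows.
#' @param features feature rows for the same groups ([ann_features()]).
#' @return List with `kept` and `removed` (lists of `pixel_group`), and
#'   `class` (predicted label per input group, input order).
#' @export
filter_groups <- function(model, groups, features) {
  stopifnot(length(groups) == nrow(features))
  if (length(groups) == 0L)
    return(list(kept = list(), removed = list(), class = integer()))
  cls <- predict(model, features)
  keep <- cls != 0L
  list(kept = groups[keep], removed = groups[!keep], class = cls)
}
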