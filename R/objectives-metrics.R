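#' Loss weighting for the joint objective
#'
#' The total training loss is `weight_cl * CL + weight_rlc * RC_L`, with the
#' classification weight 0.5 and the reconstruction weight 1.0 by default.
#'
#' @param weight_cl Weight on the classification (cross-entropy) loss.
#' @param weight_rlc Weight on the reconstruction (MSE) loss.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(weight_cl = 0.5, weight_rlc = 1.0) {
  stopifnot(weight_cl > 0, weight_cl <= 1, weight_rlc > 0, weight_rlc <= 1)
  structure(list(weight_cl = weight_cl, weight_rlc = weight_rlc),
            class = "loss_weights")
}

#' Binary cross-entropy classification loss
#'
#' `-(1/M) * sum(x * log(xhat) + (1 - x) * log(1 - xhat))` over a batch of M
#' segments. Predictions are clamped to `[clamp, 1 - clamp]` before the logs
#' for numerical safety; the bias this introduces is negligible.
#'
#' @param predictions Predicted class probabilities in (0, 1).
#' @param labels Binary labels (1 = ictal, 0 = interictal).
#' @param clamp Clamping constant (default 1e-7).
#' @return Scalar loss.
#' @export
#' @examples
#' classification_loss(rep(0.5, 4), c(0, 1, 0, 1))  # log(2)
classification_loss <- function(predictions, labels, clamp = 1e-7) {
  if (length(predictions) == 0) stop("empty batch")
  stopifnot(length(predictions) == length(labels),
            all(labels %in% c(0, 1)))
  p <- pmin(pmax(predictions, clamp), 1 - clamp)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Mean-squared reconstruction loss
#'
#' Per segment, the squared error is averaged over the full `(q x r)` value
#' grid; the batch loss is the mean over segments.
#'
#' @param originals,reconstructions Arrays of identical shape, batch first.
#' @return Scalar loss.
#' @export
#' @examples
#' x <- array(0, c(2, 4, 3))
#' reconstruction_loss(x, x + 1)  # 1
reconstruction_loss <- function(originals, reconstructions) {
  if (!identical(dim(originals), dim(reconstructions)) ||
      length(originals) != length(reconstructions))
    stop("originals and reconstructions must have identical shapes")
  mean((originals - reconstructions)^2)
}

#' Weighted total loss
#'
#' @param cl Classification loss value.
#' @param rcl Reconstruction loss value.
#' @param weights A [loss_weights()] object.
#' @return `weight_cl * cl + weight_rlc * rcl`.
#' @export
total_loss <- function(cl, rcl, weights = loss_weights()) {
  stopifnot(is.finite(cl), is.finite(rcl))
  weights$weight_cl * cl + weights$weight_rlc * rcl
}

#' Confusion counts for binary seizure classification
#'
#' @param predicted,truth Binary vectors (1 = ictal).
#' @return Object of class `confusion_counts`: true/false positives/negatives.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth),
            all(predicted %in% c(0, 1)), all(truth %in% c(0, 1)))
  structure(list(
    tp = sum(predicted == 1 & truth == 1),
    tn = sum(predicted == 0 & truth == 0),
    fp = sum(predicted == 1 & truth == 0),
    fn = sum(predicted == 0 & truth == 1)
  ), class = "confusion_counts")
}

#' Threshold probabilities into class labels
#'
#' A segment is called ictal when its probability is greater than or equal to
#' the threshold (ties at the threshold go to the positive class).
#'
#' @param probabilities Predicted probabilities in `[0, 1]`.
#' @param truth Binary ground-truth labels.
#' @param tau Decision threshold (default 0.5).
#' @return List with `labels` and `counts` (a [confusion_counts()]).
#' @export
threshold_predictions <- function(probabilities, truth, tau = 0.5) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  labels <- as.integer(probabilities >= tau)
  list(labels = labels, counts = confusion_counts(labels, truth))
}

ratio_or_zero <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator); reporting 0", what),
            call. = FALSE)
    return(0)
  }
  num / den
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity, specificity and precision as percentages, and the
#' F1 score as the harmonic mean of precision and sensitivity (computed on
#' fractions, then scaled to a percentage). Ratios with a zero denominator are
#' reported as 0 with a warning so fold aggregation stays total.
#'
#' @param counts A [confusion_counts()] object.
#' @return Object of class `metrics_record`: named vector with `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `f1`, all in `[0, 100]`.
#' @export
#' @examples
#' compute_metrics(confusion_counts(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1),
#'                                  c(1, 1, 1, 0, 0, 0, 0, 0, 1, 0)))
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  a <- counts$tp; b <- counts$tn; d <- counts$fp; m <- counts$fn
  total <- a + b + d + m
  if (total == 0) stop("no evaluated segments")
  acc <- (a + b) / total
  se <- ratio_or_zero(a, a + m, "sensitivity")
  sp <- ratio_or_zero(b, b + d, "specificity")
  pr <- ratio_or_zero(a, a + d, "precision")
  f1 <- if (pr + se == 0) {
    warning("F1 undefined (precision + sensitivity is zero); reporting 0",
            call. = FALSE)
    0
  } else 2 * pr * se / (pr + se)
  structure(100 * c(accuracy = acc, sensitivity = se, specificity = sp,
                    precision = pr, f1 = f1),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("Acc %.2f%%  Se %.2f%%  Sp %.2f%%  Pr %.2f%%  F1 %.2f%%\n",
              x[["accuracy"]], x[["sensitivity"]], x[["specificity"]],
              x[["precision"]], x[["f1"]]))
  invisible(x)
}
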