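#' Fit a one-dimensional linear discriminant
#'
#' Equal-variance Gaussian discriminant on a single scalar feature. With
#' class means `mu_p` (positive class) and `mu_n`, pooled within-class
#' variance `s2`, and priors `pi_p`, `pi_n`, the decision boundary sits at
#' `x* = (mu_p + mu_n)/2 - s2 * log(pi_p / pi_n) / (mu_p - mu_n)`, the
#' midpoint of the class means shifted toward the rarer class; with equal
#' priors it is exactly the midpoint. A case on the PAH side of `x*` is
#' predicted positive; a case exactly on the boundary resolves to the
#' normal class (conservative screening default).
#'
#' @param values Numeric feature vector.
#' @param labels Class labels (coercible to factor); exactly two classes,
#'   both present (leave-one-out splits may reduce a class to one member,
#'   which is accepted as long as the pooled variance stays positive).
#' @param priors `"empirical"` (class frequencies, default), `"equal"`, or
#'   a named numeric vector of probabilities summing to 1.
#' @param positive Name of the positive (PAH) class; default `"pah"`, or
#'   the second factor level if `"pah"` is not a level.
#' @return A `pcg_lda` model: class means, pooled variance, priors,
#'   `threshold`, and `positive_low` (TRUE when the positive class lies
#'   below the threshold).
#' @export
fit_lda <- function(values, labels, priors = "empirical", positive = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("exactly two classes are required, got ", nlevels(labels))
  if (length(values) != length(labels))
    stop("values and labels differ in length")
  if (anyNA(values)) stop("feature values contain NA")
  counts <- table(labels)
  if (any(counts < 1L))
    stop("class '", names(counts)[which.min(counts)], "' has no members")
  if (length(values) < 3L)
    stop("at least 3 cases are required to pool a variance")
  if (is.null(positive))
    positive <- if ("pah" %in% levels(labels)) "pah" else levels(labels)[2L]
  if (!positive %in% levels(labels))
    stop("positive class '", positive, "' is not a label level")
  negative <- setdiff(levels(labels), positive)

  mu <- tapply(values, labels, mean)
  ss <- tapply(values, labels, function(v) sum((v - mean(v))^2))
  pooled_var <- sum(ss) / (length(values) - 2L)
  if (pooled_var <= 0) stop("pooled within-class variance is zero")
  pr <- if (identical(priors, "empirical")) {
    as.numeric(counts) / length(values)
  } else if (identical(priors, "equal")) {
    c(0.5, 0.5)
  } else {
    if (!all(sort(names(priors)) == sort(levels(labels))) ||
        abs(sum(priors) - 1) > 1e-8)
      stop("numeric priors must be named by class and sum to 1")
    as.numeric(priors[levels(labels)])
  }
  names(pr) <- levels(labels)

  mu_p <- mu[[positive]]; mu_n <- mu[[negative]]
  if (mu_p == mu_n) stop("class means are identical: threshold undefined")
  threshold <- (mu_p + mu_n) / 2 -
    pooled_var * log(pr[[positive]] / pr[[negative]]) / (mu_p - mu_n)
  structure(
    list(class_means = mu, pooled_variance = pooled_var, priors = pr,
         threshold = unname(threshold), positive = positive,
         negative = negative, positive_low = mu_p < mu_n),
    class = "pcg_lda")
}

#' @export
print.pcg_lda <- function(x, ...) {
  cat(sprintf("<pcg_lda> threshold=%.6g (positive '%s' on %s side), priors %s\n",
              x$threshold, x$positive,
              if (x$positive_low) "low" else "high",
              paste(sprintf("%s=%.3f", names(x$priors), x$priors),
                    collapse = " ")))
  invisible(x)
}

#' Predict classes from a fitted one-dimensional discriminant
#'
#' @param object A [fit_lda()] model.
#' @param newdata Numeric feature values.
#' @param ... Unused.
#' @return Factor of predicted labels. Ties at the threshold resolve to the
#'   negative (normal) class.
#' @export
predict.pcg_lda <- function(object, newdata, ...) {
  pos <- if (object$positive_low) newdata < object$threshold
         else newdata > object$threshold
  factor(ifelse(pos, object$positive, object$negative),
         levels = c(object$negative, object$positive))
}

#' Leave-one-out cross-validated classification
#'
#' Fits the discriminant `n` times on `n - 1` cases and predicts the single
#' held-out case; confusion counts aggregate the held-out predictions only.
#'
#' @inheritParams fit_lda
#' @return A `classification_result`: list with counts `TP`, `FP`, `TN`,
#'   `FN`, `sensitivity` and `specificity` (percent), and `predictions`
#'   (data.frame with `value`, `truth`, `predicted`, `split`).
#' @export
loo_evaluate <- function(values, labels, priors = "empirical",
                         positive = NULL) {
  labels <- factor(labels)
  n <- length(values)
  if (n < 3L) stop("leave-one-out needs at least 3 cases")
  counts <- table(labels)
  if (nlevels(labels) != 2L || any(counts < 2L))
    stop("both classes need >= 2 members for every leave-one-out split")
  pred <- character(n)
  for (i in seq_len(n)) {
    model <- fit_lda(values[-i], labels[-i], priors = priors,
                     positive = positive)
    pred[i] <- as.character(stats::predict(model, values[i]))
    positive <- model$positive  # lock orientation across splits
  }
  pos <- positive
  truth_pos <- labels == pos
  pred_pos <- pred == pos
  TP <- sum(truth_pos & pred_pos); FN <- sum(truth_pos & !pred_pos)
  TN <- sum(!truth_pos & !pred_pos); FP <- sum(!truth_pos & pred_pos)
  cm <- confusion_metrics(TP, FN, TN, FP)
  structure(
    list(TP = TP, FP = FP, TN = TN, FN = FN,
         sensitivity = cm$sensitivity, specificity = cm$specificity,
         positive = pos,
         predictions = data.frame(value = values,
                                  truth = as.character(labels),
                                  predicted = pred, split = seq_len(n))),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> TP=%d FP=%d TN=%d FN=%d | SE=%.2f%% SP=%.2f%%\n",
              x$TP, x$FP, x$TN, x$FN, x$sensitivity, x$specificity))
  invisible(x)
}

#' Sensitivity and specificity from confusion counts
#'
#' `sensitivity = 100 * TP / (TP + FN)`,
#' `specificity = 100 * TN / (TN + FP)`.
#'
#' @param TP,FN,TN,FP Non-negative integer confusion counts; each class
#'   must be non-empty.
#' @return List with `sensitivity` and `specificity` in percent.
#' @export
confusion_metrics <- function(TP, FN, TN, FP) {
  counts <- c(TP = TP, FN = FN, TN = TN, FP = FP)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  if (TP + FN == 0) stop("no positive cases: sensitivity undefined")
  if (TN + FP == 0) stop("no negative cases: specificity undefined")
  list(sensitivity = 100 * TP / (TP + FN),
       specificity = 100 * TN / (TN + FP))
}
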