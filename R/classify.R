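as_feature_matrix <- function(features) {
  x <- as.matrix(features)
  if (!is.numeric(x)) stop("features must be numeric", call. = FALSE)
  x
}

#' Train a Gaussian-kernel SVM on feature vectors
#'
#' Standardizes each feature with the training-set mean and standard
#' deviation (constant features are left centered but unscaled), then fits
#' a soft-margin SVM with the radial (Gaussian) kernel. Standardization
#' matters because the texture features live on wildly different scales.
#' The default `gamma = 1 / (p * var)` — with `p` the number of features
#' and `var` the pooled variance of the standardized features — reduces to
#' `1/p` after standardization. Refitting with the same data and seed
#' yields identical predictions.
#'
#' @param features numeric matrix or data frame, one row per sample.
#' @param labels integer vector of 0 (normal) / 1 (abnormal), one per row;
#'   both classes must have at least 2 samples.
#' @param cost soft-margin penalty `C > 0` (default 1).
#' @param gamma Gaussian kernel width; default `NULL` uses
#'   `1 / (p * var(scaled features))`.
#' @param seed integer seed fixed before fitting.
#' @return an object of class `tumor_svm` carrying the fitted model and
#'   the scaling parameters.
#' @importFrom e1071 svm
#' @export
train_svm <- function(features, labels, cost = 1, gamma = NULL, seed = 0L) {
  x <- as_feature_matrix(features)
  labels <- as.integer(labels)
  if (nrow(x) != length(labels))
    stop("features and labels differ in length", call. = FALSE)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0 (normal) or 1 (abnormal)", call. = FALSE)
  if (!all(is.finite(x)))
    stop("features contain non-finite values", call. = FALSE)
  if (min(table(factor(labels, levels = c(0L, 1L)))) < 2L)
    stop("need at least 2 samples in each class", call. = FALSE)
  if (cost <= 0) stop("`cost` must be > 0", call. = FALSE)
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[!is.finite(scale_) | scale_ < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  if (is.null(gamma)) {
    v <- mean(apply(xs, 2, var))
    gamma <- 1 / (ncol(xs) * max(v, 1e-12))
  }
  set.seed(as.integer(seed))
  model <- e1071::svm(x = xs, y = factor(labels, levels = c(0L, 1L)),
                      kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE)
  structure(list(model = model, center = center, scale = scale_,
                 cost = cost, gamma = gamma, seed = as.integer(seed),
                 feature_names = colnames(x)),
            class = "tumor_svm")
}

#' Predict labels with a trained tumor SVM
#'
#' Applies the stored training-set standardization, then the fitted
#' Gaussian-kernel decision function.
#'
#' @param object a [train_svm()] model.
#' @param newdata numeric matrix or data frame of feature rows.
#' @param ... unused.
#' @return integer vector of 0/1 labels (empty input gives an empty
#'   vector).
#' @export
predict.tumor_svm <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  if (nrow(x) == 0L) return(integer(0))
  if (ncol(x) != length(object$center))
    stop("feature dimensionality does not match the trained model",
         call. = FALSE)
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  as.integer(as.character(predict(object$model, xs)))
}

#' @export
print.tumor_svm <- function(x, ...) {
  cat(sprintf("<tumor_svm> Gaussian kernel, C = %g, gamma = %.4g, %d support vectors\n",
              x$cost, x$gamma, x$model$tot.nSV))
  invisible(x)
}

#' Confusion matrix in the abnormal-first layout
#'
#' Rows are the true class, columns the predicted class, ordered
#' (abnormal, normal).
#'
#' @param truth,predicted integer vectors of 0/1 labels.
#' @return 2x2 integer matrix of class `confusion_matrix` with dimnames
#'   `truth` x `predicted`.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) != length(predicted) || length(truth) == 0L)
    stop("need equal-length, non-empty label vectors", call. = FALSE)
  lv <- c("abnormal", "normal")
  tt <- factor(ifelse(truth == 1L, "abnormal", "normal"), levels = lv)
  pp <- factor(ifelse(predicted == 1L, "abnormal", "normal"), levels = lv)
  cm <- unclass(table(truth = tt, predicted = pp))
  storage.mode(cm) <- "integer"
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Evaluate a classifier on a labeled test set
#'
#' @param clf a [train_svm()] model.
#' @param features test feature rows.
#' @param labels true 0/1 labels.
#' @return a [confusion_matrix()].
#' @export
evaluate_classifier <- function(clf, features, labels) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("empty test set", call. = FALSE)
  confusion_matrix(labels, predict(clf, features))
}

#' Classification accuracy of a confusion matrix
#'
#' @param cm a 2x2 confusion matrix with positive total count.
#' @return fraction of correctly classified samples in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  cm <- unclass(cm)
  if (!is.matrix(cm) || any(cm < 0)) stop("invalid confusion matrix", call. = FALSE)
  tot <- sum(cm)
  if (tot == 0) stop("confusion matrix has zero total", call. = FALSE)
  sum(diag(cm)) / tot
}
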