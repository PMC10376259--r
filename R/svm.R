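#' Train an RBF-kernel SVM
#'
#' Soft-margin support-vector classifier with the Gaussian kernel
#' \code{K(u, v) = exp(-gamma * ||u - v||^2)}, trained by sequential minimal
#' optimization with maximal-violating-pair selection. Defaults follow the
#' common convention when hyperparameters are unstated: \code{C = 1} and
#' \code{gamma = "scale"} = \code{1 / (n_features * var(X))} with the pooled
#' population variance of the training matrix.
#'
#' @param x numeric matrix, observations x features (standardize features
#'   with training-set statistics before calling; see
#'   \code{\link{loso_clip_predictions}}).
#' @param y labels: \code{"healthy"}/\code{"dementia"}, a factor, or +-1.
#'   Dementia (or +1) is the positive class.
#' @param C box constraint (default 1).
#' @param gamma kernel width, or \code{"scale"}.
#' @param tol KKT violation tolerance for the stopping rule.
#' @param max_iter iteration cap for the optimizer.
#' @return an \code{svm_rbf} model (support vectors, dual coefficients,
#'   offset, kernel width).
#' @export
svm_rbf_train <- function(x, y, C = 1, gamma = "scale", tol = 1e-3,
                          max_iter = 1000000L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    if (!all(y %in% class_levels))
      stop_fs("labels must be 'healthy' or 'dementia'")
    yy <- ifelse(y == "dementia", 1, -1)
  } else {
    if (!all(y %in% c(-1, 1))) stop_fs("numeric labels must be +-1")
    yy <- as.double(y)
  }
  if (length(unique(yy)) < 2L) stop_fs("training set must contain both classes")
  if (identical(gamma, "scale")) {
    v <- mean(x^2) - mean(x)^2
    gamma <- if (v > 0) 1 / (ncol(x) * v) else 1
  }
  fit <- .smo_train(x, yy, C, gamma, tol, as.integer(max_iter))
  sv <- which(fit$alpha > 1e-12)
  structure(list(sv = x[sv, , drop = FALSE],
                 coef = fit$alpha[sv] * yy[sv],
                 b = fit$b, gamma = gamma, C = C,
                 iterations = fit$iterations),
            class = "svm_rbf")
}

#' Decision values and class predictions from an RBF-SVM
#'
#' @param object an \code{\link{svm_rbf_train}} model.
#' @param newdata numeric matrix with the training feature width.
#' @param type \code{"class"} (default) or \code{"decision"} (signed margin,
#'   positive = dementia).
#' @param ... unused.
#' @return character labels or numeric decision values.
#' @export
predict.svm_rbf <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != ncol(object$sv))
    stop_fs(sprintf("feature width %d does not match training width %d",
                    ncol(newdata), ncol(object$sv)))
  d <- .smo_decision(object$sv, object$coef, object$b, object$gamma, newdata)
  if (type == "decision") return(d)
  ifelse(d > 0, "dementia", "healthy")
}
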