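# Fisher linear discriminant analysis on selected wavelengths, with equal
# priors and a ridge fallback for near-singular pooled covariance (the
# bands >> samples regime). Authored here because the selection pipeline
# needs canonical scores, equal priors and the ridge knob together;
# MASS::lda is the independent cross-check in the tests.

#' Fisher linear discriminant analysis
#'
#' Computes canonical axes maximizing between- over within-class scatter
#' (at most classes - 1 axes) and classifies by the nearest class mean in
#' canonical space with equal priors.
#'
#' @param x samples x features matrix (spectra restricted to selected
#'   wavelengths), or a [spectra_table()].
#' @param labels class label per sample.
#' @param holdback indices excluded from fitting and used for validation
#'   (default none).
#' @param ridge ridge multiplier added to the pooled covariance diagonal
#'   when it is computationally singular (scaled by its mean diagonal).
#' @return object of class `lda_model`: class means, canonical axes
#'   (`scaling`), canonical `scores` of the training samples, training and
#'   holdback accuracy (overall and per class).
#' @export
fit_lda <- function(x, labels, holdback = integer(0), ridge = 1e-6) {
  X <- if (inherits(x, "spectra_table")) x$spectra else as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  train <- setdiff(seq_len(nrow(X)), holdback)
  Xt <- X[train, , drop = FALSE]; lt <- labels[train]
  classes <- sort(unique(lt))
  if (length(classes) < 2) gs_stop("need >= 2 classes", class = "config_error")
  p <- ncol(Xt)
  means <- t(vapply(classes, function(cl) colMeans(Xt[lt == cl, , drop = FALSE]),
                    numeric(p)))
  Sw <- matrix(0, p, p)
  for (cl in classes) {
    Xi <- Xt[lt == cl, , drop = FALSE]
    if (nrow(Xi) < 2) gs_stop("class ", cl, " has < 2 training samples",
                              class = "class_size_error")
    Xi <- sweep(Xi, 2L, colMeans(Xi))
    Sw <- Sw + crossprod(Xi)
  }
  Sw <- Sw / (nrow(Xt) - length(classes))
  ev <- eigen(Sw, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev)) {
    if (ridge <= 0) gs_stop("pooled within-class covariance is singular",
                            class = "linear_algebra_error")
    Sw <- Sw + diag(ridge * mean(diag(Sw)), p)
  }
  gm <- colMeans(Xt)
  Mb <- sweep(means, 2L, gm)
  Sb <- crossprod(Mb) / length(classes)    # equal class weight (equal priors)
  # generalized eigenproblem Sb a = lambda Sw a via whitening
  R <- chol(Sw)
  M <- backsolve(R, t(backsolve(R, t(Sb), transpose = TRUE)), transpose = TRUE)
  ee <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ncan <- min(length(classes) - 1L, p)
  A <- backsolve(R, ee$vectors[, seq_len(ncan), drop = FALSE])
  # normalize axes to unit within-class variance
  A <- sweep(A, 2L, sqrt(colSums((R %*% A)^2) / 1), "/")
  model <- structure(list(
    classes = classes, means = means, scaling = A, grand_mean = gm,
    eigenvalues = ee$values[seq_len(ncan)],
    train = train, holdback = holdback,
    scores = sweep(Xt, 2L, gm) %*% A
  ), class = "lda_model")
  pred_tr <- predict(model, Xt)
  model$train_accuracy <- mean(pred_tr == lt)
  model$train_class_accuracy <- vapply(classes, function(cl)
    mean(pred_tr[lt == cl] == cl), numeric(1))
  if (length(holdback)) {
    ph <- predict(model, X[holdback, , drop = FALSE])
    lh <- labels[holdback]
    model$holdback_accuracy <- mean(ph == lh)
    model$holdback_class_accuracy <- vapply(classes, function(cl)
      if (any(lh == cl)) mean(ph[lh == cl] == cl) else NA_real_, numeric(1))
  }
  model
}

#' @export
predict.lda_model <- function(object, newdata, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "spectra_table")) newdata$spectra else as.matrix(newdata)
  S <- sweep(X, 2L, object$grand_mean) %*% object$scaling
  if (type == "scores") return(S)
  Mc <- sweep(object$means, 2L, object$grand_mean) %*% object$scaling
  d2 <- outer(rowSums(S^2), rowSums(Mc^2), `+`) - 2 * S %*% t(Mc)
  object$classes[max.col(-d2, ties.method = "first")]
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("Fisher LDA: %d classes, %d canonical axes, %d features\n",
              length(x$classes), ncol(x$scaling), nrow(x$scaling)))
  cat(sprintf("  training accuracy: %.1f%%\n", 100 * x$train_accuracy))
  if (!is.null(x$holdback_accuracy))
    cat(sprintf("  holdback accuracy: %.1f%%\n", 100 * x$holdback_accuracy))
  invisible(x)
}
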