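# NIPALS partial least squares, PLS-DA front-end, VIP scores, and VIP/beta
# wavelength selection. The bilinear NIPALS factorization is authored here
# because its internals (weights, scores, per-component Y variance) feed the
# VIP statistic and the selection rule; the pls package serves as an
# independent cross-check in the test suite, never as the implementation.

#' Class-indicator coding
#'
#' Codes class membership as binary columns: 1 for membership, 0 otherwise.
#'
#' @param labels factor or character vector of class labels.
#' @return list of class `class_coding`: `labels`, `classes`, `indicator`
#'   (samples x classes 0/1 matrix, rows summing to 1).
#' @export
class_coding <- function(labels) {
  f <- factor(labels)
  ind <- outer(f, levels(f), `==`) * 1
  colnames(ind) <- levels(f)
  structure(list(labels = as.character(f), classes = levels(f), indicator = ind),
            class = "class_coding")
}

nipals_pls <- function(X, Y, ncomp, tol = 1e-10, maxit = 500L) {
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); Q <- matrix(0, q, ncomp); U <- matrix(0, n, ncomp)
  Xd <- X; Yd <- Y
  actual <- 0L
  for (a in seq_len(ncomp)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    if (sum(u^2) < 1e-14) break
    t_old <- rep(Inf, n)
    tt <- NULL; nw <- 0

    for (it in seq_len(maxit)) {
      w <- crossprod(Xd, u)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      tt <- Xd %*% w
      qv <- crossprod(Yd, tt)[, 1] / sum(tt^2)
      u <- (Yd %*% qv) / sum(qv^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    if (is.null(tt) || nw < 1e-14 || sum(tt^2) < 1e-14) break
    pv <- crossprod(Xd, tt)[, 1] / sum(tt^2)
    Xd <- Xd - tcrossprod(tt, pv)
    Yd <- Yd - tcrossprod(tt, qv)
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- tt; Q[, a] <- qv; U[, a] <- u
    actual <- a
  }
  if (actual == 0L) gs_stop("no PLS component could be extracted",
                            class = "degenerate_model_error")
  idx <- seq_len(actual)
  list(weights = W[, idx, drop = FALSE], loadings = P[, idx, drop = FALSE],
       scores = Tm[, idx, drop = FALSE], y_loadings = Q[, idx, drop = FALSE],
       y_scores = U[, idx, drop = FALSE], ncomp = actual)
}

pls_beta <- function(fit, ncomp = fit$ncomp) {
  idx <- seq_len(ncomp)
  W <- fit$weights[, idx, drop = FALSE]
  P <- fit$loadings[, idx, drop = FALSE]
  Q <- fit$y_loadings[, idx, drop = FALSE]
  Wstar <- W %*% solve(crossprod(P, W))
  Wstar %*% t(Q)
}

#' Fit a PLS regression / discriminant model on spectra
#'
#' X is centered and scaled per band; Y is the (centered) class-indicator
#' matrix for discriminant analysis, or a centered numeric response matrix
#' for regression. Components are extracted by the iterative bilinear NIPALS
#' factorization with deflation. When `n_components` is `NULL` it is chosen
#' by 5-fold cross-validation on the training set (minimum prediction error).
#' A stratified holdback fraction of the samples (default 10%) is excluded
#' from fitting and used for validation.
#'
#' @param spectra a [spectra_table()].
#' @param response a [class_coding()] (PLS-DA) or numeric vector/matrix
#'   (PLS regression).
#' @param n_components number of latent components, or `NULL` to choose by
#'   cross-validation.
#' @param holdback_fraction fraction of samples held back for validation
#'   (stratified by class for PLS-DA); 0 disables the split.
#' @param max_components cap for the cross-validated search.
#' @param scale logical, scale X columns to unit variance (default TRUE).
#' @param seed integer seed for the split and cross-validation folds.
#' @return object of class `pls_model`: NIPALS factors, `beta` on the
#'   original X scale (bands x responses, with intercept attribute), centers
#'   and scales, the train/holdback indices, per-class percent variance
#'   explained (`pve`), and holdback/training predictions and accuracy for
#'   PLS-DA.
#' @export
fit_plsda <- function(spectra, response, n_components = NULL,
                      holdback_fraction = 0.10, max_components = 15L,
                      scale = TRUE, seed = 1) {
  stopifnot(inherits(spectra, "spectra_table"))
  X <- spectra$spectra
  is_da <- inherits(response, "class_coding")
  Y <- if (is_da) response$indicator else as.matrix(response)
  if (nrow(Y) != nrow(X)) gs_stop("response rows must match spectra rows",
                                  class = "config_error")
  set.seed(seed)
  n <- nrow(X)
  hold <- integer(0)
  if (holdback_fraction > 0) {
    if (is_da) {
      hold <- unlist(lapply(response$classes, function(cl) {
        idx <- which(response$labels == cl)
        nh <- max(1L, round(holdback_fraction * length(idx)))
        sample(idx, min(nh, length(idx) - 1L))
      }))
    } else {
      hold <- sample.int(n, max(1L, round(holdback_fraction * n)))
    }
  }
  train <- setdiff(seq_len(n), hold)
  if (is_da) {
    cnt <- table(factor(response$labels[train], levels = response$classes))
    if (any(cnt < 2))
      gs_stop("class with < 2 training samples: ",
              paste(names(cnt)[cnt < 2], collapse = ", "), class = "class_size_error")
  }
  Xt <- X[train, , drop = FALSE]; Yt <- Y[train, , drop = FALSE]
  x_mean <- colMeans(Xt)
  x_sd <- if (scale) apply(Xt, 2L, sd) else rep(1, ncol(X))
  x_sd[x_sd < 1e-12] <- 1
  y_mean <- colMeans(Yt)
  Xs <- sweep(sweep(Xt, 2L, x_mean), 2L, x_sd, "/")
  Ys <- sweep(Yt, 2L, y_mean)
  cap <- min(max_components, length(train) - 1L, ncol(X), qr(Xs)$rank)
  if (is.null(n_components)) {
    n_components <- cv_ncomp(Xs, Ys, cap, seed = seed)
  }
  if (n_components > min(length(train) - 1L, ncol(X)))
    gs_stop("n_components must be < training samples and <= bands",
            class = "config_error")
  fit <- nipals_pls(Xs, Ys, min(n_components, cap))
  beta_s <- pls_beta(fit)
  beta <- beta_s / x_sd           # back to original X units
  intercept <- y_mean - colSums(beta * x_mean)
  # per-response percent variance explained on the training set
  Yhat <- Xs %*% beta_s
  pve <- 100 * (1 - colSums((Ys - Yhat)^2) / pmax(colSums(Ys^2), 1e-300))
  names(pve) <- colnames(Y)
  model <- structure(list(
    n_components = fit$ncomp, weights = fit$weights, loadings = fit$loadings,
    scores = fit$scores, y_loadings = fit$y_loadings, y_scores = fit$y_scores,
    beta = beta, intercept = intercept, x_mean = x_mean, x_sd = x_sd,
    y_mean = y_mean, wavelengths = spectra$wavelengths,
    classes = if (is_da) response$classes else NULL,
    train = train, holdback = hold, pve = pve, is_da = is_da,
    sample_ids = spectra$sample_ids
  ), class = "pls_model")
  if (is_da) {
    model$train_accuracy <- mean(predict(model, X[train, , drop = FALSE], type = "class")
                                 == response$labels[train])
    if (length(hold))
      model$holdback_accuracy <- mean(predict(model, X[hold, , drop = FALSE], type = "class")
                                      == response$labels[hold])
  }
  model
}

cv_ncomp <- function(Xs, Ys, cap, folds = 5L, seed = 1) {
  set.seed(seed + 1L)
  n <- nrow(Xs)
  fold <- sample(rep_len(seq_len(folds), n))
  press <- numeric(cap)
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (sum(tr) < 3) next
    fit <- try(nipals_pls(Xs[tr, , drop = FALSE], Ys[tr, , drop = FALSE],
                          min(cap, sum(tr) - 1L)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    for (a in seq_len(min(cap, fit$ncomp))) {
      B <- pls_beta(fit, a)
      press[a] <- press[a] + sum((Ys[!tr, , drop = FALSE] -
                                    Xs[!tr, , drop = FALSE] %*% B)^2)
    }
    if (fit$ncomp < cap) press[(fit$ncomp + 1L):cap] <- Inf
  }
  which.min(press)
}

#' @export
predict.pls_model <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "spectra_table")) newdata$spectra else as.matrix(newdata)
  Yhat <- X %*% object$beta + matrix(object$intercept, nrow(X),
                                     length(object$intercept), byrow = TRUE)
  if (type == "class") {
    if (!object$is_da) gs_stop("class prediction needs a PLS-DA model",
                               class = "config_error")
    return(object$classes[max.col(Yhat, ties.method = "first")])
  }
  Yhat
}

#' @export
coef.pls_model <- function(object, ...) object$beta

#' @export
print.pls_model <- function(x, ...) {
  kind <- if (x$is_da) "PLS-DA" else "PLS regression"
  cat(sprintf("%s model: %d components, %d bands, %d training / %d holdback samples\n",
              kind, x$n_components, length(x$wavelengths),
              length(x$train), length(x$holdback)))
  if (x$is_da) {
    cat("  percent variance explained per class:\n")
    print(round(x$pve, 1))
    if (!is.null(x$holdback_accuracy))
      cat(sprintf("  holdback accuracy: %.1f%%\n", 100 * x$holdback_accuracy))
  }
  invisible(x)
}

#' @export
summary.pls_model <- function(object, ...) {
  print(object)
  v <- vip(object)
  cat(sprintf("  VIP >= 0.8 at %d of %d wavelengths\n",
              sum(v >= 0.8), length(v)))
  invisible(object)
}

#' Variable importance in projection (VIP)
#'
#' VIP_j = sqrt( p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a ), where
#' SSY_a is the Y variance explained by component a and p the number of
#' bands. The squared scores average to 1 across wavelengths.
#'
#' @param model a fitted [fit_plsda()] model.
#' @return named numeric vector of VIP scores, one per wavelength.
#' @export
vip <- function(model) {
  W <- model$weights; Q <- model$y_loadings; Tm <- model$scores
  p <- nrow(W)
  ssy <- colSums(Tm^2) * colSums(Q^2)      # Y variance explained per component
  if (sum(ssy) <= 0) gs_stop("model explains no Y variance",
                             class = "degenerate_model_error")
  wn <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
  v <- sqrt(p * as.numeric(wn^2 %*% ssy) / sum(ssy))
  names(v) <- format(model$wavelengths, trim = TRUE)
  v
}

#' Select informative wavelengths from a PLS model
#'
#' Keeps wavelengths whose VIP meets the threshold; optionally intersects
#' with local extrema of |beta| ("contrasting peaks") when `use_beta_peaks`
#' is set.
#'
#' @param model a fitted [fit_plsda()] model.
#' @param vip_threshold minimum VIP (default 0.8).
#' @param use_beta_peaks restrict to local maxima of max-abs beta across
#'   responses.
#' @return numeric vector of selected wavelengths (nm).
#' @export
select_wavelengths <- function(model, vip_threshold = 0.8, use_beta_peaks = FALSE) {
  v <- vip(model)
  sel <- v >= vip_threshold
  if (use_beta_peaks) {
    b <- apply(abs(model$beta), 1L, max)
    n <- length(b)
    peak <- b >= c(-Inf, b[-n]) & b >= c(b[-1], -Inf)
    sel <- sel & peak
  }
  if (!any(sel))
    gs_stop("no wavelength passes VIP >= ", vip_threshold,
            "; consider lowering the threshold", class = "selection_error")
  model$wavelengths[sel]
}
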