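# The eight chemometric pre-processing operators, applied row-wise
# (per spectrum) on a spectra_table. All preserve table shape and sample
# order. Regression results on data acquired under controlled conditions are
# typically close to raw-spectrum results, so the pipeline's default is no
# preprocessing; the operators are available and individually tested.

#' Specify a spectral pre-processing transform
#'
#' @param method one of `"none"`, `"smoothing"` (centered moving average),
#'   `"mean_norm"`, `"max_norm"`, `"range_norm"`, `"msc"` (multiplicative
#'   scatter correction), `"snv"` (standard normal variate), `"sg1"`, `"sg2"`
#'   (Savitzky-Golay first/second derivative).
#' @param window odd window length: >= 3 for smoothing (default 5), and
#'   > `polyorder` for the SG derivatives (default 7).
#' @param polyorder SG polynomial order (default 2).
#' @param reference optional reference spectrum for MSC; default is the
#'   column mean of the table the transform is applied to. Store the training
#'   mean here to reuse a fitted correction on test data.
#' @return object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(method = c("none", "smoothing", "mean_norm", "max_norm",
                                       "range_norm", "msc", "snv", "sg1", "sg2"),
                            window = NULL, polyorder = 2, reference = NULL) {
  method <- match.arg(method)
  if (is.null(window)) window <- if (method %in% c("sg1", "sg2")) 7L else 5L
  window <- as.integer(window)
  if (method %in% c("smoothing", "sg1", "sg2")) {
    if (window %% 2L == 0L || window < 3L)
      gs_stop("window must be odd and >= 3", class = "config_error")
    if (method != "smoothing" && window <= polyorder)
      gs_stop("window must exceed polyorder for Savitzky-Golay",
              class = "config_error")
  }
  structure(list(method = method, window = window,
                 polyorder = as.integer(polyorder), reference = reference),
            class = "preprocess_spec")
}

moving_average <- function(x, window) {
  # centered moving average with shrinking window at the edges
  n <- length(x); h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L); hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

sg_derivative <- function(x, window, polyorder, order, delta) {
  # interior by signal's SG filter; boundaries by explicit local polynomial fit
  n <- length(x); h <- (window - 1L) %/% 2L
  out <- signal::sgolayfilt(x, p = polyorder, n = window, m = order, ts = delta)
  # sgolayfilt already handles the transient with the full SG matrix, but its
  # edge rows are the fitted-polynomial derivatives at the window ends, which
  # is exactly the boundary handling wanted; keep them.
  stopifnot(length(out) == n, h >= 1)
  out
}

#' Apply a pre-processing transform to a spectra table
#'
#' Per-spectrum definitions: smoothing = centered moving average; mean_norm =
#' x / mean(x); max_norm = x / max(x); range_norm = (x - min) / (max - min);
#' snv = (x - mean) / sd (sample sd, n-1 denominator); msc = regress the
#' spectrum on the reference and return (x - intercept) / slope; sg1/sg2 =
#' Savitzky-Golay derivative of order 1/2 (per nm, using the median band
#' spacing).
#'
#' @param spectra a [spectra_table()].
#' @param spec a [preprocess_spec()].
#' @return a transformed [spectra_table()] of identical shape and order. For
#'   MSC the reference actually used is attached as attribute `"reference"`.
#' @export
apply_preprocess <- function(spectra, spec) {
  stopifnot(inherits(spectra, "spectra_table"), inherits(spec, "preprocess_spec"))
  X <- spectra$spectra
  method <- spec$method
  if (method == "none") return(spectra)
  ref <- NULL
  if (method == "msc") {
    ref <- spec$reference %||% colMeans(X)
    if (length(ref) != ncol(X))
      gs_stop("MSC reference length must match band count", class = "config_error")
  }
  delta <- median(diff(spectra$wavelengths))
  Y <- t(apply(X, 1L, function(x) {
    switch(method,
      smoothing = moving_average(x, spec$window),
      mean_norm = x / mean(x),
      max_norm = x / max(x),
      range_norm = {
        r <- range(x)
        if (r[2] <= r[1]) gs_stop("constant spectrum under range_norm",
                                  class = "degenerate_spectrum_error")
        (x - r[1]) / (r[2] - r[1])
      },
      snv = {
        s <- sd(x)
        if (s == 0) gs_stop("constant spectrum under SNV",
                            class = "degenerate_spectrum_error")
        (x - mean(x)) / s
      },
      msc = {
        fit <- lm.fit(cbind(1, ref), x)
        slope <- fit$coefficients[2]
        if (!is.finite(slope) || abs(slope) < 1e-12)
          gs_stop("MSC slope ~ 0; scatter correction undefined",
                  class = "scatter_correction_error")
        (x - fit$coefficients[1]) / slope
      },
      sg1 = sg_derivative(x, spec$window, spec$polyorder, 1L, delta),
      sg2 = sg_derivative(x, spec$window, spec$polyorder, 2L, delta)
    )
  }))
  out <- spectra_table(Y, spectra$wavelengths, spectra$sample_ids)
  if (method == "msc") attr(out, "reference") <- ref
  out
}

#' Apply a chain of pre-processing transforms
#'
#' @param spectra a [spectra_table()].
#' @param methods character vector of method names, applied left to right
#'   (e.g. `c("snv", "sg1")`); `"none"` entries are skipped.
#' @param ... passed to [preprocess_spec()] for every step.
#' @return transformed [spectra_table()].
#' @export
preprocess_chain <- function(spectra, methods, ...) {
  for (mth in methods) {
    if (identical(mth, "none")) next
    spectra <- apply_preprocess(spectra, preprocess_spec(mth, ...))
  }
  spectra
}
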