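#' @useDynLib grainspec, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor dist as.dist hclust kmeans lm lm.fit median
#'   na.omit p.adjust pchisq pf prcomp predict qbeta qchisq quantile rbinom
#'   rnorm runif sd setNames smooth.spline var
#' @importFrom utils read.delim write.table head tail
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

gs_stop <- function(..., class) {
  stop(structure(
    class = c(class, "grainspec_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    gs_stop(name, " must be a single number in [", lo, ", ", hi, "]",
            class = "config_error")
  invisible(x)
}

#' Min-max normalization to \[0, 1\]
#'
#' @param x numeric vector with max > min.
#' @return vector rescaled so min maps to 0 and max to 1.
#' @export
normalize01 <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!all(is.finite(r)) || r[2] <= r[1])
    gs_stop("cannot min-max normalize a constant vector", class = "degenerate_error")
  (x - r[1]) / (r[2] - r[1])
}
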