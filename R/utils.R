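# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stopf("'%s' must be finite and > 0", name)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stopf("'%s' must be finite and >= 0", name)
  invisible(x)
}

# small-sample corrected AIC from a least-squares fit
# k counts the fitted curve parameters; +1 for the noise variance
aicc_from_rss <- function(rss, n, k) {
  k <- k + 1
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n + .Machine$double.xmin) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# linear interpolation that errors outside the data range
interp_strict <- function(x, y, xout) {
  if (any(xout < min(x) - 1e-9) || any(xout > max(x) + 1e-9))
    stopf("interpolation target outside data range")
  approx(x, y, xout, rule = 2)$y
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
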