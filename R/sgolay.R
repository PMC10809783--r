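#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing filter used to smooth pointwise
#' compressibility-modulus curves (9-point window by default). Interior
#' points are smoothed by the standard convolution; within half a window
#' of either end, the local polynomial fitted to the first/last full
#' window is evaluated directly, so the output has the input's length.
#'
#' @param y numeric vector to smooth.
#' @param window odd window length in points (default 9).
#' @param order polynomial order, < window (default 3).
#' @return Numeric vector, same length as `y`.
#' @examples
#' y <- sin(seq(0, pi, length.out = 50)) + rnorm(50, sd = 0.05)
#' ys <- savitzkyGolay(y, window = 9, order = 3)
#' @export
savitzkyGolay <- function(y, window = 9L, order = 3L) {
  window <- as.integer(window)
  order <- as.integer(order)
  if (window %% 2L != 1L || window < 3L)
    stop("window must be an odd integer >= 3")
  if (order < 0L || order >= window)
    stop("order must be nonnegative and smaller than window")
  n <- length(y)
  if (n < window)
    stop(sprintf("series of %d points shorter than window %d", n, window))
  h <- (window - 1L) %/% 2L
  X <- outer(seq.int(-h, h), 0:order, `^`)
  ## projection onto the local polynomial space, evaluated at every
  ## in-window offset; row h+1 is the usual central convolution kernel
  P <- X %*% solve(crossprod(X), t(X))
  out <- y
  center <- P[h + 1L, ]
  if (n >= window) {
    for (i in seq.int(h + 1L, n - h))
      out[i] <- sum(center * y[(i - h):(i + h)])
    out[seq_len(h)] <- (P %*% y[seq_len(window)])[seq_len(h)]
    out[seq.int(n - h + 1L, n)] <-
      (P %*% y[seq.int(n - window + 1L, n)])[seq.int(h + 2L, window)]
  }
  out
}
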