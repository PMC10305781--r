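`%||%` <- function(a, b) if (is.null(a)) b else a

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Central-difference derivative of a uniformly sampled signal
#'
#' Interior points use central differences; the two endpoints use one-sided
#' differences, so the output has the same length as the input.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @return numeric vector of the same length as `x`.
#' @keywords internal
num_gradient <- function(x, fs) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) * fs
  d[n] <- (x[n] - x[n - 1L]) * fs
  if (n > 2L) d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  d
}

# Zero-phase 4th-order Butterworth low-pass. The straight line through the
# endpoints is removed first (so constants and ramps pass through exactly and
# DC start-up transients vanish), and the residual is padded by odd reflection
# before filtfilt.
lowpass_zerophase <- function(x, fs, cutoff, order = 4L) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency (", fs / 2, " Hz)")
  n <- length(x)
  if (n < 3L) return(x)
  base <- seq(x[1L], x[n], length.out = n)
  r <- x - base
  npad <- min(n - 1L, 50L)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  head_pad <- -r[(npad + 1L):2L]
  tail_pad <- -r[(n - 1L):(n - npad)]
  y <- signal::filtfilt(bf, c(head_pad, r, tail_pad))
  y[(npad + 1L):(npad + n)] + base
}

# Draw per-stream child seeds from a root seed, all < 2^31.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

is_uniform <- function(t, tol = 1e-6) {
  if (length(t) < 3L) return(TRUE)
  dt <- diff(t)
  max(abs(dt - dt[1L])) <= tol * max(dt[1L], .Machine$double.eps)
}
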