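#' Convert beats per minute to Hz
#'
#' @param bpm numeric vector in beats per minute.
#' @return frequency in Hz.
#' @export
#' @examples
#' bpm_to_hz(72)   # 1.2 Hz
bpm_to_hz <- function(bpm) bpm / 60

#' Convert Hz to beats per minute
#'
#' @param hz numeric vector in Hz.
#' @return rate in beats per minute.
#' @export
hz_to_bpm <- function(hz) hz * 60

#' Unwrap a phase sequence
#'
#' Removes 2*pi jumps: whenever the difference between consecutive samples
#' exceeds pi in magnitude, a multiple of 2*pi is added so that no step
#' exceeds pi.
#'
#' @param p phase vector in radians.
#' @return unwrapped phase vector, same length.
#' @export
unwrap_phase <- function(p) {
  if (length(p) < 2) return(p)
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}

#' Analytic signal via the frequency domain
#'
#' Discrete Hilbert-transform construction: the negative-frequency half of
#' the spectrum is zeroed and the positive half doubled, giving a complex
#' signal whose real part is the input and whose modulus is the envelope.
#'
#' @param x real signal vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  stopifnot(n >= 2, all(is.finite(x)))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## Zero-phase (forward-backward) IIR filtering with odd-reflection padding.
## signal::filtfilt alone leaves large startup transients for the very low
## normalized cutoffs used by the clutter filter; extending the signal by an
## odd reflection at both ends keeps the transients inside the padding.
filtfilt_pad <- function(filt, x, padlen = NULL) {
  n <- length(x)
  nf <- max(length(filt$b), length(filt$a)) - 1L
  if (is.null(padlen)) padlen <- 100L * nf
  padlen <- min(n - 1L, as.integer(padlen))
  if (padlen < 1L) return(signal::filtfilt(filt, x))
  pre <- 2 * x[1] - x[seq(padlen + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
  ext <- c(pre, x, post)
  y <- rev(signal::filter(filt, rev(signal::filter(filt, ext))))
  y[(padlen + 1L):(padlen + n)]
}

## Local maxima of a vector (strictly above both neighbours) together with
## their topographic prominence: height above the higher of the two deepest
## valleys separating the peak from higher ground (or the signal edge).
find_local_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(data.frame(index = integer(), value = numeric(), prominence = numeric()))
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  if (!length(idx)) return(data.frame(index = integer(), value = numeric(), prominence = numeric()))
  prom <- vapply(idx, function(i) {
    left <- y[seq_len(i - 1)]
    higher_l <- which(left > y[i])
    lmin <- if (length(higher_l)) min(y[(max(higher_l) + 1):(i - 1)]) else min(left)
    right <- y[(i + 1):n]
    higher_r <- which(right > y[i])
    rmin <- if (length(higher_r)) min(y[(i + 1):(i + min(higher_r) - 1)]) else min(right)
    y[i] - max(lmin, rmin)
  }, numeric(1))
  data.frame(index = idx, value = y[idx], prominence = prom)
}

## Numeric vector -> text with enough digits to round-trip exactly.
fmt_full <- function(x) sprintf("%.17g", x)
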