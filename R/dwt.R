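## Orthonormal Daubechies low-pass filters (sum = sqrt(2), unit energy).
## "dbN" has N vanishing moments and 2N taps.
WAVELET_FILTERS <- list(
  haar = c(1, 1) / sqrt(2),
  db2 = c(0.48296291314469025, 0.836516303737469,
          0.22414386804185735, -0.12940952255092145),
  db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
          -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
          0.032883011666982945, -0.010597401784997278)
)

## Quadrature-mirror high-pass from the low-pass: g[k] = (-1)^k h[L-1-k].
qmf_highpass <- function(h) {
  L <- length(h)
  (-1)^(0:(L - 1)) * rev(h)
}

## One periodized analysis step (input length must be even).
dwt_step <- function(x, h, g) {
  N <- length(x)
  L <- length(h)
  half <- N %/% 2L
  a <- numeric(half)
  d <- numeric(half)
  for (n in seq_len(half)) {
    idx <- ((2L * (n - 1L) + 0:(L - 1L)) %% N) + 1L
    a[n] <- sum(h * x[idx])
    d[n] <- sum(g * x[idx])
  }
  list(a = a, d = d)
}

## One periodized synthesis step (adjoint of dwt_step; exact inverse for
## orthonormal filters).
idwt_step <- function(a, d, h, g) {
  half <- length(a)
  N <- 2L * half
  L <- length(h)
  x <- numeric(N)
  for (n in seq_len(half)) {
    idx <- ((2L * (n - 1L) + 0:(L - 1L)) %% N) + 1L
    x[idx] <- x[idx] + h * a[n] + g * d[n]
  }
  x
}

#' Discrete wavelet decomposition
#'
#' Pyramid decomposition: at each level the running approximation is
#' convolved with the scaling (low-pass) and wavelet (high-pass) filters
#' and downsampled by two, splitting the band in half. At a 20 Hz sampling
#' rate and 3 levels, the level-3 approximation A3 spans 0--1.25 Hz and the
#' level-3 detail D3 spans 1.25--2.5 Hz, so A3 and D3 together cover
#' 0--2.5 Hz (0--150 bpm), the band containing the HR.
#'
#' The transform is periodized (circular); the input is zero-padded to the
#' next multiple of `2^levels` internally and the original length is kept
#' so that reconstruction restores it. The filter pair is orthonormal, so
#' reconstruction from the full coefficient set is exact to rounding.
#'
#' @param x real signal vector, `length(x) >= 2^levels`.
#' @param levels decomposition depth (default 3).
#' @param wavelet `"db4"` (default), `"db2"`, or `"haar"`.
#' @return an object of class `wavelet_decomposition`: lists `approx`
#'   (`A_1..A_levels`) and `detail` (`D_1..D_levels`), the filters `h` and
#'   `g`, `levels`, `wavelet`, and the original length.
#' @export
#' @examples
#' x <- sin(2 * pi * 1.0 * (0:99) / 20)
#' dec <- dwt_decompose(x)
#' xr <- dwt_reconstruct(dec)
#' max(abs(xr - x))   # perfect reconstruction
dwt_decompose <- function(x, levels = 3, wavelet = "db4") {
  h <- WAVELET_FILTERS[[wavelet]]
  if (is.null(h)) stop("unknown wavelet '", wavelet, "'")
  if (length(x) < 2^levels)
    stop("signal of length ", length(x), " too short for ", levels, " levels")
  g <- qmf_highpass(h)
  n0 <- length(x)
  block <- 2^levels
  pad <- (block - n0 %% block) %% block
  a <- c(x, numeric(pad))
  approx <- vector("list", levels)
  detail <- vector("list", levels)
  for (j in seq_len(levels)) {
    s <- dwt_step(a, h, g)
    approx[[j]] <- s$a
    detail[[j]] <- s$d
    a <- s$a
  }
  structure(list(approx = approx, detail = detail, h = h, g = g,
                 levels = levels, wavelet = wavelet, n = n0),
            class = "wavelet_decomposition")
}

#' Inverse discrete wavelet transform
#'
#' Reconstructs the signal from the deepest approximation and the detail
#' coefficients, optionally zeroing chosen subbands.
#'
#' @param decomp a [dwt_decompose()] result.
#' @param keep_detail integer vector of detail levels to keep (others are
#'   zeroed); default all.
#' @param keep_approx keep the deepest approximation? Default `TRUE`.
#' @return reconstructed signal, same length as the input of
#'   [dwt_decompose()].
#' @export
dwt_reconstruct <- function(decomp, keep_detail = seq_len(decomp$levels),
                            keep_approx = TRUE) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  a <- decomp$approx[[decomp$levels]]
  if (!keep_approx) a <- numeric(length(a))
  for (j in rev(seq_len(decomp$levels))) {
    d <- decomp$detail[[j]]
    if (!(j %in% keep_detail)) d <- numeric(length(d))
    a <- idwt_step(a, d, decomp$h, decomp$g)
  }
  a[seq_len(decomp$n)]
}

#' Reconstruct the HR band (A3 + D3)
#'
#' Inverse transform keeping only the deepest approximation and deepest
#' detail band. With 3 levels at 20 Hz this retains 0--2.5 Hz
#' (0--150 bpm) and discards D1 (5--10 Hz) and D2 (2.5--5 Hz), leaving
#' solely the frequency band containing the HR.
#'
#' @param decomp a [dwt_decompose()] result with `levels >= 3`.
#' @return band-limited signal, same length as the original input.
#' @export
reconstruct_hr_band <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  if (decomp$levels < 3) stop("need a decomposition of at least 3 levels")
  dwt_reconstruct(decomp, keep_detail = decomp$levels)
}

#' Subband frequency edges of a dyadic decomposition
#'
#' @param fs sampling rate (Hz).
#' @param levels decomposition depth.
#' @return `data.frame(band, f_lo, f_hi)` for `A_levels` and
#'   `D_1..D_levels`.
#' @export
#' @examples
#' dwt_band_edges(20, 3)   # A3: 0-1.25 Hz, D3: 1.25-2.5 Hz
dwt_band_edges <- function(fs, levels) {
  bands <- data.frame(
    band = c(paste0("A", levels), paste0("D", seq_len(levels))),
    f_lo = c(0, fs / 2^(seq_len(levels) + 1)),
    f_hi = c(fs / 2^(levels + 1), fs / 2^seq_len(levels))
  )
  bands[order(bands$f_lo), ]
}
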