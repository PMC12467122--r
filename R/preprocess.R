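#' Range FFT (fast-time FFT) of a radar cube
#'
#' Applies a Hann window across each chirp and a one-sided FFT, resolving
#' targets in range. For a linear sweep of bandwidth `B`, bin `k`
#' (0-based) corresponds to range `k * c / (2 B)` when the ADC captures
#' the full chirp (`bin_spacing` is reported on the result).
#'
#' @param cube a `radar_cube`.
#' @param window fast-time window: `"hann"` (default) or `"rect"`.
#' @return an object of class `range_profiles`: complex matrix `profiles`
#'   (`n_frames x n_bins`, `n_bins = n_samples/2 + 1`), `bin_spacing` (m),
#'   `fs_slow` (Hz), and the originating `config`.
#' @export
range_fft <- function(cube, window = c("hann", "rect")) {
  stopifnot(inherits(cube, "radar_cube"))
  window <- match.arg(window)
  x <- cube$data
  if (!all(is.finite(x))) stop("cube contains non-finite samples")
  n <- ncol(x)
  stopifnot(n >= 8)
  w <- if (window == "hann") 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1))) else rep(1, n)
  xw <- x * matrix(w, nrow(x), n, byrow = TRUE)
  n_bins <- n %/% 2L + 1L
  profiles <- t(stats::mvfft(t(xw)))[, seq_len(n_bins), drop = FALSE]
  cfg <- cube$config
  ## bin k <-> beat frequency k*fs/n <-> range k * c*Tc*fs / (2*B*n)
  bin_spacing <- C_LIGHT * cfg$chirp_time * cfg$fs_fast /
    (2 * cfg$bandwidth * cfg$n_samples)
  structure(list(profiles = profiles, bin_spacing = bin_spacing,
                 fs_slow = cfg$fs_slow, window = window, config = cfg),
            class = "range_profiles")
}

#' Slow-time clutter filter
#'
#' Removes static reflections (seat, dashboard) by high-pass filtering each
#' range bin along slow time: the per-bin temporal mean is subtracted and a
#' zero-phase (forward-backward) Butterworth high-pass with the given
#' cutoff is applied. A constant bin is suppressed to numerical zero while
#' physiological modulation above ~0.5 Hz passes within 1 dB.
#'
#' @param profiles a `range_profiles`.
#' @param cutoff high-pass cutoff (Hz); default 0.1 Hz.
#' @param order Butterworth order (applied forward-backward).
#' @return filtered `range_profiles`; if the recording is shorter than
#'   three filter settling times (`3/cutoff` s) the result carries
#'   `attr(, "short_record") = TRUE`.
#' @export
clutter_filter <- function(profiles, cutoff = 0.1, order = 4) {
  stopifnot(inherits(profiles, "range_profiles"))
  fs <- profiles$fs_slow
  if (fs <= 2 * cutoff) stop("fs_slow must exceed 2*cutoff")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  padlen <- ceiling(3 * fs / cutoff)
  p <- profiles$profiles
  out <- apply(p, 2, function(col) {
    col <- col - mean(col)
    complex(real = filtfilt_pad(bf, Re(col), padlen),
            imaginary = filtfilt_pad(bf, Im(col), padlen))
  })
  profiles$profiles <- matrix(out, nrow = nrow(p))
  if (nrow(p) < 3 * fs / cutoff) {
    warning("recording shorter than 3 clutter-filter settling times")
    attr(profiles, "short_record") <- TRUE
  }
  profiles
}

#' Select the target range bin
#'
#' Picks the range bin with the maximum time-averaged absolute amplitude
#' inside a physical search range (default 0.2--1.5 m, the sun-visor to
#' chest geometry). One bin is used for the whole recording.
#'
#' @param profiles a `range_profiles`.
#' @param search_range two-element vector (m).
#' @return 1-based bin (column) index.
#' @export
select_range_bin <- function(profiles, search_range = c(0.2, 1.5)) {
  stopifnot(inherits(profiles, "range_profiles"), length(search_range) == 2)
  ranges <- (seq_len(ncol(profiles$profiles)) - 1) * profiles$bin_spacing
  inside <- which(ranges >= search_range[1] & ranges <= search_range[2])
  if (!length(inside)) stop("no range bin inside the search range [",
                            search_range[1], ", ", search_range[2], "] m")
  amp <- colMeans(Mod(profiles$profiles[, inside, drop = FALSE]))
  inside[which.max(amp)]
}

#' Extract the slow-time phase at a range bin
#'
#' The unwrapped angle of the complex slow-time series at the selected
#' bin. A chest displacement `dR` maps to a phase change
#' `dphi = 4 pi dR / lambda`; at 60 GHz (lambda ~5 mm) a 0.1 mm
#' micro-movement is a 14.4 degree phase shift, which is what makes
#' cardiac motion observable.
#'
#' @param profiles a `range_profiles`.
#' @param bin 1-based bin index (e.g. from [select_range_bin()]).
#' @return an object of class `phase_signal`: `phi` (rad, unwrapped),
#'   `fs` (Hz), `bin_index`, `lambda_c` (m), and `disp_scale`
#'   (`lambda_c / 4 pi`, m per rad).
#' @export
extract_phase <- function(profiles, bin) {
  stopifnot(inherits(profiles, "range_profiles"),
            bin >= 1, bin <= ncol(profiles$profiles))
  z <- profiles$profiles[, bin]
  bad <- which(Mod(z) == 0)
  if (length(bad))
    stop("zero amplitude at frame ", bad[1], " in bin ", bin,
         "; phase is undefined there")
  lambda_c <- C_LIGHT / profiles$config$f_center
  structure(list(phi = unwrap_phase(Arg(z)), fs = profiles$fs_slow,
                 bin_index = bin, lambda_c = lambda_c,
                 disp_scale = lambda_c / (4 * pi)),
            class = "phase_signal")
}

#' Band-pass the phase signal to the HR band
#'
#' Zero-phase Butterworth band-pass, default 0.5--3.0 Hz (30--180 bpm, the
#' typical HR range). Respiratory motion (0.1--0.5 Hz) and most
#' road-vibration energy outside the band are rejected.
#'
#' @param phi a `phase_signal`.
#' @param band two-element vector (Hz).
#' @param order Butterworth order (applied forward-backward).
#' @return filtered `phase_signal`.
#' @export
bandpass_hr <- function(phi, band = c(0.5, 3.0), order = 4) {
  stopifnot(inherits(phi, "phase_signal"), length(band) == 2,
            band[1] > 0, band[2] > band[1])
  if (phi$fs <= 2 * band[2]) stop("band exceeds Nyquist: fs = ", phi$fs, " Hz")
  bf <- signal::butter(order, band / (phi$fs / 2), type = "pass")
  ## the mean is removed first so a pure DC offset is rejected exactly
  x <- phi$phi - mean(phi$phi)
  phi$phi <- filtfilt_pad(bf, x, ceiling(3 * phi$fs / band[1]))
  phi
}

#' Robust (Hilbert-Kalman) smoothing of the phase signal
#'
#' Scalar Kalman filter with a constant-velocity state model and a
#' Huber-type weighted update: the innovation `nu` is scaled by
#' `w = min(1, delta * sqrt(S) / |nu|)` before the state correction, so
#' large residuals (outliers from body motion or unwrapping glitches) are
#' not excessively weighted. The envelope of the analytic signal scales the
#' measurement-noise variance adaptively: samples with a weak envelope
#' (low radar return) are trusted less.
#'
#' @param phi a `phase_signal` (typically the band-passed phase).
#' @param delta robustness threshold of the Huber weight (in units of
#'   innovation standard deviations); must be positive.
#' @param q process-noise spectral density; `NULL` = automatic
#'   (`100 * r * fs^3`, a light-touch setting whose tracking bandwidth
#'   comfortably covers the 0.5--3 Hz band).
#' @param r baseline measurement-noise variance; `NULL` = automatic (a
#'   robust MAD estimate from the first difference of the signal).
#' @param robust set `FALSE` for a classical (unweighted) update; used for
#'   comparison.
#' @return smoothed `phase_signal`.
#' @export
hilbert_kalman <- function(phi, delta = 1.5, q = NULL, r = NULL,
                           robust = TRUE) {
  stopifnot(inherits(phi, "phase_signal"))
  x <- phi$phi
  n <- length(x)
  if (n < 10) stop("need at least 10 samples")
  if (delta <= 0) stop("delta must be positive")
  dt <- 1 / phi$fs
  env <- Mod(analytic_signal(x))
  env_ref <- stats::median(env)
  w_env <- if (env_ref > 0) pmin(pmax((env_ref / pmax(env, 1e-12))^2, 0.25), 4)
           else rep(1, n)
  if (is.null(r)) {
    r <- (1.4826 * stats::mad(diff(x), constant = 1))^2 / 2
    r <- max(r, 1e-24)
  }
  if (is.null(q)) q <- 100 * r * phi$fs^3
  A <- matrix(c(1, 0, dt, 1), 2, 2)
  H <- matrix(c(1, 0), 1, 2)
  Q <- q * matrix(c(dt^3 / 3, dt^2 / 2, dt^2 / 2, dt), 2, 2)
  st <- c(x[1], 0)
  P <- diag(c(r, r / dt^2))
  out <- numeric(n)
  out[1] <- x[1]
  for (k in 2:n) {
    st <- A %*% st
    P <- A %*% P %*% t(A) + Q
    Rk <- r * w_env[k]
    S <- drop(H %*% P %*% t(H)) + Rk
    nu <- x[k] - drop(H %*% st)
    w <- if (robust && abs(nu) > 0) min(1, delta * sqrt(S) / abs(nu)) else 1
    K <- P %*% t(H) / S
    st <- st + K * (w * nu)
    P <- (diag(2) - K %*% H) %*% P
    out[k] <- st[1]
  }
  phi$phi <- out
  phi
}

#' First difference of the phase signal
#'
#' The phase-difference series is the pipeline's working signal: it
#' whitens the dominant low-frequency respiratory residual and is the
#' input of both estimation stages.
#'
#' @param phi a `phase_signal`.
#' @return an object of class `phase_difference`: `dphi` (rad, length
#'   `n - 1`) and `fs` (Hz).
#' @export
phase_difference <- function(phi) {
  stopifnot(inherits(phi, "phase_signal"), length(phi$phi) >= 2)
  structure(list(dphi = diff(phi$phi), fs = phi$fs),
            class = "phase_difference")
}
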