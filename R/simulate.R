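#' Radar acquisition configuration
#'
#' Describes one FMCW chirp sequence: a linear sweep from `f_start` to
#' `f_end` sampled at `fs_fast`, one (or more) chirps per frame, frames
#' repeated every `frame_rep` seconds. The defaults are the settings of a
#' commercial 60 GHz sensor operated from a sun visor: 58--63.5 GHz sweep
#' (bandwidth 5.5 GHz), 3 MHz ADC rate, 128 samples per chirp, 50 ms frame
#' repetition time (20 Hz slow-time rate), a single chirp per frame.
#'
#' @param f_start chirp start frequency (Hz).
#' @param f_end chirp end frequency (Hz); must exceed `f_start`.
#' @param fs_fast ADC sample rate within a chirp (Hz).
#' @param n_samples ADC samples per chirp.
#' @param frame_rep frame repetition time (s). Its reciprocal is the
#'   slow-time sampling rate and must exceed twice the upper edge of the
#'   HR band (3 Hz), i.e. `frame_rep < 1/6` s.
#' @param n_chirps_per_frame chirps per frame (slow time uses one chirp per
#'   frame; values > 1 are kept as metadata only).
#' @param duration recording length (s).
#' @return an object of class `radar_config` with derived fields
#'   `bandwidth`, `f_center`, `lambda_c` (wavelength at the centre
#'   frequency), `chirp_time` (`n_samples/fs_fast`), `fs_slow`
#'   (`1/frame_rep`) and `n_frames`.
#' @export
#' @examples
#' cfg <- radar_config(duration = 90)
#' cfg$n_frames      # 1800 frames at 50 ms
#' cfg$lambda_c      # ~4.93 mm at 60.75 GHz
radar_config <- function(f_start = 58e9, f_end = 63.5e9, fs_fast = 3e6,
                         n_samples = 128L, frame_rep = 0.05,
                         n_chirps_per_frame = 1L, duration = 90) {
  stopifnot(f_end > f_start, fs_fast > 0, n_samples >= 8, frame_rep > 0,
            duration > 0)
  chirp_time <- n_samples / fs_fast
  if (chirp_time > frame_rep)
    stop("chirp duration n_samples/fs_fast (", chirp_time,
         " s) exceeds the frame repetition time (", frame_rep, " s)")
  if (1 / frame_rep <= 2 * 3.0)
    stop("slow-time rate 1/frame_rep = ", 1 / frame_rep,
         " Hz violates the Nyquist requirement for the 0.5-3 Hz HR band")
  f_center <- (f_start + f_end) / 2
  structure(list(
    f_start = f_start, f_end = f_end, fs_fast = fs_fast,
    n_samples = as.integer(n_samples), frame_rep = frame_rep,
    n_chirps_per_frame = as.integer(n_chirps_per_frame), duration = duration,
    bandwidth = f_end - f_start, f_center = f_center,
    lambda_c = C_LIGHT / f_center, chirp_time = chirp_time,
    fs_slow = 1 / frame_rep, n_frames = as.integer(round(duration / frame_rep))
  ), class = "radar_config")
}

#' @export
print.radar_config <- function(x, ...) {
  cat("FMCW radar configuration\n")
  cat(sprintf("  sweep       : %.2f-%.2f GHz (B = %.2f GHz)\n",
              x$f_start / 1e9, x$f_end / 1e9, x$bandwidth / 1e9))
  cat(sprintf("  fast time   : %d samples at %.2f MHz (Tc = %.1f us)\n",
              x$n_samples, x$fs_fast / 1e6, x$chirp_time * 1e6))
  cat(sprintf("  slow time   : %.0f ms frame repetition (%.1f Hz), %d frames (%.0f s)\n",
              x$frame_rep * 1e3, x$fs_slow, x$n_frames, x$duration))
  invisible(x)
}

#' In-cabin scene configuration for the simulator
#'
#' Parameterizes the simulated thorax motion seen by the radar. The chest
#' displacement is the sum of a cardiac pulse train (peak-to-peak
#' `cardiac_amp`, typically 0.2--0.6 mm), a sinusoidal respiratory
#' component (peak-to-peak `resp_amp`, typically 4--12 mm at 0.1--0.5 Hz),
#' and band-limited Gaussian vehicle vibration in `vib_band`
#' (road-induced vertical body motion, mainly 0.5--5 Hz).
#'
#' @param range0 nominal chest distance from the radar (m); about 0.5 m for
#'   a sun-visor mounting.
#' @param hr_bpm heart-rate trace: either a single constant value in bpm or
#'   a two-column `data.frame`/matrix `(time_s, hr_bpm)` of control points
#'   interpolated piecewise-linearly.
#' @param cardiac_amp peak-to-peak cardiac chest displacement (m),
#'   within \[0, 1e-3\].
#' @param cardiac_shape `"pulse"` (raised-cosine pulse train, generating
#'   the harmonics seen in real cardiac displacement) or `"sinusoid"`.
#' @param cardiac_duty fraction of the cardiac cycle occupied by the pulse.
#' @param resp_rate respiratory rate (Hz).
#' @param resp_amp peak-to-peak respiratory displacement (m), within
#'   \[0, 2e-2\].
#' @param vib_band two-element vector (Hz): band of the vehicle vibration.
#' @param vib_rms RMS displacement of the vibration component (m).
#' @param noise_snr baseband signal-to-noise ratio in dB (`Inf` = no noise).
#' @param seed integer seed fixing all randomness of the scene.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(range0 = 0.5, hr_bpm = 72, cardiac_amp = 4e-4,
                         cardiac_shape = c("pulse", "sinusoid"),
                         cardiac_duty = 0.3, resp_rate = 0.25,
                         resp_amp = 8e-3, vib_band = c(0.5, 5),
                         vib_rms = 1e-4, noise_snr = 20, seed = 1L) {
  cardiac_shape <- match.arg(cardiac_shape)
  if (cardiac_amp < 0 || resp_amp < 0 || vib_rms < 0)
    stop("displacement amplitudes must be non-negative")
  if (cardiac_amp > 1e-3)
    stop("cardiac_amp ", cardiac_amp, " m is outside the physiological range [0, 1e-3] m")
  if (resp_amp > 2e-2)
    stop("resp_amp ", resp_amp, " m is outside the physiological range [0, 2e-2] m")
  stopifnot(length(vib_band) == 2, vib_band[1] > 0, vib_band[2] > vib_band[1],
            cardiac_duty > 0, cardiac_duty <= 1, resp_rate > 0)
  hr <- if (is.numeric(hr_bpm) && length(hr_bpm) == 1) {
    data.frame(time_s = 0, hr_bpm = hr_bpm)
  } else {
    hr <- as.data.frame(hr_bpm)
    names(hr) <- c("time_s", "hr_bpm")
    hr
  }
  if (any(hr$hr_bpm < 30 | hr$hr_bpm > 220))
    stop("hr trace leaves the physiological range [30, 220] bpm")
  structure(list(
    range0 = range0, hr = hr, cardiac_amp = cardiac_amp,
    cardiac_shape = cardiac_shape, cardiac_duty = cardiac_duty,
    resp_rate = resp_rate, resp_amp = resp_amp, vib_band = vib_band,
    vib_rms = vib_rms, noise_snr = noise_snr, seed = as.integer(seed)
  ), class = "scene_config")
}

## Piecewise-linear HR trace evaluation, constant beyond the control points.
hr_at <- function(scene, t) {
  h <- scene$hr
  if (nrow(h) == 1) return(rep(h$hr_bpm, length(t)))
  stats::approx(h$time_s, h$hr_bpm, xout = t, rule = 2)$y
}

#' Simulate thorax displacement over slow time
#'
#' Builds the chest displacement series `R(t) = range0 + cardiac(t) +
#' respiratory(t) + vibration(t)`. The cardiac component is a raised-cosine
#' pulse train (or sinusoid) whose instantaneous frequency follows the
#' scene's HR trace; the respiratory component is a sinusoid; the vibration
#' component is white Gaussian noise band-limited to `vib_band` and scaled
#' to `vib_rms`.
#'
#' @param scene a [scene_config()].
#' @param t_slow uniformly spaced slow-time stamps (s).
#' @param seed optional integer; when non-`NULL`, `set.seed(seed)` is
#'   called so the vibration draw is reproducible. Defaults to the scene
#'   seed.
#' @return a list with `displacement` (m, same length as `t_slow`) and
#'   `hr_bpm` (true instantaneous HR per sample).
#' @export
#' @examples
#' sc <- scene_config(vib_rms = 0, noise_snr = Inf)
#' d <- simulate_displacement(sc, seq(0, 10, by = 0.05))
#' range(d$displacement - sc$range0)   # sub-mm chest motion
simulate_displacement <- function(scene, t_slow, seed = scene$seed) {
  stopifnot(inherits(scene, "scene_config"), length(t_slow) >= 2)
  dt <- diff(t_slow)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("t_slow must be uniformly spaced")
  if (!is.null(seed)) set.seed(as.integer(seed))
  dt <- dt[1]
  hr <- hr_at(scene, t_slow)
  f_inst <- hr / 60
  ## cardiac phase: cumulative trapezoid of the instantaneous frequency
  theta <- 2 * pi * c(0, cumsum((f_inst[-1] + f_inst[-length(f_inst)]) / 2 * dt))
  cardiac <- if (scene$cardiac_amp > 0) {
    if (scene$cardiac_shape == "sinusoid") {
      scene$cardiac_amp / 2 * sin(theta)
    } else {
      u <- (theta / (2 * pi)) %% 1
      w <- ifelse(u < scene$cardiac_duty,
                  0.5 * (1 - cos(2 * pi * u / scene$cardiac_duty)), 0)
      scene$cardiac_amp * (w - mean(w))
    }
  } else numeric(length(t_slow))
  resp <- if (scene$resp_amp > 0) {
    scene$resp_amp / 2 * sin(2 * pi * scene$resp_rate * t_slow)
  } else numeric(length(t_slow))
  vib <- if (scene$vib_rms > 0) {
    fs <- 1 / dt
    w <- stats::rnorm(length(t_slow))
    bf <- signal::butter(2, scene$vib_band / (fs / 2), type = "pass")
    v <- filtfilt_pad(bf, w)
    v * scene$vib_rms / sqrt(mean(v^2))
  } else numeric(length(t_slow))
  list(displacement = scene$range0 + cardiac + resp + vib, hr_bpm = hr)
}

#' Synthesize raw FMCW baseband frames from a displacement series
#'
#' Each frame is one real-valued sampled beat tone: a target at range `R`
#' produces the intermediate frequency `f_b = 2 B R / (c T_c)` with phase
#' `4 pi f_start R / c` (start-frequency convention: after the windowed
#' range FFT the phase at the target bin is then `4 pi R / lambda_c`, the
#' displacement law at the sweep centre frequency). White Gaussian noise is
#' added at the configured SNR.
#'
#' @param displacement chest range per frame (m); length must equal
#'   `config$n_frames`.
#' @param config a [radar_config()].
#' @param noise_snr baseband SNR in dB (`Inf` disables noise).
#' @param seed optional integer seed for the noise draw.
#' @return an object of class `radar_cube`: list with `data`
#'   (`n_frames x n_samples` real matrix), `config`, and `t_slow`.
#' @export
synthesize_baseband <- function(displacement, config, noise_snr = Inf,
                                seed = NULL) {
  stopifnot(inherits(config, "radar_config"))
  if (length(displacement) != config$n_frames)
    stop("displacement length ", length(displacement),
         " != n_frames ", config$n_frames)
  r_max <- C_LIGHT * config$n_samples / (4 * config$bandwidth)
  if (max(displacement) >= r_max)
    stop(sprintf(
      "displacement reaches %.3f m, beyond the unambiguous range %.3f m",
      max(displacement), r_max))
  if (min(displacement) <= 0) stop("displacement must stay positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  t_fast <- (seq_len(config$n_samples) - 1) / config$fs_fast
  f_b <- 2 * config$bandwidth * displacement / (C_LIGHT * config$chirp_time)
  phi0 <- 4 * pi * config$f_start * displacement / C_LIGHT
  ## outer(): frame-by-sample phase matrix, one beat tone per frame
  data <- cos(outer(f_b, t_fast, function(f, t) 2 * pi * f * t) + phi0)
  if (is.finite(noise_snr)) {
    noise_sd <- sqrt(0.5 / 10^(noise_snr / 10))
    data <- data + matrix(stats::rnorm(length(data), sd = noise_sd),
                          nrow = nrow(data))
  }
  structure(list(
    data = data, config = config,
    t_slow = (seq_len(config$n_frames) - 1) * config$frame_rep
  ), class = "radar_cube")
}

#' @export
print.radar_cube <- function(x, ...) {
  cat(sprintf("radar_cube: %d frames x %d samples (%.1f s at %.1f Hz slow time)\n",
              nrow(x$data), ncol(x$data), x$config$duration, x$config$fs_slow))
  invisible(x)
}

#' Simulate a complete in-cabin recording with ground truth
#'
#' Convenience wrapper: seeds the RNG from the scene, simulates the chest
#' displacement on the radar's slow-time grid, synthesizes the baseband
#' cube at the scene's SNR, and samples the true HR trace at 1 Hz
#' (inclusive endpoints, emulating a chest-strap export).
#'
#' @param config a [radar_config()].
#' @param scene a [scene_config()].
#' @return list with `cube` (a `radar_cube`) and `truth`
#'   (`data.frame(time_s, hr_bpm)`).
#' @export
#' @examples
#' rec <- simulate_recording(radar_config(duration = 10), scene_config(seed = 7))
#' dim(rec$cube$data)   # 200 x 128
#' nrow(rec$truth)      # 11 samples: 0..10 s inclusive
simulate_recording <- function(config, scene) {
  t_slow <- (seq_len(config$n_frames) - 1) * config$frame_rep
  d <- simulate_displacement(scene, t_slow, seed = scene$seed)
  cube <- synthesize_baseband(d$displacement, config,
                              noise_snr = scene$noise_snr,
                              seed = scene$seed + 1L)
  t_truth <- seq(0, floor(config$duration), by = 1)
  truth <- data.frame(time_s = t_truth, hr_bpm = hr_at(scene, t_truth))
  list(cube = cube, truth = truth)
}
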