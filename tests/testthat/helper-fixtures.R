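## Shared fixtures: small, fast synthetic scenes built in code.

## Radar settings of the reference sensor (Table-2-style), short duration.
test_radar <- function(duration = 10, ...) {
  radar_config(duration = duration, ...)
}

## A radar configuration whose sweep is centred exactly at 60 GHz
## (lambda_c = c/60e9 ~ 5 mm), for the textbook phase-shift checks.
radar_60ghz <- function(duration = 0.1, ...) {
  radar_config(f_start = 57.25e9, f_end = 62.75e9, duration = duration, ...)
}

## Quiet scene: cardiac motion only.
cardiac_only_scene <- function(hr_bpm = 72, cardiac_amp = 4e-4, seed = 1,
                               ...) {
  scene_config(hr_bpm = hr_bpm, cardiac_amp = cardiac_amp, resp_amp = 0,
               vib_rms = 0, noise_snr = Inf, seed = seed, ...)
}

## Hand-built range_profiles object (bypasses the FFT) for selector tests.
fake_profiles <- function(profiles, bin_spacing = 0.0272538, fs_slow = 20) {
  structure(list(profiles = profiles, bin_spacing = bin_spacing,
                 fs_slow = fs_slow, window = "hann",
                 config = test_radar(duration = nrow(profiles) / fs_slow)),
            class = "range_profiles")
}

## Hand-built energy spectrum on an exact 0.01 Hz grid.
fake_energy <- function(freqs, energies,
                        grid = seq(0.5, 2.5, by = 0.01)) {
  e <- numeric(length(grid))
  for (i in seq_along(freqs)) e[which.min(abs(grid - freqs[i]))] <- energies[i]
  structure(list(f = grid, energy = e), class = "energy_spectrum")
}

## Batch Kalman oracle: one update with the stacked 2-vector measurement
## and diagonal noise; the sequential filter must match this exactly.
batch_kf_oracle <- function(x0, P0, Q, R0, R1, z0, z1) {
  P <- matrix(P0 + Q, 1, 1)          # predicted covariance (random walk)
  H <- matrix(c(1, 1), 2, 1)         # both measurements observe the state
  R <- diag(c(R0, R1))
  S <- H %*% P %*% t(H) + R
  K <- P %*% t(H) %*% solve(S)       # 1 x 2 gain
  x <- x0 + drop(K %*% (c(z0, z1) - drop(H %*% matrix(x0))))
  Pp <- (diag(1) - K %*% H) %*% P
  list(x = x, P = drop(Pp))
}
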