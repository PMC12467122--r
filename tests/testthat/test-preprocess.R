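test_that("range FFT basics: zero input, bin count, non-finite rejection", {
  cfg <- test_radar(duration = 0.5)
  zero <- structure(list(data = matrix(0, cfg$n_frames, cfg$n_samples),
                         config = cfg,
                         t_slow = (seq_len(cfg$n_frames) - 1) * 0.05),
                    class = "radar_cube")
  prof <- range_fft(zero)
  expect_true(all(Mod(prof$profiles) == 0))
  expect_equal(ncol(prof$profiles), 65L)   # 128/2 + 1 one-sided bins
  zero$data[3, 5] <- NaN
  expect_error(range_fft(zero), "non-finite")
})

test_that("clutter filter rejects static bins and passes the HR band", {
  fs <- 20
  n <- 1200
  t <- (0:(n - 1)) / fs
  static <- complex(real = rep(3, n), imaginary = rep(-2, n))
  tone <- complex(real = cos(2 * pi * 1.2 * t), imaginary = sin(2 * pi * 1.2 * t))
  prof <- fake_profiles(cbind(static, tone, deparse.level = 0))
  out <- clutter_filter(prof)   # default cutoff 0.1 Hz
  expect_lt(sqrt(mean(Mod(out$profiles[, 1])^2)), 1e-3 * Mod(static[1]))
  gain <- stats::sd(Re(out$profiles[, 2])) / stats::sd(Re(tone))
  expect_lt(abs(20 * log10(gain)), 1)   # 1.2 Hz preserved within 1 dB
  expect_equal(formals(clutter_filter)$cutoff, 0.1)
})

test_that("a short recording raises the settling-time warning flag", {
  prof <- fake_profiles(matrix(complex(real = rnorm(80), imaginary = rnorm(80)),
                               ncol = 2))
  expect_warning(out <- clutter_filter(prof), "settling")
  expect_true(attr(out, "short_record"))
})

test_that("range bin selection picks the strongest target in range", {
  m <- matrix(0 + 0i, 100, 65)
  m[, 12] <- 1 + 0i
  expect_equal(select_range_bin(fake_profiles(m)), 12L)
  ## two targets: the stronger one at 0.5 m wins
  cfg <- test_radar(duration = 1)
  c1 <- synthesize_baseband(rep(0.5, cfg$n_frames), cfg, noise_snr = Inf)
  c2 <- synthesize_baseband(rep(0.9, cfg$n_frames), cfg, noise_snr = Inf)
  c1$data <- c1$data + 0.4 * c2$data
  prof <- range_fft(c1)
  bin <- select_range_bin(prof)
  expect_equal((bin - 1) * prof$bin_spacing, 0.5, tolerance = 0.03)
  expect_error(select_range_bin(fake_profiles(m), c(10, 20)), "search range")
})

test_that("a 0.1 mm step at 60 GHz shifts the phase by 14.4 degrees", {
  cfg <- radar_60ghz()
  cube <- synthesize_baseband(c(0.5, 0.5 + 1e-4), cfg, noise_snr = Inf)
  prof <- range_fft(cube)
  ph <- extract_phase(prof, select_range_bin(prof))
  step_deg <- diff(ph$phi) * 180 / pi
  expect_equal(step_deg, 14.4, tolerance = 0.01)
})

test_that("phase extraction: static target and amplitude linearity", {
  cfg <- radar_60ghz(duration = 10)
  n <- cfg$n_frames
  t <- (0:(n - 1)) * cfg$frame_rep
  cube <- synthesize_baseband(rep(0.5, n), cfg, noise_snr = Inf)
  prof <- range_fft(cube)
  ph <- extract_phase(prof, select_range_bin(prof))
  expect_lt(stats::var(ph$phi), 1e-20)
  ## sinusoidal displacement a = 0.3 mm -> phase amplitude 4*pi*a/lambda
  for (a in c(3e-4, 1.5e-4)) {
    cube <- synthesize_baseband(0.5 + a * sin(2 * pi * 1.0 * t), cfg,
                                noise_snr = Inf)
    prof <- range_fft(cube)
    ph <- extract_phase(prof, select_range_bin(prof))
    amp <- (max(ph$phi) - min(ph$phi)) / 2
    expect_equal(amp, 4 * pi * a / cfg$lambda_c, tolerance = 0.02)
  }
  ## doubling displacement doubles the phase amplitude (linearity, 1%)
  amp_of <- function(a) {
    cube <- synthesize_baseband(0.5 + a * sin(2 * pi * 1.0 * t), cfg,
                                noise_snr = Inf)
    prof <- range_fft(cube)
    ph <- extract_phase(prof, select_range_bin(prof))
    (max(ph$phi) - min(ph$phi)) / 2
  }
  expect_equal(amp_of(4e-4) / amp_of(2e-4), 2, tolerance = 0.01)
})

test_that("zero-amplitude frames are reported by index", {
  m <- matrix(1 + 1i, 50, 65)
  m[17, 3] <- 0
  expect_error(extract_phase(fake_profiles(m), 3), "frame 17")
})

test_that("HR band-pass: DC rejection, passband, stopband, defaults", {
  fs <- 20
  t <- (0:1199) / fs
  mk <- function(x) structure(list(phi = x, fs = fs, bin_index = 1,
                                   lambda_c = 5e-3,
                                   disp_scale = 5e-3 / (4 * pi)),
                              class = "phase_signal")
  out <- bandpass_hr(mk(rep(4, length(t))))
  expect_lt(abs(mean(out$phi)), 1e-6 * 4)
  g <- function(f) {
    y <- bandpass_hr(mk(sin(2 * pi * f * t)))$phi
    stats::sd(y[200:1000]) / stats::sd(sin(2 * pi * f * t)[200:1000])
  }
  expect_lt(abs(20 * log10(g(1.2))), 1)
  expect_lt(20 * log10(g(0.2)), -20)
  expect_lt(20 * log10(g(5)), -30)
  expect_lt(20 * log10(g(0.1)), -30)
  expect_equal(eval(formals(bandpass_hr)$band), c(0.5, 3.0))
  expect_error(bandpass_hr(mk(t), band = c(0.5, 11)), "Nyquist")
})

test_that("zero-phase filtering keeps a symmetric pulse symmetric", {
  fs <- 20
  n <- 801
  pulse <- exp(-((seq_len(n) - 401) / 40)^2) * cos(2 * pi * 1.5 * (seq_len(n) - 401) / fs)
  mk <- structure(list(phi = pulse, fs = fs, bin_index = 1, lambda_c = 5e-3,
                       disp_scale = 5e-3 / (4 * pi)), class = "phase_signal")
  y <- bandpass_hr(mk)$phi
  expect_lt(max(abs(y - rev(y))), 1e-6 * max(abs(y)))
})

test_that("robust smoothing: exactness on constants, outlier suppression", {
  fs <- 20
  mk <- function(x) structure(list(phi = x, fs = fs, bin_index = 1,
                                   lambda_c = 5e-3,
                                   disp_scale = 5e-3 / (4 * pi)),
                              class = "phase_signal")
  out <- hilbert_kalman(mk(rep(2.5, 100)))
  expect_true(all(abs(out$phi[21:100] - 2.5) < 1e-9))
  ## a 10-sigma spike is corrected harder by the Huber weight than by the
  ## classical update
  set.seed(7)
  x <- sin(2 * pi * 1.2 * (0:499) / fs) + rnorm(500, 0, 0.05)
  x[250] <- x[250] + 10 * 0.05 * 10
  rob <- hilbert_kalman(mk(x), robust = TRUE)$phi
  std <- hilbert_kalman(mk(x), robust = FALSE)$phi
  clean <- sin(2 * pi * 1.2 * (0:499) / fs)
  expect_lt(abs(rob[250] - clean[250]), abs(std[250] - clean[250]))
  expect_error(hilbert_kalman(mk(x), delta = 0), "delta")
})

test_that("phase differencing matches its closed forms", {
  mk <- function(x) structure(list(phi = x, fs = 20, bin_index = 1,
                                   lambda_c = 5e-3,
                                   disp_scale = 5e-3 / (4 * pi)),
                              class = "phase_signal")
  expect_equal(phase_difference(mk(rep(1.3, 50)))$dphi, rep(0, 49))
  expect_equal(phase_difference(mk(0.2 * (0:49)))$dphi, rep(0.2, 49))
  ## differencing scales a tone's RMS by |2 sin(pi f / fs)|
  t <- (0:999) / 20
  tone <- sin(2 * pi * 1.0 * t)
  d <- phase_difference(mk(tone))$dphi
  expect_equal(sqrt(mean(d^2)) / sqrt(mean(tone^2)), 2 * sin(pi * 1.0 / 20),
               tolerance = 1e-3)
  expect_equal(length(d), 999L)
})

test_that("simulate -> preprocess recovers the cardiac tone", {
  ## sinusoidal cardiac motion: a single line at HR/60, so the raw FFT of
  ## the phase difference must peak there (the pulse-train shape instead
  ## puts deliberate harmonic energy at 2x, which Stage 1's rules handle)
  cfg <- test_radar(duration = 30)
  sc <- cardiac_only_scene(hr_bpm = 84, seed = 5, cardiac_shape = "sinusoid")
  rec <- simulate_recording(cfg, sc)
  prof <- clutter_filter(range_fft(rec$cube))
  ph <- bandpass_hr(extract_phase(prof, select_range_bin(prof)))
  d <- phase_difference(ph)$dphi
  spec <- Mod(stats::fft(d - mean(d)))^2
  fr <- (seq_along(d) - 1) * 20 / length(d)
  sel <- fr >= 0.5 & fr <= 3
  f_dom <- fr[sel][which.max(spec[sel])]
  expect_lt(abs(f_dom - 84 / 60), 20 / length(d) + 1e-12)
})
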