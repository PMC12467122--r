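test_that("Burg order-0 limit returns the sample variance", {
  set.seed(21)
  x <- rnorm(1000, sd = 2)
  m <- burg_ar(x, order = 0)
  expect_equal(m$noise_var, stats::var(x), tolerance = 0.1)
})

test_that("Burg recovers AR(2) coefficients and improves with n", {
  ## generating model: x[n] = 1.0 x[n-1] - 0.5 x[n-2] + e[n]
  gen <- function(n, seed) {
    set.seed(seed)
    as.numeric(stats::filter(rnorm(n + 200), c(1.0, -0.5),
                             method = "recursive"))[-(1:200)]
  }
  truth <- c(-1.0, 0.5)   # alpha convention: x[n] = -sum alpha_k x[n-k] + e
  m2000 <- burg_ar(gen(2000, 31), order = 2)
  expect_lt(max(abs(m2000$coeffs - truth)), 0.05)
  err <- function(n) max(abs(burg_ar(gen(n, 31), order = 2)$coeffs - truth))
  expect_lt(err(2000), err(500) + 0.01)
  ## Burg construction is stable: characteristic roots inside unit circle
  expect_true(all(Mod(polyroot(c(1, m2000$coeffs))) > 1))
})

test_that("a short noisy tone is localized within 0.05 Hz", {
  set.seed(5)
  t <- (0:99) / 20
  x <- sin(2 * pi * 1.2 * t) + rnorm(100, 0, 0.05)
  spec <- ar_psd(burg_ar(x, order = 12))
  expect_lt(abs(spec$freqs[which.max(spec$psd)] - 1.2), 0.05)
})

test_that("model-order preconditions are enforced", {
  expect_error(burg_ar(rnorm(20), order = -1), "order")
  expect_error(burg_ar(rnorm(20), order = 10), "order")
})

test_that("AR spectrum: flat order-0 limit and variance matching", {
  m0 <- burg_ar(rnorm(100), order = 0)
  spec0 <- ar_psd(m0, seq(0, 10, length.out = 64))
  expect_equal(spec0$psd, rep(m0$noise_var, 64))
  ## PSD of a fitted AR(2) integrates to the process variance (10%)
  set.seed(41)
  x <- as.numeric(stats::filter(rnorm(4200), c(1.0, -0.5),
                                method = "recursive"))[-(1:200)]
  m <- burg_ar(x, order = 2)
  grid <- seq(0, 10, length.out = 4096)
  spec <- ar_psd(m, grid)
  ## two-sided symmetry: total variance = 2 * integral over [0, fs/2] / fs
  v <- 2 * sum((spec$psd[-1] + spec$psd[-4096]) / 2 * diff(grid)) / 20
  expect_equal(v, stats::var(x), tolerance = 0.1)
  expect_true(all(spec$psd > 0))
  expect_error(ar_psd(m, seq(0, 11, by = 1)), "fs/2")
})

test_that("peak detection: monotone spectra and two-bump placement", {
  grid <- seq(0.5, 2.5, length.out = 512)
  mono <- structure(list(freqs = grid, psd = exp(-grid)),
                    class = "spectrum_estimate")
  expect_equal(nrow(detect_peaks(mono)), 0L)
  bumps <- exp(-((grid - 1.0) / 0.05)^2) + 0.8 * exp(-((grid - 2.0) / 0.05)^2)
  two <- structure(list(freqs = grid, psd = bumps),
                   class = "spectrum_estimate")
  pk <- detect_peaks(two)
  expect_equal(nrow(pk), 2L)
  step <- diff(grid)[1]
  expect_lt(abs(pk$freq[1] - 1.0), step + 1e-12)
  expect_lt(abs(pk$freq[2] - 2.0), step + 1e-12)
})

test_that("peak decision follows the shipped rule table", {
  cfg <- stage1_config()
  one <- data.frame(freq = 1.3, amplitude = 2, prominence = 2)
  expect_equal(peak_decision(one, config = cfg)$f0, 1.3)
  expect_equal(peak_decision(one, config = cfg)$rule_applied, "single")
  ## harmonic pair 0.9/1.8: both f_low and f_high/2 estimate 0.9 Hz
  harm <- data.frame(freq = c(0.9, 1.8), amplitude = c(1, 2),
                     prominence = c(1, 2))
  d <- peak_decision(harm, config = cfg)
  expect_equal(d$f0, 0.9)
  expect_equal(d$rule_applied, "H1")
  ## near-equal amplitudes at 1.10/1.20 -> mean 1.15
  near <- data.frame(freq = c(1.10, 1.20), amplitude = c(1.0, 1.1),
                     prominence = c(1, 1))
  d2 <- peak_decision(near, config = cfg)
  expect_equal(d2$f0, 1.15)
  expect_equal(d2$rule_applied, "M1")
  ## no peaks -> invalid estimate without f0
  empty <- peak_decision(data.frame(freq = numeric(),
                                    amplitude = numeric(),
                                    prominence = numeric()), config = cfg)
  expect_false(empty$valid)
  expect_true(is.na(empty$f0))
  ## determinism: a pure function of peaks, history, config
  expect_identical(peak_decision(near, history = c(1.1, 1.2), config = cfg),
                   peak_decision(near, history = c(1.1, 1.2), config = cfg))
})

test_that("plausibility gate suppresses implausible jumps", {
  cfg <- stage1_config()
  mk <- function(f0) structure(list(f0 = f0, n_peaks_detected = 1L,
                                    rule_applied = "single", valid = TRUE),
                               class = "coarse_estimate")
  expect_true(plausibility_check(mk(2.0), numeric(), cfg)$valid)
  hist <- c(72, 73, 72) / 60
  expect_false(plausibility_check(mk(120 / 60), hist, cfg)$valid)
  expect_true(plausibility_check(mk(78 / 60), hist, cfg)$valid)
})

test_that("stage 1 finds a clean cardiac line on one chunk", {
  set.seed(13)
  t <- (0:99) / 20
  chunk <- 0.3 * sin(2 * pi * 1.2 * t + 0.4) + rnorm(100, 0, 0.03)
  est <- stage1_estimate(chunk, 20)
  expect_true(est$valid)
  expect_lt(abs(est$f0 - 1.2) * 60, 5)
})
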