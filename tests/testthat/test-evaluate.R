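test_that("alignment averages the reference samples inside each chunk", {
  est <- data.frame(t_start_s = c(0, 5, 10), hr_bpm = c(70, 71, 72))
  ref <- data.frame(time_s = 0:14, hr_bpm = 60 + (0:14))
  pairs <- align_traces(est, ref)
  expect_equal(pairs$ref, c(mean(60:64), mean(65:69), mean(70:74)))
  expect_equal(attr(pairs, "n_dropped"), 0L)
  ## identical grids pass through
  est2 <- data.frame(t_start_s = c(0, 5), hr_bpm = c(70, 71))
  ref2 <- data.frame(time_s = c(0, 5), hr_bpm = c(65, 66))
  expect_equal(align_traces(est2, ref2)$ref, c(65, 66))
  ## shifted reference: interval intersection, hand-computed means
  ref3 <- data.frame(time_s = 0:14 + 2.5, hr_bpm = 60 + (0:14))
  pairs3 <- align_traces(est, ref3)
  ## chunk [0,5): ref times 2.5,3.5,4.5 -> samples 60,61,62
  expect_equal(pairs3$ref,
               c(mean(60:62), mean(63:67), mean(68:72)))
  expect_error(align_traces(est, data.frame(time_s = 100, hr_bpm = 70)),
               "overlap")
})

test_that("MAE and MRE match their definitions", {
  same <- structure(data.frame(t = 0:4, est = 61:65, ref = 61:65),
                    class = c("aligned_pairs", "data.frame"))
  expect_equal(mae_mre(same), list(mae = 0, mre = 0))
  off <- structure(data.frame(t = 0:4, est = rep(66, 5), ref = rep(60, 5)),
                   class = c("aligned_pairs", "data.frame"))
  expect_equal(mae_mre(off), list(mae = 6, mre = 10))
  ## naive loop oracle on random pairs
  set.seed(33)
  p <- structure(data.frame(t = 1:50, est = runif(50, 55, 100),
                            ref = runif(50, 55, 100)),
                 class = c("aligned_pairs", "data.frame"))
  mm <- mae_mre(p)
  mae_o <- 0; mre_o <- 0
  for (i in 1:50) {
    mae_o <- mae_o + abs(p$est[i] - p$ref[i]) / 50
    mre_o <- mre_o + abs(p$est[i] - p$ref[i]) / p$ref[i] * 100 / 50
  }
  expect_equal(mm$mae, mae_o, tolerance = 1e-12)
  expect_equal(mm$mre, mre_o, tolerance = 1e-12)
  expect_error(mae_mre(structure(data.frame(t = 1, est = 1, ref = 0),
                                 class = c("aligned_pairs", "data.frame"))),
               "zero")
})

test_that("out-of-SD gating counts errors against the period SD", {
  same <- structure(data.frame(t = 0:4, est = 60 + 2 * (0:4),
                               ref = 60 + 2 * (0:4)),
                    class = c("aligned_pairs", "data.frame"))
  oos <- out_of_sd_errors(same)
  expect_equal(oos$out1$count, 0L)
  expect_equal(oos$out2$count, 0L)
  ## ref {60,62,64,66,68}, SD ~ 3.16: one chunk off by 10 trips both gates
  p <- structure(data.frame(t = 0:4, est = c(60, 62, 74, 66, 68),
                            ref = c(60, 62, 64, 66, 68)),
                 class = c("aligned_pairs", "data.frame"))
  oos2 <- out_of_sd_errors(p)
  expect_equal(oos2$ref_sd, sd(c(60, 62, 64, 66, 68)))
  expect_equal(oos2$out1$count, 1L)
  expect_equal(oos2$out2$count, 1L)
  expect_equal(oos2$out1$mae, 10)
  ## nested thresholds: 2 SD errors are a subset of 1 SD errors
  set.seed(44)
  for (rep in 1:10) {
    q <- structure(data.frame(t = 1:30, est = 70 + rnorm(30, 0, 8),
                              ref = 70 + rnorm(30, 0, 4)),
                   class = c("aligned_pairs", "data.frame"))
    o <- out_of_sd_errors(q)
    expect_lte(o$out2$count, o$out1$count)
  }
  ## degenerate constant reference: flagged, 1 bpm absolute tolerance
  dg <- structure(data.frame(t = 0:3, est = c(70, 70.5, 72, 70),
                             ref = rep(70, 4)),
                  class = c("aligned_pairs", "data.frame"))
  od <- out_of_sd_errors(dg)
  expect_true(od$degenerate_sd)
  expect_equal(od$out1$count, 1L)
})

test_that("Bland-Altman limits follow the textbook formulas", {
  same <- structure(data.frame(t = 0:3, est = c(60, 62, 64, 66),
                               ref = c(60, 62, 64, 66)),
                    class = c("aligned_pairs", "data.frame"))
  ba0 <- bland_altman(same)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  p <- structure(data.frame(t = 0:2, est = c(59, 60, 61), ref = rep(60, 3)),
                 class = c("aligned_pairs", "data.frame"))
  ba <- bland_altman(p)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(c(ba$loa_low, ba$loa_high), c(-1.96, 1.96))
  ## formula oracle on random input
  set.seed(55)
  q <- structure(data.frame(t = 1:40, est = rnorm(40, 70, 6),
                            ref = rnorm(40, 70, 3)),
                 class = c("aligned_pairs", "data.frame"))
  bq <- bland_altman(q)
  d <- q$est - q$ref
  expect_equal(bq$bias, mean(d), tolerance = 1e-12)
  expect_equal(bq$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
})

test_that("Pearson agreement matches the covariance formula", {
  p <- structure(data.frame(t = 0:4, est = c(60, 64, 66, 70, 75),
                            ref = c(60, 64, 66, 70, 75)),
                 class = c("aligned_pairs", "data.frame"))
  expect_equal(pearson_agreement(p)$r, 1)
  neg <- structure(data.frame(t = 0:4, est = 140 - c(60, 64, 66, 70, 75),
                              ref = c(60, 64, 66, 70, 75)),
                   class = c("aligned_pairs", "data.frame"))
  expect_equal(pearson_agreement(neg)$r, -1)
  set.seed(66)
  q <- structure(data.frame(t = 1:30, est = rnorm(30, 70, 5),
                            ref = rnorm(30, 70, 5)),
                 class = c("aligned_pairs", "data.frame"))
  r_oracle <- sum((q$est - mean(q$est)) * (q$ref - mean(q$ref))) /
    sqrt(sum((q$est - mean(q$est))^2) * sum((q$ref - mean(q$ref))^2))
  expect_equal(pearson_agreement(q)$r, r_oracle, tolerance = 1e-12)
  cst <- structure(data.frame(t = 0:3, est = rep(70, 4), ref = 60:63),
                   class = c("aligned_pairs", "data.frame"))
  expect_error(pearson_agreement(cst), "constant")
})

test_that("metrics are invariant under a common time shift", {
  set.seed(77)
  est <- data.frame(t_start_s = seq(0, 85, by = 5), hr_bpm = 70 + rnorm(18, 0, 3))
  ref <- data.frame(time_s = 0:89, hr_bpm = 70 + sin((0:89) / 10))
  r1 <- agreement_report(align_traces(est, ref))
  est2 <- est; est2$t_start_s <- est2$t_start_s + 1000
  ref2 <- ref; ref2$time_s <- ref2$time_s + 1000
  r2 <- agreement_report(align_traces(est2, ref2))
  expect_equal(r1$mae, r2$mae)
  expect_equal(r1$bias, r2$bias)
  expect_equal(r1$r, r2$r)
})

test_that("limits of agreement widen monotonically with added noise", {
  ref <- data.frame(time_s = 0:89, hr_bpm = 70 + sin((0:89) / 7))
  base <- data.frame(t_start_s = seq(0, 85, by = 5), hr_bpm = rep(70, 18))
  widths <- sapply(c(0, 2, 5, 9), function(s) {
    set.seed(88)
    est <- base
    est$hr_bpm <- est$hr_bpm + rnorm(18, 0, s)
    ba <- bland_altman(align_traces(est, ref))
    ba$loa_high - ba$loa_low
  })
  expect_true(all(diff(widths) > 0))
})
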