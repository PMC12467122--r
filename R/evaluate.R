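#' Align an estimated HR trace with a reference trace
#'
#' For every chunk interval `[t_start, t_start + chunk_len)` the reference
#' value is the mean of all reference samples falling inside the interval
#' (chest-strap exports are typically 1 Hz, so a 5 s chunk averages 5
#' samples). Chunks containing no reference sample are dropped and
#' counted.
#'
#' @param est `data.frame(t_start_s, hr_bpm)`: one estimate per chunk.
#' @param ref `data.frame(time_s, hr_bpm)`: the reference trace.
#' @param chunk_len_s chunk length (s).
#' @return an object of class `aligned_pairs`:
#'   `data.frame(t, est, ref)`, with `attr(, "n_dropped")`.
#' @export
align_traces <- function(est, ref, chunk_len_s = 5) {
  stopifnot(all(c("t_start_s", "hr_bpm") %in% names(est)),
            all(c("time_s", "hr_bpm") %in% names(ref)))
  ref_mean <- vapply(est$t_start_s, function(t0) {
    sel <- ref$time_s >= t0 & ref$time_s < t0 + chunk_len_s
    if (!any(sel)) NA_real_ else mean(ref$hr_bpm[sel])
  }, numeric(1))
  keep <- !is.na(ref_mean) & !is.na(est$hr_bpm)
  if (!any(keep)) stop("estimate and reference have no overlapping support")
  out <- data.frame(t = est$t_start_s[keep], est = est$hr_bpm[keep],
                    ref = ref_mean[keep])
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("aligned_pairs", "data.frame")
  out
}

#' Mean absolute and mean relative error
#'
#' `MAE = mean(|est - ref|)` (bpm); `MRE = mean(|est - ref| / ref) * 100`
#' (percent).
#'
#' @param pairs an [align_traces()] result (columns `est`, `ref`).
#' @return `list(mae, mre)`.
#' @export
mae_mre <- function(pairs) {
  stopifnot(nrow(pairs) >= 1)
  if (any(pairs$ref == 0)) stop("reference contains zeros; MRE undefined")
  err <- abs(pairs$est - pairs$ref)
  list(mae = mean(err), mre = mean(err / pairs$ref) * 100)
}

#' Out-of-SD error counting
#'
#' An estimate counts as an error only when it deviates from the reference
#' by more than `k` standard deviations of the reference HR over the
#' measurement period (`k = 1` and `k = 2`). Reported are the counts,
#' rates, and the MAE/MRE restricted to the error chunks. With
#' `scope = "per_recording"` (default) the SD is that of the supplied
#' pairs, read as one recording; pre-pooled pairs can be assessed with
#' `scope = "pooled"` (identical arithmetic, different intent).
#'
#' @param pairs an [align_traces()] result.
#' @param scope `"per_recording"` or `"pooled"` (documentation of intent;
#'   the SD is always computed over the rows given).
#' @return list with `ref_sd`, and per threshold (`out1`, `out2`):
#'   `count`, `rate`, `mae`, `mre`. A degenerate period (`SD = 0`) is
#'   flagged via `degenerate_sd` and assessed with a 1 bpm absolute
#'   tolerance.
#' @export
out_of_sd_errors <- function(pairs, scope = c("per_recording", "pooled")) {
  scope <- match.arg(scope)
  stopifnot(nrow(pairs) >= 2)
  ref_sd <- stats::sd(pairs$ref)
  degenerate <- ref_sd == 0
  err <- abs(pairs$est - pairs$ref)
  gate <- function(k) {
    thr <- if (degenerate) 1 else k * ref_sd
    sel <- err > thr
    sub <- pairs[sel, , drop = FALSE]
    list(count = sum(sel), rate = mean(sel),
         mae = if (any(sel)) mean(abs(sub$est - sub$ref)) else 0,
         mre = if (any(sel)) mean(abs(sub$est - sub$ref) / sub$ref) * 100 else 0)
  }
  list(ref_sd = ref_sd, degenerate_sd = degenerate, scope = scope,
       out1 = gate(1), out2 = gate(2))
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = est - ref`; bias is `mean(d)` and the 95% limits of
#' agreement are `bias +/- 1.96 * sd(d)`.
#'
#' @param pairs an [align_traces()] result.
#' @return `list(bias, sd_diff, loa_low, loa_high)`.
#' @export
bland_altman <- function(pairs) {
  stopifnot(nrow(pairs) >= 2)
  d <- pairs$est - pairs$ref
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd_diff = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Pearson correlation between estimate and reference
#'
#' Sample Pearson `r` with the two-sided t-distribution p-value, via
#' [stats::cor.test()].
#'
#' @param pairs an [align_traces()] result.
#' @return `list(r, p_value)`.
#' @export
pearson_agreement <- function(pairs) {
  stopifnot(nrow(pairs) >= 3)
  if (stats::sd(pairs$est) == 0 || stats::sd(pairs$ref) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(pairs$est, pairs$ref, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Full agreement report
#'
#' Combines [mae_mre()], [out_of_sd_errors()], [bland_altman()], and
#' [pearson_agreement()] into one summary.
#'
#' @param pairs an [align_traces()] result.
#' @param scope SD scope for the out-of-SD gating.
#' @return an object of class `agreement_report` (a named list).
#' @export
agreement_report <- function(pairs, scope = "per_recording") {
  mm <- mae_mre(pairs)
  oos <- out_of_sd_errors(pairs, scope)
  ba <- bland_altman(pairs)
  ## constant traces (e.g. a constant-HR simulation) have no defined r
  pr <- tryCatch(pearson_agreement(pairs),
                 error = function(e) list(r = NA_real_, p_value = NA_real_))
  structure(c(mm, list(ref_sd = oos$ref_sd, out1 = oos$out1,
                       out2 = oos$out2, degenerate_sd = oos$degenerate_sd),
              ba, pr, list(n = nrow(pairs))),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report (", x$n, " chunk pairs)\n", sep = "")
  cat(sprintf("  MAE  %.2f bpm   MRE  %.2f %%\n", x$mae, x$mre))
  cat(sprintf("  out-of-1SD %d (%.0f %%)   out-of-2SD %d (%.0f %%)   ref SD %.2f bpm\n",
              x$out1$count, 100 * x$out1$rate, x$out2$count,
              100 * x$out2$rate, x$ref_sd))
  cat(sprintf("  Bland-Altman bias %.2f bpm, LoA [%.2f, %.2f] bpm\n",
              x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  Pearson r %.3f (p = %.3g)\n", x$r, x$p_value))
  invisible(x)
}
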