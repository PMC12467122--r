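#' Burg autoregressive model fit
#'
#' Fits an AR(p) model `x[n] = -sum_k alpha_k x[n-k] + e[n]` by Burg's
#' method (minimizing forward plus backward prediction error), which gives
#' high-resolution spectra on the short 5 s windows used here. The fit is
#' delegated to [stats::ar.burg()]; the coefficients are reported in the
#' sign convention above, and the Burg lattice construction guarantees all
#' characteristic roots strictly inside the unit circle.
#'
#' @param x signal vector (de-meaned internally).
#' @param order model order `p`; must satisfy `0 <= p < length(x)/2`.
#' @param fs sampling rate (Hz), carried for spectrum evaluation.
#' @return an object of class `ar_model`: `order`, `coeffs` (the
#'   `alpha_k`), `noise_var` (innovation variance), `fs`.
#' @export
burg_ar <- function(x, order = 12, fs = 20) {
  n <- length(x)
  if (order < 0 || (order > 0 && n <= 2 * order))
    stop("order must satisfy 0 <= p < length(x)/2 (p = ", order,
         ", n = ", n, ")")
  x <- x - mean(x)
  if (order == 0) {
    coeffs <- numeric(0)
    noise_var <- mean(x^2)
  } else {
    fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = FALSE)
    coeffs <- -fit$ar
    noise_var <- fit$var.pred
  }
  if (!is.finite(noise_var) || noise_var <= 0) noise_var <- .Machine$double.eps
  structure(list(order = order, coeffs = coeffs, noise_var = noise_var,
                 fs = fs), class = "ar_model")
}

#' Power spectral density of an AR model
#'
#' Evaluates `P(f) = sigma_e^2 / |1 + sum_k alpha_k exp(-i 2 pi f k / fs)|^2`
#' on a frequency grid. The default grid spans 0.5--2.5 Hz (30--150 bpm)
#' with 512 points, the display band in which the HR peak patterns appear.
#'
#' @param model an [burg_ar()] fit.
#' @param freqs frequency grid (Hz) within `[0, fs/2]`.
#' @return an object of class `spectrum_estimate`: `freqs`, `psd`
#'   (strictly positive), and an empty `peaks` slot filled by
#'   [detect_peaks()].
#' @export
ar_psd <- function(model, freqs = seq(0.5, 2.5, length.out = 512)) {
  stopifnot(inherits(model, "ar_model"), length(freqs) >= 1)
  if (any(freqs < 0 | freqs > model$fs / 2))
    stop("frequency grid must lie within [0, fs/2]")
  denom <- if (model$order == 0) rep(1, length(freqs)) else {
    E <- exp(-2i * pi * outer(freqs / model$fs, seq_len(model$order)))
    Mod(1 + drop(E %*% model$coeffs))^2
  }
  structure(list(freqs = freqs, psd = model$noise_var / denom,
                 peaks = NULL), class = "spectrum_estimate")
}

#' Detect spectral peaks
#'
#' Local maxima of the PSD with topographic prominence of at least
#' `min_prominence_frac` times the spectrum maximum, sorted by ascending
#' frequency. These peaks form the 1- to 4-peak patterns on which the
#' coarse decision logic operates.
#'
#' @param spec a `spectrum_estimate` (or any list with `freqs`, `psd`).
#' @param min_prominence_frac prominence threshold as a fraction of
#'   `max(psd)`; default 0.05.
#' @return `data.frame(freq, amplitude, prominence)` sorted by frequency.
#' @export
detect_peaks <- function(spec, min_prominence_frac = 0.05) {
  stopifnot(length(spec$psd) >= 3)
  pk <- find_local_peaks(spec$psd)
  pk <- pk[pk$prominence >= min_prominence_frac * max(spec$psd), , drop = FALSE]
  out <- data.frame(freq = spec$freqs[pk$index], amplitude = pk$value,
                    prominence = pk$prominence)
  out[order(out$freq), , drop = FALSE]
}

#' Default Stage 1 configuration
#'
#' Tunables of the coarse estimation stage. `harmonic_ratio` bounds the
#' frequency ratio treated as a fundamental/second-harmonic pair;
#' `equal_amp_ratio` is the amplitude ratio below which two peaks are
#' averaged; `harmonic_tol` is the relative tolerance of the 3--4-peak
#' harmonic pruning; `hr_band` gates the plausible coarse estimates;
#' `jump_limit_bpm` bounds the step against the recent history.
#'
#' @param levels,wavelet wavelet decomposition depth and family.
#' @param ar_order Burg model order for 100-sample chunks.
#' @param grid_n points of the AR spectrum evaluation grid.
#' @param min_prominence_frac peak prominence threshold.
#' @param harmonic_ratio two-element range of `f_high/f_low` treated as a
#'   harmonic pair.
#' @param equal_amp_ratio amplitude ratio under which two peaks count as
#'   near-equal and are averaged.
#' @param harmonic_tol relative tolerance for pruning peaks near twice a
#'   lower peak.
#' @param hr_band plausible coarse-estimate band (Hz).
#' @param jump_limit_bpm maximum plausible jump against the history median.
#' @param history_n number of accepted estimates the plausibility check
#'   looks back over.
#' @return named list of settings.
#' @export
stage1_config <- function(levels = 3, wavelet = "db4", ar_order = 16,
                          grid_n = 512, min_prominence_frac = 0.05,
                          harmonic_ratio = c(1.65, 2.35),
                          equal_amp_ratio = 1.25, harmonic_tol = 0.1,
                          hr_band = c(0.5, 2.5), jump_limit_bpm = 15,
                          history_n = 3) {
  list(levels = levels, wavelet = wavelet, ar_order = ar_order,
       grid_n = grid_n, min_prominence_frac = min_prominence_frac,
       harmonic_ratio = harmonic_ratio, equal_amp_ratio = equal_amp_ratio,
       harmonic_tol = harmonic_tol, hr_band = hr_band,
       jump_limit_bpm = jump_limit_bpm, history_n = history_n)
}

## Two-peak decision: harmonic pair -> fundamental; near-equal amplitudes
## -> mean; otherwise the stronger peak.
decide_two_peaks <- function(p, config) {
  ratio <- p$freq[2] / p$freq[1]
  if (ratio >= config$harmonic_ratio[1] && ratio <= config$harmonic_ratio[2]) {
    ## harmonic pair: f_low and f_high/2 are two estimates of the same
    ## fundamental (the harmonic is usually the sharper peak); average them
    return(list(f0 = mean(c(p$freq[1], p$freq[2] / 2)), rule = "H1"))
  }
  amp_ratio <- max(p$amplitude) / min(p$amplitude)
  if (amp_ratio < config$equal_amp_ratio)
    return(list(f0 = mean(p$freq), rule = "M1"))
  list(f0 = p$freq[which.max(p$amplitude)], rule = "A1")
}

#' Coarse peak decision
#'
#' Maps a detected peak pattern to a single coarse HR estimate `f0`.
#' Selecting the highest peak alone is unreliable (harmonics of the
#' heartbeat and respiration intermodulation often dominate); the shipped
#' rule table instead keys on the number of peaks:
#'
#' * 1 peak: select it.
#' * 2 peaks: if `f_high/f_low` is within `harmonic_ratio`, select the
#'   lower (rule `H1`); else if the amplitudes are near-equal
#'   (ratio < `equal_amp_ratio`), select their mean (rule `M1`); else the
#'   stronger peak (rule `A1`).
#' * 3--4 peaks: prune any peak within `harmonic_tol` of twice a lower
#'   retained peak (low-to-high), then apply the 1/2-peak rules to the two
#'   largest survivors (rule prefixed `P+`).
#' * more than 4 peaks: the peak nearest the history median if a history
#'   exists (rule `HIST`), else the strongest (rule `AMAX`).
#'
#' @param peaks `data.frame(freq, amplitude, ...)` sorted by frequency.
#' @param history previously accepted `f0` values (Hz), oldest first.
#' @param config a [stage1_config()].
#' @return an object of class `coarse_estimate`: `f0` (Hz, `NA` if no
#'   peak), `n_peaks_detected`, `rule_applied`, `valid` (in-band gating;
#'   see [plausibility_check()] for the history gate).
#' @export
peak_decision <- function(peaks, history = numeric(),
                          config = stage1_config()) {
  n <- nrow(peaks)
  if (is.null(n) || n == 0) {
    return(structure(list(f0 = NA_real_, n_peaks_detected = 0L,
                          rule_applied = "none", valid = FALSE),
                     class = "coarse_estimate"))
  }
  ## with an established history, an ambiguous pattern is resolved towards
  ## the peak(s) within the plausible jump range of the history median:
  ## a stronger peak outside that range would be rejected by the
  ## plausibility gate anyway, so preferring the nearby peak keeps the
  ## chunk informative
  near_history <- function(p) {
    if (!length(history) || nrow(p) < 2) return(p)
    ref <- stats::median(history)
    sel <- abs(p$freq - ref) * 60 <= config$jump_limit_bpm
    if (any(sel) && !all(sel)) p[sel, , drop = FALSE] else p
  }
  if (n == 1) {
    f0 <- peaks$freq[1]; rule <- "single"
  } else if (n == 2) {
    ratio <- peaks$freq[2] / peaks$freq[1]
    harmonic <- ratio >= config$harmonic_ratio[1] &&
      ratio <= config$harmonic_ratio[2]
    cand <- if (harmonic) peaks else near_history(peaks)
    if (nrow(cand) == 1) {
      f0 <- cand$freq[1]; rule <- "HISTN"
    } else {
      d <- decide_two_peaks(cand, config)
      f0 <- d$f0; rule <- d$rule
    }
  } else if (n <= 4) {
    keep <- rep(TRUE, n)
    for (j in 2:n) {
      lower <- peaks$freq[seq_len(j - 1)][keep[seq_len(j - 1)]]
      if (any(abs(peaks$freq[j] - 2 * lower) <= config$harmonic_tol * 2 * lower))
        keep[j] <- FALSE
    }
    surv <- near_history(peaks[keep, , drop = FALSE])
    if (nrow(surv) == 1) {
      f0 <- surv$freq[1]; rule <- "P+single"
    } else {
      top2 <- surv[order(surv$amplitude, decreasing = TRUE)[1:2], ]
      top2 <- top2[order(top2$freq), ]
      d <- decide_two_peaks(top2, config)
      f0 <- d$f0; rule <- paste0("P+", d$rule)
    }
  } else {
    if (length(history)) {
      f0 <- peaks$freq[which.min(abs(peaks$freq - stats::median(history)))]
      rule <- "HIST"
    } else {
      f0 <- peaks$freq[which.max(peaks$amplitude)]
      rule <- "AMAX"
    }
  }
  valid <- is.finite(f0) && f0 >= config$hr_band[1] && f0 <= config$hr_band[2]
  structure(list(f0 = f0, n_peaks_detected = as.integer(n),
                 rule_applied = rule, valid = valid),
            class = "coarse_estimate")
}

#' Plausibility check against the estimation history
#'
#' Suppresses implausible jumps: if the coarse estimate deviates from the
#' median of the last `history_n` accepted estimates by more than
#' `jump_limit_bpm` (default 15 bpm over a 5 s chunk, a physiological slew
#' bound), it is marked invalid, signalling the fine stage to continue
#' independently from the last fused estimate.
#'
#' @param est a `coarse_estimate`.
#' @param history accepted `f0` values (Hz), oldest first.
#' @param config a [stage1_config()].
#' @return the (possibly invalidated) `coarse_estimate`.
#' @export
plausibility_check <- function(est, history = numeric(),
                               config = stage1_config()) {
  stopifnot(inherits(est, "coarse_estimate"))
  if (!est$valid || !length(history)) return(est)
  ref <- stats::median(utils::tail(history, config$history_n))
  if (abs(est$f0 - ref) * 60 > config$jump_limit_bpm) {
    est$valid <- FALSE
    est$rule_applied <- paste0(est$rule_applied, "/jump")
  }
  est
}

#' Stage 1: coarse HR estimation on one chunk
#'
#' Runs the full coarse chain on a 5 s phase-difference chunk: wavelet
#' decomposition, HR-band (A3+D3) reconstruction, Burg AR fit, AR spectrum
#' on the 0.5--2.5 Hz grid, peak detection, pattern decision, and the
#' plausibility gate.
#'
#' @param chunk phase-difference samples (typically 100 at 20 Hz).
#' @param fs sampling rate (Hz).
#' @param history accepted `f0` values (Hz) from previous chunks.
#' @param config a [stage1_config()].
#' @return a `coarse_estimate` with the spectrum attached as
#'   `attr(, "spectrum")`.
#' @export
stage1_estimate <- function(chunk, fs = 20, history = numeric(),
                            config = stage1_config()) {
  dec <- dwt_decompose(chunk, levels = config$levels,
                       wavelet = config$wavelet)
  hrb <- reconstruct_hr_band(dec)
  model <- burg_ar(hrb, order = config$ar_order, fs = fs)
  spec <- ar_psd(model, seq(config$hr_band[1], config$hr_band[2],
                            length.out = config$grid_n))
  peaks <- detect_peaks(spec, config$min_prominence_frac)
  spec$peaks <- peaks
  est <- peak_decision(peaks, history, config)
  est <- plausibility_check(est, history, config)
  attr(est, "spectrum") <- spec
  est
}
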