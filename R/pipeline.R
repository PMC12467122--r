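#' Split a signal into non-overlapping chunks
#'
#' Non-overlapping windows of `chunk_len_s` seconds (5 s = 100 samples at
#' 20 Hz, the unit at which both estimation stages operate). A trailing
#' remainder shorter than one chunk is dropped and reported.
#'
#' @param n signal length in samples (or a vector whose length is used).
#' @param fs sampling rate (Hz); `fs * chunk_len_s` must be integral.
#' @param chunk_len_s chunk length (s).
#' @return `data.frame(chunk_index, start, end)` with 0-based
#'   `chunk_index`, 1-based inclusive sample indices, and
#'   `attr(, "n_dropped")` trailing samples.
#' @export
#' @examples
#' chunk_indices(1800, 20)        # 18 chunks of a 90 s recording
chunk_indices <- function(n, fs = 20, chunk_len_s = 5) {
  if (length(n) > 1) n <- length(n)
  size <- fs * chunk_len_s
  if (abs(size - round(size)) > 1e-9) stop("fs * chunk_len_s must be integral")
  size <- as.integer(round(size))
  k <- n %/% size
  if (k < 1) stop("signal (", n, " samples) shorter than one chunk (",
                  size, " samples)")
  out <- data.frame(chunk_index = 0:(k - 1L),
                    start = size * (0:(k - 1L)) + 1L,
                    end = size * (1:k))
  attr(out, "n_dropped") <- n - k * size
  out
}

#' Full pipeline configuration
#'
#' Every tunable of the pipeline in one nested list, round-trippable
#' through YAML with [write_config()] / [read_config()].
#'
#' @param ... overrides, e.g. `pipeline_config(stage1 = list(ar_order = 16))`
#'   (partial lists are merged over the defaults).
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    version = "1",
    seed = 1L,
    preprocess = list(
      window = "hann", clutter_cutoff = 0.1, filter_order = 4,
      search_range = c(0.2, 1.5), hr_band = c(0.5, 3.0),
      hilbert_kalman = TRUE, hk_delta = 1.5
    ),
    chunk_len_s = 5,
    stage1 = stage1_config(),
    stage2 = stage2_config(),
    fuse = list(Q = 0.5, R0 = 25, R1 = 9, P0 = 100),
    evaluate = list(sd_scope = "per_recording")
  )
  overrides <- list(...)
  merge_cfg <- function(base, over, path = "") {
    bad <- setdiff(names(over), names(base))
    if (length(bad)) stop("unknown config key", if (length(bad) > 1) "s",
                          ": ", paste0(path, bad, collapse = ", "))
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_cfg(base[[nm]], over[[nm]], paste0(path, nm, "$"))
      else over[[nm]]
    }
    base
  }
  structure(merge_cfg(defaults, overrides), class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a validated `pipeline_config` (unknown keys are rejected).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the complete estimation pipeline on a recording
#'
#' Executes pre-processing (range FFT, clutter filter, bin selection,
#' phase extraction, HR band-pass, robust smoothing, phase difference),
#' 5 s chunking, Stage 1 and Stage 2 per chunk, and the sequential Kalman
#' fusion.
#'
#' The phase-difference series is one sample shorter than the phase; it is
#' front-padded with its first value so that a 90 s recording yields
#' exactly 18 aligned 5 s chunks.
#'
#' Bookkeeping of the two stages: the Stage 1 history collects accepted
#' coarse estimates; when a chunk's coarse estimate is invalid, the Stage 2
#' window is centred on the previous fused estimate, and if none exists
#' yet the full 0.5--2.5 Hz band is searched.
#'
#' Track management (see the methods vignette for rationale): the history
#' starts only once two of the last three coarse estimates agree within
#' the jump limit (acquisition); three mutually consistent rejections
#' within eight chunks restart it (re-lock) and re-inflate the fused
#' covariance; chunks before the first lock report the first locked
#' estimate (backcast).
#'
#' @param recording a `radar_cube` or the path of a recording container.
#' @param config a [pipeline_config()].
#' @return an object of class `hr_pipeline_result`: `results` (one row per
#'   chunk: `chunk_index`, `t_start_s`, `f0_bpm`, `f0_valid`, `rule`,
#'   `n_peaks`, `f1_bpm`, `n_window_peaks`, `fallback_used`, `locked`,
#'   `hr_skf_bpm`, `P`), plus the intermediate `phase`, `dphi`,
#'   `bin_index`, and the `config` in effect.
#' @export
run_pipeline <- function(recording, config = pipeline_config()) {
  if (is.character(recording)) recording <- read_recording(recording)
  stopifnot(inherits(recording, "radar_cube"),
            inherits(config, "pipeline_config"))
  pp <- config$preprocess
  profiles <- range_fft(recording, window = pp$window)
  profiles <- clutter_filter(profiles, cutoff = pp$clutter_cutoff,
                             order = pp$filter_order)
  bin <- select_range_bin(profiles, search_range = pp$search_range)
  phase <- extract_phase(profiles, bin)
  phase <- bandpass_hr(phase, band = pp$hr_band, order = pp$filter_order)
  if (isTRUE(pp$hilbert_kalman))
    phase <- hilbert_kalman(phase, delta = pp$hk_delta)
  dp <- phase_difference(phase)
  dphi <- c(dp$dphi[1], dp$dphi)   # front-pad: keep duration/chunk_len chunks
  fs <- dp$fs
  chunks <- chunk_indices(length(dphi), fs, config$chunk_len_s)
  n_chunk <- chunks$end[1] - chunks$start[1] + 1L
  basis <- build_basis(n_chunk, fs,
                       f_lo = config$stage1$hr_band[1],
                       f_hi = config$stage1$hr_band[2])
  history <- numeric()
  rejects <- data.frame(chunk = integer(), f0 = numeric()) # recent jump-gated f0
  acq_f0 <- numeric()    # recent coarse estimates during acquisition
  prev_fused <- NA_real_
  locked <- FALSE  # the track locks once two consecutive coarse estimates
                   # agree within the jump limit; until then nothing enters
                   # the history and the fusion filter is not initialized
  state <- NULL    # SKF runs incrementally: Stage 2 windows centre on the
                   # previous fused estimate when Stage 1 is invalid
  jump_hz <- config$stage1$jump_limit_bpm / 60
  rows <- vector("list", nrow(chunks))
  for (i in seq_len(nrow(chunks))) {
    y <- dphi[chunks$start[i]:chunks$end[i]]
    s1 <- tryCatch(
      stage1_estimate(y, fs, history, config$stage1),
      error = function(e) stop("stage1 failed on chunk ", i - 1, ": ",
                               conditionMessage(e)))
    if (!locked) {
      mate <- acq_f0[abs(s1$f0 - acq_f0) <= jump_hz]
      if (s1$valid && length(mate)) {
        locked <- TRUE
        history <- c(mate[length(mate)], s1$f0)
        s1$rule_applied <- paste0(s1$rule_applied, "/lock")
      } else {
        if (s1$valid) {
          acq_f0 <- utils::tail(c(acq_f0, s1$f0), 3)
          s1$valid <- FALSE   # unconfirmed single estimate: acquiring
          s1$rule_applied <- paste0(s1$rule_applied, "/acq")
        }
      }
    } else if (!s1$valid && grepl("/jump$", s1$rule_applied)) {
      ## re-lock: three mutually consistent rejected estimates within a
      ## short span indicate the history locked onto the wrong line (e.g.
      ## a harmonic or vibration peak); restart the history from them
      rejects <- rbind(rejects, data.frame(chunk = i, f0 = s1$f0))
      rejects <- rejects[rejects$chunk > i - 8, , drop = FALSE]
      if (nrow(rejects) >= 3) {
        md <- stats::median(rejects$f0)
        near <- rejects$f0[abs(rejects$f0 - md) <= jump_hz / 2]
        if (length(near) >= 3 && abs(s1$f0 - md) <= jump_hz / 2) {
          history <- utils::tail(near, 3)
          rejects <- rejects[0, , drop = FALSE]
          s1$valid <- TRUE
          s1$rule_applied <- paste0(sub("/jump$", "", s1$rule_applied),
                                    "/relock")
        }
      }
    }
    ## Stage 2 window centre: the coarse estimate when available (confirmed
    ## or still acquiring), else the previous fused value, else full band
    center <- if (!is.na(s1$f0) &&
                  (s1$valid || !locked)) s1$f0 else if (!is.na(prev_fused))
      bpm_to_hz(prev_fused) else NA_real_
    s2 <- tryCatch(
      stage2_estimate(y, basis, center, config$stage2),
      error = function(e) stop("stage2 failed on chunk ", i - 1, ": ",
                               conditionMessage(e)))
    if (locked && s1$valid && !grepl("/relock|/lock", s1$rule_applied))
      history <- c(history, s1$f0)
    f0b <- if (is.na(s1$f0)) NA_real_ else hz_to_bpm(s1$f0)
    f1b <- hz_to_bpm(s2$f1)
    if (locked) {
      if (is.null(state)) {
        state <- kalman_state(x0 = hz_to_bpm(stats::median(history)),
                              P0 = config$fuse$P0, Q = config$fuse$Q,
                              R0 = config$fuse$R0, R1 = config$fuse$R1)
      }
      if (grepl("/relock$", s1$rule_applied)) {
        ## the coarse stage concluded its history was locked onto the wrong
        ## spectral line; the fused state is equally suspect
        state$P <- state$P + diag(config$fuse$P0, nrow(state$P))
      }
      state <- kf_predict(state)
      ## an f1 from a window centred on the fused prior is partially
      ## self-confirming: treat it like a fallback measurement
      f1_weak <- s2$fallback_used || (!s1$valid && !is.na(prev_fused))
      state <- sequential_update(state, f0b, f1b, s1$valid, f1_weak,
                                 config$stage2$r1_inflation)
      prev_fused <- drop(state$x)[1]
      fused_i <- prev_fused
      P_i <- state$P[1, 1]
    } else {
      ## before the first lock the fine estimate is reported as-is with
      ## full prior uncertainty
      fused_i <- f1b
      P_i <- config$fuse$P0
    }
    rows[[i]] <- data.frame(
      chunk_index = chunks$chunk_index[i],
      t_start_s = (chunks$start[i] - 1) / fs,
      f0_bpm = f0b,
      f0_valid = s1$valid,
      rule = s1$rule_applied,
      n_peaks = s1$n_peaks_detected,
      f1_bpm = f1b,
      n_window_peaks = s2$n_window_peaks,
      fallback_used = s2$fallback_used,
      locked = locked,
      hr_skf_bpm = fused_i,
      P = P_i
    )
  }
  results <- do.call(rbind, rows)
  ## backcast: recordings are processed offline, so the unconfirmed
  ## acquisition chunks (before the first lock) are replaced by the first
  ## locked estimate -- the HR seconds before lock is far better predicted
  ## by the locked state than by a single unconfirmed chunk
  if (any(results$locked) && !results$locked[1]) {
    first <- which(results$locked)[1]
    results$hr_skf_bpm[seq_len(first - 1)] <- results$hr_skf_bpm[first]
  }
  structure(list(results = results, phase = phase, dphi = dphi,
                 bin_index = bin, config = config),
            class = "hr_pipeline_result")
}

#' @export
print.hr_pipeline_result <- function(x, ...) {
  cat("HR pipeline result: ", nrow(x$results), " chunks, range bin ",
      x$bin_index, "\n", sep = "")
  print(utils::head(x$results[c("chunk_index", "t_start_s", "f0_bpm",
                                "f1_bpm", "hr_skf_bpm")], 6))
  if (nrow(x$results) > 6) cat("  ...\n")
  invisible(x)
}

#' Evaluate a pipeline result against a reference trace
#'
#' Aligns the fused per-chunk HR with the reference and computes the full
#' agreement report.
#'
#' @param result an [run_pipeline()] result.
#' @param truth `data.frame(time_s, hr_bpm)` (or a CSV path).
#' @param which which trace to score: `"skf"` (default), `"f0"`, `"f1"`.
#' @return an [agreement_report()].
#' @export
evaluate_pipeline <- function(result, truth, which = c("skf", "f0", "f1")) {
  which <- match.arg(which)
  if (is.character(truth)) truth <- read_truth(truth)
  col <- switch(which, skf = "hr_skf_bpm", f0 = "f0_bpm", f1 = "f1_bpm")
  est <- data.frame(t_start_s = result$results$t_start_s,
                    hr_bpm = result$results[[col]])
  pairs <- align_traces(est, truth, result$config$chunk_len_s)
  agreement_report(pairs, result$config$evaluate$sd_scope)
}
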