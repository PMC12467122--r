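#' Write a radar recording to a plain-text container
#'
#' The container is a line-oriented text file: a one-line JSON header with
#' every acquisition parameter, one line with the slow-time stamps, then
#' one line per frame of ADC samples. All numbers are written with 17
#' significant digits so a read-back is bit-identical.
#'
#' @param cube a `radar_cube`.
#' @param path output file path.
#' @param truth optional `data.frame(time_s, hr_bpm)` reference trace.
#' @param truth_path CSV path for `truth` (required when `truth` is given).
#' @param overwrite overwrite existing files? Refused by default.
#' @return `path`, invisibly.
#' @seealso [read_recording()], [read_truth()]
#' @export
write_recording <- function(cube, path, truth = NULL, truth_path = NULL,
                            overwrite = FALSE) {
  stopifnot(inherits(cube, "radar_cube"))
  if (file.exists(path) && !overwrite)
    stop("'", path, "' exists; use overwrite = TRUE to replace it")
  cfg <- cube$config
  header <- jsonlite::toJSON(list(
    format = "cabinpulse-recording", version = 1L,
    f_start = cfg$f_start, f_end = cfg$f_end, fs_fast = cfg$fs_fast,
    n_samples = cfg$n_samples, frame_rep = cfg$frame_rep,
    n_chirps_per_frame = cfg$n_chirps_per_frame, duration = cfg$duration,
    n_frames = nrow(cube$data)
  ), auto_unbox = TRUE, digits = NA)
  lines <- c(
    as.character(header),
    paste(fmt_full(cube$t_slow), collapse = " "),
    apply(cube$data, 1, function(row) paste(fmt_full(row), collapse = " "))
  )
  writeLines(lines, path)
  if (!is.null(truth)) {
    if (is.null(truth_path)) stop("truth_path must be given when truth is supplied")
    if (file.exists(truth_path) && !overwrite)
      stop("'", truth_path, "' exists; use overwrite = TRUE to replace it")
    utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a radar recording container
#'
#' @param path file written by [write_recording()].
#' @return a `radar_cube`.
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  if (!identical(hdr$format, "cabinpulse-recording"))
    stop("'", path, "' is not a cabinpulse recording container")
  cfg <- radar_config(f_start = hdr$f_start, f_end = hdr$f_end,
                      fs_fast = hdr$fs_fast, n_samples = hdr$n_samples,
                      frame_rep = hdr$frame_rep,
                      n_chirps_per_frame = hdr$n_chirps_per_frame,
                      duration = hdr$duration)
  t_slow <- scan(text = lines[2], quiet = TRUE)
  frames <- lines[-(1:2)]
  if (length(frames) != hdr$n_frames)
    stop("container truncated: expected ", hdr$n_frames, " frames, found ",
         length(frames))
  data <- matrix(scan(text = frames, quiet = TRUE),
                 nrow = hdr$n_frames, ncol = hdr$n_samples, byrow = TRUE)
  structure(list(data = data, config = cfg, t_slow = t_slow),
            class = "radar_cube")
}

#' Read a reference heart-rate trace
#'
#' Expects a CSV with columns `time_s` and `hr_bpm` (a chest-strap style
#' export).
#'
#' @param path CSV path.
#' @return `data.frame(time_s, hr_bpm)`.
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "hr_bpm") %in% names(df)))
    stop("'", path, "' must have columns time_s and hr_bpm")
  df[c("time_s", "hr_bpm")]
}
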