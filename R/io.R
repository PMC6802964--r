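# File interchange: multi-page TIFF movies (16-bit, ImageJ-style metadata),
# trace/titration/transient CSV, ground truth and fit-report JSON.

#' Write a movie as a 16-bit multi-page TIFF
#'
#' Pixel values are clipped to `[0, 65535]` and stored as 16-bit unsigned
#' integers. Physical calibration (`pixel_size_um`, `frame_interval_s`,
#' `channel`) is written to a JSON sidecar (`<path>.meta.json`) so the TIFF
#' remains readable by any viewer while the calibration round-trips exactly.
#'
#' @param movie a [tirf_movie()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "tirf_movie"))
  nt <- dim(movie$frames)[3]
  pages <- lapply(seq_len(nt), function(f) {
    pmin(pmax(movie$frames[, , f], 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(pixel_size_um = movie$pixel_size,
         frame_interval_s = movie$frame_interval,
         channel = movie$channel, images = nt, unit = "micron"),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(path)
}

#' Read a movie written by [write_movie()]
#'
#' @param path TIFF file path.
#' @param pixel_size,frame_interval calibration overrides; taken from the
#'   JSON sidecar when omitted.
#' @return A [tirf_movie()].
#' @export
read_movie <- function(path, pixel_size = NULL, frame_interval = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".meta.json")
  channel <- NA_character_
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(pixel_size)) pixel_size <- meta$pixel_size_um
    if (is.null(frame_interval)) frame_interval <- meta$frame_interval_s
    if (!is.null(meta$channel)) channel <- meta$channel
  }
  if (is.null(pixel_size) || is.null(frame_interval))
    stop(sprintf("'%s' lacks calibration metadata; pass pixel_size and frame_interval",
                 path))
  frames <- vapply(pages, function(p) p * 65535, pages[[1]] * 0)
  tirf_movie(frames, pixel_size, frame_interval, channel)
}

#' Write / read an intensity trace as CSV
#'
#' Columns `time_s`, `intensity_au`.
#'
#' @param trace an [intensity_trace()].
#' @param path CSV path.
#' @return `path` (write) or an [intensity_trace()] (read).
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(data.frame(time_s = trace$time, intensity_au = trace$intensity),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("time_s", "intensity_au") %in% names(d)))
    stop("trace CSV must have columns time_s, intensity_au")
  dt <- median(diff(d$time_s))
  intensity_trace(d$time_s, d$intensity_au, dt)
}

#' Write ground truth (or any results list) as JSON
#'
#' @param truth list or data.frame.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
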