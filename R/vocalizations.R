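#' Frame-level vocal activity track
#'
#' Energy-based activity detection: the recording is cut into
#' non-overlapping frames, each frame's RMS level (dB) is compared with
#' an adaptive noise floor (the 5th percentile of frame levels), and a
#' frame is active when it exceeds the floor by `threshold_db`.
#'
#' A frame is also active when it exceeds an absolute level
#' (`abs_level_db`, dBFS), which keeps uniformly loud recordings - where
#' the adaptive floor rises to the signal level itself - fully active.
#'
#' @param sample An [audio_sample].
#' @param frame Frame length, ms.
#' @param threshold_db Margin over the noise floor, dB.
#' @param abs_level_db Absolute activity level, dB re full scale.
#' @return Logical vector of per-frame activity with attributes
#'   `frame_s` (frame length, s) and `floor_db`.
#' @export
frame_activity <- function(sample, frame = 10, threshold_db = 15,
                           abs_level_db = -25) {
  stopifnot(inherits(sample, "audio_sample"))
  stopifnot_scalar_pos(frame, "frame")
  fl <- max(1L, as.integer(round(frame / 1000 * sample$sample_rate)))
  n <- length(sample$samples)
  nf <- n %/% fl
  if (nf == 0L) {
    out <- logical(0)
    attr(out, "frame_s") <- fl / sample$sample_rate
    return(out)
  }
  x <- sample$samples[seq_len(nf * fl)]
  rms <- sqrt(colMeans(matrix(x ^ 2, nrow = fl)))
  db <- 20 * log10(pmax(rms, 1e-12))
  floor_db <- stats::quantile(db, 0.05, names = FALSE)
  active <- (db > floor_db + threshold_db) | (db > abs_level_db)
  attr(active, "frame_s") <- fl / sample$sample_rate
  attr(active, "floor_db") <- floor_db
  active
}

#' Detect and count vocalizations
#'
#' A vocalization is a continuous run of vocal activity containing no
#' silent pause longer than `pause_ms`: active runs separated by gaps
#' of at most `pause_ms` are merged into one vocalization, longer gaps
#' split. A gap of exactly `pause_ms` therefore merges. The count is
#' normalized by recording duration to vocalizations per minute.
#'
#' @param sample An [audio_sample].
#' @param pause_ms Maximum internal pause, ms (default 300).
#' @param frame Detector frame length, ms.
#' @param threshold_db Detector threshold over the noise floor, dB.
#' @return An object of class `vocalization_result`: `segments`
#'   (data.frame of start/end seconds), `count`, `rate`
#'   (vocalizations per minute) and `duration` (s).
#' @export
detect_vocalizations <- function(sample, pause_ms = 300, frame = 10,
                                 threshold_db = 15) {
  stopifnot(inherits(sample, "audio_sample"))
  stopifnot_scalar_pos(pause_ms, "pause_ms")
  if (length(sample$samples) == 0L) {
    stop("degenerate input: empty sample", call. = FALSE)
  }
  active <- frame_activity(sample, frame, threshold_db)
  frame_s <- attr(active, "frame_s")

  segments <- data.frame(start = numeric(0), end = numeric(0))
  if (any(active)) {
    r <- rle(as.vector(active))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    act <- which(r$values)
    seg_start <- (starts[act] - 1L) * frame_s
    seg_end <- ends[act] * frame_s
    # merge across gaps <= pause_ms
    keep_start <- seg_start[1]
    out_start <- numeric(0); out_end <- numeric(0)
    for (i in seq_along(seg_start)[-1]) {
      gap_ms <- (seg_start[i] - seg_end[i - 1L]) * 1000
      if (gap_ms > pause_ms + 1e-9) {
        out_start <- c(out_start, keep_start)
        out_end <- c(out_end, seg_end[i - 1L])
        keep_start <- seg_start[i]
      }
    }
    out_start <- c(out_start, keep_start)
    out_end <- c(out_end, seg_end[length(seg_end)])
    segments <- data.frame(start = out_start, end = out_end)
  }
  count <- nrow(segments)
  structure(
    list(segments = segments, count = count,
         rate = count / (sample$duration / 60),
         duration = sample$duration,
         pause_ms = pause_ms),
    class = "vocalization_result"
  )
}

#' @export
print.vocalization_result <- function(x, ...) {
  cat(sprintf("<vocalizations: %d in %.1f s (%.2f / min; pause rule %g ms)>\n",
              x$count, x$duration, x$rate, x$pause_ms))
  invisible(x)
}

#' Write detected segments as a two-column CSV
#'
#' @param result A `vocalization_result`.
#' @param path Output CSV path (columns `start`, `end`, seconds).
#' @return `path`, invisibly.
#' @export
write_segments_csv <- function(result, path) {
  stopifnot(inherits(result, "vocalization_result"))
  utils::write.csv(result$segments, path, row.names = FALSE)
  invisible(path)
}
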