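#' Construct an audio sample
#'
#' The basic unit of per-participant input: a mono waveform with its
#' sample rate. Amplitudes are stored as doubles, nominally in `[-1, 1]`.
#'
#' @param samples Numeric vector of amplitudes.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `audio_sample` with fields `samples`,
#'   `sample_rate` and derived `duration` (seconds).
#' @examples
#' a <- audio_sample(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), 8000)
#' a$duration
#' @export
audio_sample <- function(samples, sample_rate) {
  stopifnot_scalar_pos(sample_rate, "sample_rate")
  if (!is.numeric(samples)) stop("`samples` must be numeric", call. = FALSE)
  structure(
    list(
      samples = as.double(samples),
      sample_rate = as.double(sample_rate),
      duration = length(samples) / sample_rate
    ),
    class = "audio_sample"
  )
}

#' @export
print.audio_sample <- function(x, ...) {
  cat(sprintf("<audio_sample: %.3f s at %g Hz (%d samples)>\n",
              x$duration, x$sample_rate, length(x$samples)))
  invisible(x)
}

#' Read a PCM WAV file
#'
#' Reads 16-bit (or 8-bit/32-bit integer) PCM RIFF/WAVE files. Stereo
#' input is mixed down to mono by channel averaging; the original sample
#' rate is preserved.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_sample].
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz + sz %% 2L)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        channels = readBin(fmt_raw[3:4], "integer", 1, size = 2,
                           endian = "little", signed = FALSE),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1, size = 4,
                              endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, size = 2,
                       endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV file (missing fmt or data chunk): ", path, call. = FALSE)
  }
  if (fmt$audio_format != 1L) {
    stop("only uncompressed PCM WAV is supported (format tag ",
         fmt$audio_format, ")", call. = FALSE)
  }
  if (!fmt$channels %in% c(1L, 2L)) {
    stop("only mono or stereo WAV is supported", call. = FALSE)
  }
  x <- switch(as.character(fmt$bits),
    "16" = readBin(data_raw, "integer", length(data_raw) %/% 2L,
                   size = 2, endian = "little") / 32768,
    "8"  = (readBin(data_raw, "integer", length(data_raw), size = 1,
                    signed = FALSE) - 128) / 128,
    "32" = readBin(data_raw, "integer", length(data_raw) %/% 4L,
                   size = 4, endian = "little") / 2147483648,
    stop("unsupported bit depth: ", fmt$bits, call. = FALSE)
  )
  if (fmt$channels == 2L) {
    n <- length(x) %/% 2L
    x <- (x[seq(1L, 2L * n, by = 2L)] + x[seq(2L, 2L * n, by = 2L)]) / 2
  }
  audio_sample(x, fmt$sample_rate)
}

#' Write an audio sample as 16-bit PCM WAV
#'
#' Amplitudes are clipped to `[-1, 1]` and quantized to 16 bits.
#'
#' @param sample An [audio_sample].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(sample, path) {
  stopifnot(inherits(sample, "audio_sample"))
  q <- as.integer(pmin(pmax(round(sample$samples * 32768), -32768), 32767))
  n_bytes <- 2L * length(q)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  sr <- as.integer(round(sample$sample_rate))
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(sr * 2L), con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}

#' Resample an audio sample by band-limited interpolation
#'
#' Frequency-domain (FFT) resampling: the spectrum is truncated or
#' zero-padded to the target Nyquist, which preserves in-band tone power
#' essentially exactly. Duration is preserved to within one sample
#' period.
#'
#' @param sample An [audio_sample].
#' @param target_rate Target sampling rate in Hz (default 22050, the
#'   rate at which the analyses in this package are defined).
#' @return An [audio_sample] at `target_rate`. Returned unchanged if the
#'   rate already matches.
#' @export
resample <- function(sample, target_rate = 22050) {
  stopifnot(inherits(sample, "audio_sample"))
  stopifnot_scalar_pos(target_rate, "target_rate")
  fs <- sample$sample_rate
  if (isTRUE(all.equal(fs, target_rate))) return(sample)
  x <- sample$samples
  n <- length(x)
  if (n == 0L) return(audio_sample(numeric(0), target_rate))
  m_out <- as.integer(round(n * target_rate / fs))
  # pad to an FFT-friendly length; trim the tail after transforming back
  n_pad <- next_fast_len(n)
  m_pad <- as.integer(round(n_pad * target_rate / fs))
  m_fft <- next_fast_len(m_pad)
  n_eff <- as.integer(round(m_fft * fs / target_rate))
  n_eff <- max(n_eff, n)
  n_eff <- next_fast_len(n_eff)
  m_fft <- as.integer(round(n_eff * target_rate / fs))
  xp <- c(x, numeric(n_eff - n))
  X <- stats::fft(xp)
  Y <- complex(length.out = m_fft)
  k <- min(n_eff, m_fft)
  h <- k %/% 2L
  Y[1:(h + 1L)] <- X[1:(h + 1L)]
  if (h > 0L) Y[(m_fft - h + 1L):m_fft] <- X[(n_eff - h + 1L):n_eff]
  if (k %% 2L == 0L && m_fft > n_eff) {
    # split the old Nyquist bin symmetrically when upsampling
    Y[h + 1L] <- X[h + 1L] / 2
    Y[m_fft - h + 1L] <- Conj(X[h + 1L]) / 2
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / n_eff
  audio_sample(y[seq_len(min(m_out, length(y)))], target_rate)
}

#' Define intervals of a recording to excise
#'
#' Holds annotated time intervals (adult speech, environmental noise,
#' ...) to be removed before analysis. Intervals are normalized: sorted,
#' clipped to `[0, Inf)` and overlapping/adjacent intervals merged.
#'
#' @param intervals A two-column matrix or data.frame of start/end times
#'   in seconds (half-open `[start, end)`), or `NULL` for none.
#' @return An object of class `exclusion_annotation`.
#' @export
exclusion_annotation <- function(intervals = NULL) {
  if (is.null(intervals) || NROW(intervals) == 0L) {
    iv <- matrix(numeric(0), ncol = 2)
  } else {
    iv <- as.matrix(intervals)[, 1:2, drop = FALSE]
    storage.mode(iv) <- "double"
    if (any(!is.finite(iv)) || any(iv[, 2] <= iv[, 1]) || any(iv < 0)) {
      stop("intervals must be finite, non-negative, with end > start",
           call. = FALSE)
    }
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    merged <- iv[1, , drop = FALSE]
    if (nrow(iv) > 1L) {
      for (i in 2:nrow(iv)) {
        j <- nrow(merged)
        if (iv[i, 1] <= merged[j, 2]) {
          merged[j, 2] <- max(merged[j, 2], iv[i, 2])
        } else {
          merged <- rbind(merged, iv[i, ])
        }
      }
    }
    iv <- merged
  }
  colnames(iv) <- c("start", "end")
  structure(list(intervals = iv), class = "exclusion_annotation")
}

#' Read exclusion intervals from a two-column CSV
#'
#' @param path CSV with columns `start`, `end` (seconds).
#' @return An [exclusion_annotation].
#' @export
read_annotation_csv <- function(path) {
  df <- utils::read.csv(path)
  exclusion_annotation(df[, c("start", "end")])
}

#' Excise annotated intervals and concatenate recordings
#'
#' Removes the annotated intervals from each recording and joins the
#' retained pieces in order, emulating the preparation of one combined
#' speech sample per participant from multiple recording contexts. A
#' short cosine cross-fade (default 5 ms) is applied across each splice
#' so that editing does not inject click transients into the fast
#' (50-100 Hz) modulation band.
#'
#' @param samples A list of [audio_sample] objects (all at one rate).
#' @param annotations Optional list of [exclusion_annotation], one per
#'   sample (or `NULL` entries for none).
#' @param crossfade_ms Cross-fade length at splice points, in ms. Set to
#'   0 for plain cutting (retained samples then pass through bit-exact).
#' @param min_duration_s Below this combined duration a warning is
#'   issued (short samples give noisy modulation statistics).
#' @return A single concatenated [audio_sample]. If everything is
#'   excised the result has zero length and carries attribute
#'   `empty = TRUE`.
#' @export
excise_and_concatenate <- function(samples, annotations = NULL,
                                   crossfade_ms = 5, min_duration_s = 120) {
  if (inherits(samples, "audio_sample")) samples <- list(samples)
  stopifnot(length(samples) >= 1L,
            all(vapply(samples, inherits, TRUE, "audio_sample")))
  rates <- vapply(samples, function(s) s$sample_rate, 0)
  if (length(unique(rates)) != 1L) {
    stop("all samples must share one sample rate; resample() first",
         call. = FALSE)
  }
  fs <- rates[1]
  if (!is.null(annotations) && length(annotations) != length(samples)) {
    stop("need one annotation (or NULL) per sample", call. = FALSE)
  }

  pieces <- list()
  for (i in seq_along(samples)) {
    x <- samples[[i]]$samples
    ann <- if (is.null(annotations)) NULL else annotations[[i]]
    if (is.null(ann) || nrow(ann$intervals) == 0L) {
      pieces[[length(pieces) + 1L]] <- x
      next
    }
    iv <- ann$intervals
    dur <- length(x) / fs
    if (any(iv[, 1] > dur)) {
      stop("annotation interval starts beyond sample duration", call. = FALSE)
    }
    keep_start <- c(0, pmin(iv[, 2], dur))
    keep_end <- c(iv[, 1], dur)
    for (j in seq_along(keep_start)) {
      a <- floor(keep_start[j] * fs) + 1L
      b <- floor(keep_end[j] * fs)
      if (b >= a) pieces[[length(pieces) + 1L]] <- x[a:b]
    }
  }
  pieces <- Filter(length, pieces)
  if (length(pieces) == 0L) {
    warning("all audio excised; returning empty sample")
    out <- audio_sample(numeric(0), fs)
    attr(out, "empty") <- TRUE
    return(out)
  }

  # taper the cut edges (half-cosine ramps) instead of overlap-adding, so
  # splices are click-free while total duration is conserved exactly
  nf <- max(0L, as.integer(round(crossfade_ms / 1000 * fs / 2)))
  if (nf > 0L && length(pieces) > 1L) {
    for (i in seq_along(pieces)) {
      p <- pieces[[i]]
      k <- min(nf, length(p))
      if (k == 0L) next
      ramp <- 0.5 * (1 - cos(pi * (seq_len(k) - 0.5) / k))
      if (i > 1L) p[seq_len(k)] <- p[seq_len(k)] * ramp
      if (i < length(pieces)) {
        idx <- (length(p) - k + 1L):length(p)
        p[idx] <- p[idx] * rev(ramp)
      }
      pieces[[i]] <- p
    }
  }
  res <- audio_sample(unlist(pieces, use.names = FALSE), fs)
  if (res$duration < min_duration_s) {
    warning(sprintf(
      "combined sample is %.1f s (< %g s); modulation statistics may be noisy",
      res$duration, min_duration_s))
  }
  res
}
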