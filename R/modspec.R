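#' Spectrogram configuration
#'
#' Analysis parameters for the short-time Fourier spectrogram that the
#' modulation analysis is built on. The defaults (25 ms Gaussian
#' window, 2 ms hop, 8 kHz ceiling, log magnitude floored 80 dB below
#' the per-file maximum) give a temporal-modulation Nyquist of 250 Hz,
#' comfortably above the 100 Hz upper edge of the fastest articulatory
#' band, and a frequency step of ~21.5 Hz (nfft 1024 at 22.05 kHz),
#' which resolves spectral modulations up to ~23 cycles/kHz - an order
#' of magnitude finer than the harmonic spacing of child vocalization
#' (f0 near 300 Hz, i.e. ~3.3 cycles/kHz).
#'
#' @param window_length Analysis window, ms.
#' @param hop Frame step, ms; must satisfy `1/(2 hop) >= 100` Hz so the
#'   temporal-modulation axis covers the 50-100 Hz band.
#' @param window_shape `"gaussian"` (sd = length/6), `"hann"` or
#'   `"hamming"`.
#' @param amplitude_scale `"log"` (dB, the default) or `"linear"`.
#' @param log_floor Floor below the per-file maximum, dB.
#' @param max_frequency Highest retained acoustic frequency, Hz.
#' @param nfft FFT length (`NULL`: next power of two >= window, min 1024).
#' @return An object of class `spectrogram_config`.
#' @export
spectrogram_config <- function(window_length = 25, hop = 2,
                               window_shape = "gaussian",
                               amplitude_scale = "log", log_floor = 80,
                               max_frequency = 8000, nfft = NULL) {
  stopifnot_scalar_pos(window_length, "window_length")
  stopifnot_scalar_pos(hop, "hop")
  if (hop > window_length) stop("`hop` must be <= `window_length`", call. = FALSE)
  if (1000 / (2 * hop) < 100) {
    stop("`hop` too large: temporal-modulation Nyquist 1/(2 hop) must be >= 100 Hz",
         call. = FALSE)
  }
  window_shape <- match.arg(window_shape, c("gaussian", "hann", "hamming"))
  amplitude_scale <- match.arg(amplitude_scale, c("log", "linear"))
  stopifnot_scalar_pos(log_floor, "log_floor")
  stopifnot_scalar_pos(max_frequency, "max_frequency")
  structure(
    list(window_length = window_length, hop = hop,
         window_shape = window_shape, amplitude_scale = amplitude_scale,
         log_floor = log_floor, max_frequency = max_frequency, nfft = nfft),
    class = "spectrogram_config"
  )
}

taper_window <- function(shape, n) {
  k <- seq_len(n)
  switch(shape,
    gaussian = exp(-0.5 * ((k - (n + 1) / 2) / (n / 6)) ^ 2),
    hann = 0.5 * (1 - cos(2 * pi * (k - 1) / (n - 1))),
    hamming = 0.54 - 0.46 * cos(2 * pi * (k - 1) / (n - 1))
  )
}

#' Compute a magnitude spectrogram
#'
#' Short-time Fourier magnitude on the configured grid. In `"log"`
#' scale the magnitude is expressed in dB and floored at
#' `log_floor` dB below the file maximum (silence maps to the floor).
#'
#' @param sample An [audio_sample].
#' @param config A [spectrogram_config].
#' @return An object of class `spectrogram`: `magnitude` (frequency x
#'   time matrix), `freq` (Hz axis), `freq_step`, `time_step` (s),
#'   `times` (frame centres, s), and the config.
#' @export
compute_spectrogram <- function(sample, config = spectrogram_config()) {
  stopifnot(inherits(sample, "audio_sample"),
            inherits(config, "spectrogram_config"))
  fs <- sample$sample_rate
  win_s <- as.integer(round(config$window_length / 1000 * fs))
  hop_s <- max(1L, as.integer(round(config$hop / 1000 * fs)))
  if (sample$duration < 2 * config$window_length / 1000) {
    stop("sample too short: need at least two window lengths of audio",
         call. = FALSE)
  }
  nfft <- config$nfft
  if (is.null(nfft)) nfft <- max(1024L, 2L ^ ceiling(log2(win_s)))
  if (nfft < win_s) stop("`nfft` must be >= window length in samples", call. = FALSE)

  x <- sample$samples
  starts <- seq.int(1L, length(x) - win_s + 1L, by = hop_s)
  w <- taper_window(config$window_shape, win_s)
  idx <- rep(starts - 1L, each = win_s) + seq_len(win_s)
  frames <- matrix(0, nfft, length(starts))
  frames[seq_len(win_s), ] <- x[idx] * w
  S <- stats::mvfft(frames)

  freq_step <- fs / nfft
  n_keep <- min(nfft %/% 2L + 1L, floor(config$max_frequency / freq_step) + 1L)
  mag <- Mod(S[seq_len(n_keep), , drop = FALSE])
  if (config$amplitude_scale == "log") {
    peak <- max(mag)
    if (peak == 0) peak <- .Machine$double.eps
    floor_lin <- peak * 10 ^ (-config$log_floor / 20)
    mag <- 20 * log10(pmax(mag, floor_lin))
  }
  structure(
    list(magnitude = mag,
         freq = (seq_len(n_keep) - 1) * freq_step,
         freq_step = freq_step,
         time_step = hop_s / fs,
         times = (starts - 1 + win_s / 2) / fs,
         config = config),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram: %d freq bins x %d frames (%.1f Hz x %.1f ms steps, %s scale)>\n",
              nrow(x$magnitude), ncol(x$magnitude), x$freq_step,
              1000 * x$time_step, x$config$amplitude_scale))
  invisible(x)
}

# centred FFT-frequency axis for length n and sampling step `step`
fft_axis <- function(n, step) {
  k <- seq_len(n) - 1L
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  sort_idx <- order(k)
  list(values = k[sort_idx] / (n * step), unshift = sort_idx)
}

#' Compute the Speech Modulation Spectrum
#'
#' Takes the two-dimensional Fourier transform of the (mean-removed)
#' spectrogram over fixed-length chunks and power-averages the results,
#' yielding the joint distribution of spectral modulation frequency
#' (omega_f, cycles/kHz; from structure across the frequency axis) and
#' temporal modulation frequency (omega_t, Hz; from fluctuation across
#' time). Fixed chunking makes the modulation grid - and therefore
#' contour bin counts - identical across recordings of different
#' lengths. The returned power is normalized to sum to one, so the
#' modulation spectrum can be read as a probability distribution over
#' spectro-temporal modulations.
#'
#' @param spgm A [spectrogram].
#' @param chunk_duration Chunk length in seconds (default 1, giving a
#'   1 Hz temporal-modulation resolution).
#' @param chunk_overlap Fractional overlap of consecutive chunks
#'   (default 0.5).
#' @return An object of class `modulation_spectrum`: `power`
#'   (omega_f x omega_t matrix over the full, centred plane, summing to
#'   1), axes `wf` (cycles/kHz) and `wt` (Hz), the axis steps, the
#'   unnormalized `total_power`, and `n_chunks`.
#' @export
compute_modulation_spectrum <- function(spgm, chunk_duration = 1,
                                        chunk_overlap = 0.5) {
  stopifnot(inherits(spgm, "spectrogram"))
  stopifnot_scalar_pos(chunk_duration, "chunk_duration")
  stopifnot(chunk_overlap >= 0, chunk_overlap < 1)
  cw <- as.integer(round(chunk_duration / spgm$time_step))
  nt <- ncol(spgm$magnitude)
  if (cw < 2L || nt < cw) {
    stop("spectrogram must span at least one chunk of `chunk_duration`",
         call. = FALSE)
  }
  step <- max(1L, as.integer(round(cw * (1 - chunk_overlap))))
  starts <- seq.int(1L, nt - cw + 1L, by = step)
  nr <- nrow(spgm$magnitude)

  acc <- matrix(0, nr, cw)
  for (s0 in starts) {
    ch <- spgm$magnitude[, s0:(s0 + cw - 1L), drop = FALSE]
    ch <- ch - mean(ch)
    # |2-D DFT|^2 / N so that total power equals the chunk's energy (Parseval)
    acc <- acc + Mod(stats::fft(ch)) ^ 2 / (nr * cw)
  }
  acc <- acc / length(starts)

  ax_f <- fft_axis(nr, spgm$freq_step)       # cycles/Hz
  ax_t <- fft_axis(cw, spgm$time_step)       # Hz
  power <- acc[ax_f$unshift, ax_t$unshift, drop = FALSE]
  total <- sum(power)
  if (total > 0) power <- power / total
  structure(
    list(power = power,
         wf = ax_f$values * 1000,            # cycles/kHz
         wt = ax_t$values,
         wf_step = 1000 / (nr * spgm$freq_step),
         wt_step = 1 / (cw * spgm$time_step),
         total_power = total,
         n_chunks = length(starts)),
    class = "modulation_spectrum"
  )
}

#' @export
print.modulation_spectrum <- function(x, ...) {
  cat(sprintf(
    "<modulation_spectrum: %d x %d bins; |wf| <= %.1f cyc/kHz, |wt| <= %.1f Hz (%d chunks)>\n",
    nrow(x$power), ncol(x$power), max(abs(x$wf)), max(abs(x$wt)), x$n_chunks))
  invisible(x)
}

#' Temporal-modulation marginal
#'
#' Sums modulation power over the spectral-modulation axis, giving the
#' distribution of power across temporal modulation frequencies alone.
#'
#' @param ms A [modulation_spectrum].
#' @return Named numeric vector over omega_t (names are frequencies in
#'   Hz); sums to the total power of `ms`.
#' @export
wt_marginal <- function(ms) {
  stopifnot(inherits(ms, "modulation_spectrum"))
  stats::setNames(colSums(ms$power), format(ms$wt, trim = TRUE))
}
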