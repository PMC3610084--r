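# Shared fixture builders and small independent oracles.

FS <- 22050

# analytic-signal amplitude envelope (FFT Hilbert transform)
envelope_of <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

# amplitude-modulated tone; depth < 1 keeps the log envelope smooth
make_am_tone <- function(mod_hz, dur = 4, carrier = 1000, depth = 0.6,
                         fs = FS) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  audio_sample((1 + depth * cos(2 * pi * mod_hz * t)) / (1 + depth) *
                 sin(2 * pi * carrier * t), fs)
}

# tone bursts at given onsets (s); each `burst_dur` s long
make_burst_train <- function(onsets, burst_dur, total_dur, fs = FS,
                             freq = 800, amp = 0.8) {
  x <- numeric(round(total_dur * fs))
  nb <- round(burst_dur * fs)
  env <- sin(pi * (seq_len(nb) - 0.5) / nb)  # smooth on/off
  for (o in onsets) {
    i0 <- round(o * fs) + 1
    seg <- i0:(i0 + nb - 1)
    x[seg] <- x[seg] + amp * env * sin(2 * pi * freq * (seg - i0) / fs)
  }
  audio_sample(x, fs)
}

# random modulation_spectrum object on a small centred grid
random_modspec <- function(nf = 21, nt = 31, wt_ny = 120, wf_ny = 30,
                           seed = 1) {
  set.seed(seed)
  wf <- seq(-wf_ny, wf_ny, length.out = nf)
  wt <- seq(-wt_ny, wt_ny, length.out = nt)
  p <- matrix(rexp(nf * nt), nf, nt)
  p <- p / sum(p)
  structure(
    list(power = p, wf = wf, wt = wt,
         wf_step = diff(wf)[1], wt_step = diff(wt)[1],
         total_power = 1, n_chunks = 1),
    class = "modulation_spectrum"
  )
}

# independent greedy oracle for the minimal 99.9%-energy bin set
contour_oracle <- function(ms, fraction, wt_max = 100, wf_max = 20) {
  keep_f <- which(abs(ms$wf) <= wf_max + 1e-9)
  keep_t <- which(ms$wt >= -1e-9 & ms$wt <= wt_max + 1e-9)
  cells <- expand.grid(i = keep_f, j = keep_t)
  cells$p <- ms$power[as.matrix(cells[, c("i", "j")])]
  cells$awt <- abs(ms$wt[cells$j])
  cells$awf <- abs(ms$wf[cells$i])
  cells <- cells[!(cells$awf < 1e-9 & cells$awt < 1e-9), ]
  cells <- cells[order(-cells$p, cells$awt, cells$awf), ]
  cum <- cumsum(cells$p)
  k <- which(cum >= fraction * sum(cells$p) - 1e-12)[1]
  sel <- cells[seq_len(k), ]
  list(area = k, bins = sort(paste(sel$i, sel$j)))
}

# spectrogram object wrapping an arbitrary magnitude matrix
as_spectrogram <- function(mag, freq_step = 21.5, time_step = 0.002) {
  structure(
    list(magnitude = mag,
         freq = (seq_len(nrow(mag)) - 1) * freq_step,
         freq_step = freq_step, time_step = time_step,
         times = (seq_len(ncol(mag)) - 1) * time_step,
         config = spectrogram_config()),
    class = "spectrogram"
  )
}

# short synthetic vocalization with / without plosive-like bursts
make_vocalization <- function(gain = 1, seed = 1, dur = 4) {
  sts <- syllable_train_spec(
    syllable_rate = 4, burst_rate = if (gain > 0) 3 * gain else 0,
    burst_level = 0.06 * gain, noise_snr = Inf,
    utterance_durations = c(1200, 1500),
    pause_durations = c(600))
  generate_vocalization(sts, seed = seed, total_duration = dur)
}
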