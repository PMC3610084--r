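#' Specification of a synthetic vocalization (syllable train)
#'
#' Parameterizes a toddler-like vocalization as a train of utterances:
#' a harmonic carrier shaped by vowel-like formant resonances, amplitude
#' modulated at the syllable rate, with linear formant sweeps at
#' syllable onsets (transition-like components) and short broadband
#' noise bursts (plosive-like transients). The three knobs map onto the
#' three modulation timescales analysed downstream: `syllable_rate`
#' drives slow (0-10 Hz) envelope modulations, `formant_sweep` the
#' intermediate (10-50 Hz) range, and bursts of 5-15 ms the fast
#' (50-100 Hz) range.
#'
#' @param syllable_rate Syllable repetition rate, Hz (in `(0, 100]`;
#'   child-realistic values 2-10).
#' @param vowel_duration Duration of the voiced nucleus within each
#'   syllable period, ms. Defaults to 80% of the syllable period.
#' @param formant_sweep Numeric `c(start_hz, end_hz, duration_ms)` for
#'   the second-formant glide at each syllable onset, or `NULL`.
#' @param burst_rate Mean rate of noise bursts within utterances, Hz
#'   (0 disables bursts).
#' @param burst_duration Burst length, ms (plosive-like: 5-15).
#' @param burst_level Burst amplitude relative to the voiced carrier.
#' @param carrier_f0 Fundamental frequency of the harmonic carrier, Hz.
#' @param noise_snr Broadband background noise SNR, dB (`Inf` = none).
#' @param utterance_durations Numeric vector of utterance lengths, ms.
#' @param pause_durations Numeric vector of silent gaps between
#'   consecutive utterances, ms; length must be `length(utterance_durations) - 1`.
#' @return An object of class `syllable_train_spec`.
#' @export
syllable_train_spec <- function(syllable_rate = 4,
                                vowel_duration = NULL,
                                formant_sweep = c(1200, 1900, 40),
                                burst_rate = 0,
                                burst_duration = 10,
                                burst_level = 0.1,
                                carrier_f0 = 300,
                                noise_snr = Inf,
                                utterance_durations = c(1500),
                                pause_durations = numeric(0)) {
  stopifnot_scalar_pos(syllable_rate, "syllable_rate")
  if (syllable_rate > 100) stop("`syllable_rate` must be in (0, 100]", call. = FALSE)
  if (is.null(vowel_duration)) vowel_duration <- 0.8 * 1000 / syllable_rate
  stopifnot_scalar_pos(vowel_duration, "vowel_duration")
  stopifnot_scalar_pos(burst_duration, "burst_duration")
  stopifnot_scalar_pos(carrier_f0, "carrier_f0")
  if (burst_rate < 0) stop("`burst_rate` must be >= 0", call. = FALSE)
  if (length(utterance_durations) > 0 && any(utterance_durations <= 0)) {
    stop("utterance durations must be positive", call. = FALSE)
  }
  if (length(pause_durations) != max(0L, length(utterance_durations) - 1L)) {
    stop("need exactly one pause between consecutive utterances", call. = FALSE)
  }
  if (length(pause_durations) > 0 && any(pause_durations <= 0)) {
    stop("pause durations must be positive", call. = FALSE)
  }
  if (!is.null(formant_sweep)) {
    stopifnot(length(formant_sweep) == 3, all(formant_sweep > 0))
  }
  structure(
    list(syllable_rate = syllable_rate, vowel_duration = vowel_duration,
         formant_sweep = formant_sweep, burst_rate = burst_rate,
         burst_duration = burst_duration, burst_level = burst_level,
         carrier_f0 = carrier_f0, noise_snr = noise_snr,
         utterance_durations = as.double(utterance_durations),
         pause_durations = as.double(pause_durations)),
    class = "syllable_train_spec"
  )
}

# voiced utterance waveform: harmonic stack x formant envelope x syllable
# envelope; F2 glides linearly at each syllable onset when a sweep is set
synth_utterance <- function(spec, dur_s, fs) {
  n <- as.integer(round(dur_s * fs))
  if (n == 0L) return(numeric(0))
  t <- (seq_len(n) - 1) / fs
  f0 <- spec$carrier_f0

  # second formant trajectory
  f2 <- rep(1800, n)
  if (!is.null(spec$formant_sweep)) {
    sw <- spec$formant_sweep
    period <- 1 / spec$syllable_rate
    ph <- t %% period                       # time since syllable onset
    frac <- pmin(ph / (sw[3] / 1000), 1)
    f2 <- sw[1] + (sw[2] - sw[1]) * frac
    f2[t >= floor(t / period) * period + period] <- sw[2]  # no-op guard
  }

  formant_gain <- function(f, centre, bw, g) g * exp(-0.5 * ((f - centre) / bw) ^ 2)
  nh <- max(1L, floor(min(fs / 2 * 0.9, 8000) / f0))
  x <- numeric(n)
  for (k in seq_len(nh)) {
    fk <- k * f0
    a <- formant_gain(fk, 700, 150, 1) +
      formant_gain(fk, f2, 220, 0.7) +
      formant_gain(fk, 3200, 350, 0.35)
    phase <- stats::runif(1, 0, 2 * pi)
    x <- x + a * sin(2 * pi * fk * t + phase)
  }

  # raised-cosine syllable envelope, voiced for `vowel_duration` of each period
  period <- 1 / spec$syllable_rate
  vd <- min(spec$vowel_duration / 1000, period)
  ph <- t %% period
  env <- ifelse(ph < vd, 0.5 * (1 - cos(2 * pi * ph / vd)), 0)
  x <- x * env
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak

  # plosive-like noise bursts
  if (spec$burst_rate > 0) {
    n_burst <- stats::rpois(1, spec$burst_rate * dur_s)
    if (n_burst > 0) {
      bl <- as.integer(round(spec$burst_duration / 1000 * fs))
      bl <- max(bl, 2L)
      onsets <- sort(stats::runif(n_burst, 0, max(dur_s - bl / fs, 0)))
      w <- 0.5 * (1 - cos(2 * pi * (seq_len(bl) - 1) / (bl - 1)))
      for (o in onsets) {
        i0 <- as.integer(round(o * fs)) + 1L
        i1 <- min(i0 + bl - 1L, n)
        seg <- seq.int(i0, i1)
        x[seg] <- x[seg] + spec$burst_level * w[seq_along(seg)] *
          stats::rnorm(length(seg))
      }
    }
  }
  x
}

#' Synthesize one vocalization sample
#'
#' Renders the utterance/pause train described by a
#' [syllable_train_spec] into a waveform. Deterministic for a fixed
#' `(spec, sample_rate, seed)` triple; the caller's RNG state is left
#' untouched.
#'
#' @param spec A [syllable_train_spec].
#' @param sample_rate Output rate in Hz (default 22050).
#' @param seed Integer seed controlling phases, burst placement and
#'   background noise.
#' @param total_duration Optional total length in seconds; the tail
#'   beyond the utterance train is filled with silence (plus background
#'   noise if `noise_snr` is finite).
#' @return An [audio_sample].
#' @examples
#' v <- generate_vocalization(syllable_train_spec(syllable_rate = 5),
#'                            sample_rate = 22050, seed = 1)
#' @export
generate_vocalization <- function(spec, sample_rate = 22050, seed = 1,
                                  total_duration = NULL) {
  stopifnot(inherits(spec, "syllable_train_spec"))
  stopifnot_scalar_pos(sample_rate, "sample_rate")
  with_seed(seed, {
    parts <- list()
    nu <- length(spec$utterance_durations)
    for (i in seq_len(nu)) {
      parts[[length(parts) + 1L]] <-
        synth_utterance(spec, spec$utterance_durations[i] / 1000, sample_rate)
      if (i < nu) {
        np <- as.integer(round(spec$pause_durations[i] / 1000 * sample_rate))
        parts[[length(parts) + 1L]] <- numeric(np)
      }
    }
    x <- unlist(parts, use.names = FALSE)
    if (!is.null(total_duration)) {
      n_tot <- as.integer(round(total_duration * sample_rate))
      if (length(x) > n_tot) x <- x[seq_len(n_tot)]
      if (length(x) < n_tot) x <- c(x, numeric(n_tot - length(x)))
    }
    if (is.finite(spec$noise_snr) && length(x) > 0) {
      sig <- sqrt(mean(x ^ 2))
      if (sig > 0) {
        sd_n <- sig / 10 ^ (spec$noise_snr / 20)
        x <- x + stats::rnorm(length(x), sd = sd_n)
      }
    }
    peak <- max(abs(x), 0)
    if (peak > 1) x <- x / peak
    audio_sample(x, sample_rate)
  })
}

#' Group profile for the cohort simulator
#'
#' Describes one diagnostic group: its size, behavioral-score
#' distributions (Gaussian, truncated to legal scale ranges), the
#' fast-modulation gain governing plosive-like burst energy, and the
#' vocalization rate. `gain_sdlog` sets per-participant lognormal
#' heterogeneity of the gain; `gain_viq_rho` couples the gain latent to
#' the verbal-IQ latent (negative values concentrate fast-modulation
#' energy in low-VIQ participants).
#'
#' @param label Group label, one of `"ASD"`, `"TD"`, `"DD"` (free-form
#'   labels are accepted).
#' @param n Number of participants (>= 2).
#' @param score_means,score_sds,score_lo,score_hi Named numeric vectors
#'   over behavioral scales (same names in all four).
#' @param fast_modulation_gain Median multiplier on burst energy.
#' @param gain_sdlog Lognormal sd (log scale) of the per-participant gain.
#' @param gain_viq_rho Latent correlation between gain and VIQ.
#' @param vocalization_rate_mean,vocalization_rate_sd Utterances per
#'   minute (truncated below at 1).
#' @param male_prop Proportion of males (for simulated sex labels).
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(label, n, score_means, score_sds,
                          score_lo, score_hi,
                          fast_modulation_gain = 1, gain_sdlog = 0.3,
                          gain_viq_rho = 0,
                          vocalization_rate_mean = 8,
                          vocalization_rate_sd = 2.5,
                          male_prop = 0.75) {
  stopifnot(n >= 2, all(score_sds > 0), fast_modulation_gain >= 0,
            abs(gain_viq_rho) <= 1)
  nm <- names(score_means)
  stopifnot(!is.null(nm), identical(nm, names(score_sds)),
            identical(nm, names(score_lo)), identical(nm, names(score_hi)))
  structure(
    list(label = label, n = as.integer(n), score_means = score_means,
         score_sds = score_sds, score_lo = score_lo, score_hi = score_hi,
         fast_modulation_gain = fast_modulation_gain,
         gain_sdlog = gain_sdlog, gain_viq_rho = gain_viq_rho,
         vocalization_rate_mean = vocalization_rate_mean,
         vocalization_rate_sd = vocalization_rate_sd,
         male_prop = male_prop),
    class = "group_profile"
  )
}

#' Reference cohort characteristics
#'
#' Published clinical characteristics of the toddler cohort the
#' simulator emulates (three groups: autism spectrum disorder, typical
#' development, idiopathic developmental delay). Returns the per-group
#' per-scale mean, SD and observed range, the group sizes, and the
#' male/female counts. These numbers parameterize [default_profiles()]
#' and serve as inputs to [anova_from_summary()] /
#' [chi_square_independence()].
#'
#' @return A list with elements `summaries` (data.frame: scale, group,
#'   mean, sd, lo, hi, n), `gender_counts` (2 x 3 matrix, male/female by
#'   group) and `group_n` (named vector).
#' @export
cohort_reference <- function() {
  g <- c("ASD", "TD", "DD")
  n <- c(ASD = 39L, TD = 26L, DD = 20L)
  row <- function(scale, m, s, lo, hi) {
    data.frame(scale = scale, group = g, mean = m, sd = s, lo = lo, hi = hi,
               n = as.integer(n), stringsAsFactors = FALSE)
  }
  summaries <- rbind(
    row("age_months",   c(23.5, 23.1, 22.1), c(3.8, 3.0, 3.5),  c(18, 18, 18),  c(30, 29, 30)),
    row("mullen_elc",   c(59.4, 105.2, 79.1), c(16.0, 7.7, 10.7), c(24, 94, 57), c(95, 127, 108)),
    row("mullen_rl",    c(22.2, 57.4, 37.2), c(7.2, 6.8, 13.3), c(20, 40, 20),  c(56, 78, 69)),
    row("mullen_el",    c(26.9, 48.1, 32.5), c(9.2, 8.7, 7.6),  c(20, 30, 20),  c(56, 68, 46)),
    row("mullen_fm",    c(32.1, 49.8, 35.7), c(11.6, 6.4, 12.8), c(20, 39, 20), c(50, 64, 66)),
    row("vabs_abc",     c(69.2, 95.2, 78.5), c(6.9, 8.3, 8.9),  c(57, 81, 64),  c(86, 115, 97)),
    row("vabs_rl",      c(11.1, 14.6, 13.3), c(3.4, 0.9, 1.3),  c(5, 13, 10),   c(28, 16, 15)),
    row("vabs_el",      c(5.8, 11.6, 8.1),   c(2.3, 1.8, 1.4),  c(2, 8, 6),     c(12, 15, 11)),
    row("ados_severity", c(7.3, 1.6, 2.2),   c(1.7, 1.0, 1.9),  c(4, 1, 1),     c(10, 4, 9)),
    row("ados_social",  c(11.6, 1.5, 4.0),   c(2.3, 1.4, 3.1),  c(6, 0, 0),     c(14, 5, 13)),
    row("ados_comm",    c(5.5, 1.1, 2.0),    c(1.6, 1.0, 2.0),  c(2, 0, 0),     c(9, 3, 8)),
    row("ados_rep",     c(2.7, 0.5, 1.1),    c(1.6, 0.7, 1.4),  c(0, 0, 0),     c(6, 2, 4))
  )
  gender <- matrix(c(29L, 10L, 19L, 7L, 17L, 3L), nrow = 2,
                   dimnames = list(c("male", "female"), g))
  list(summaries = summaries, gender_counts = gender, group_n = n)
}

#' Default group profiles for the cohort simulator
#'
#' Builds [group_profile]s for the ASD, TD and DD groups with
#' behavioral-score distributions taken from [cohort_reference()].
#' The ASD profile carries an elevated, long-tailed fast-modulation
#' gain whose latent is negatively coupled to VIQ, so that low-VIQ
#' ASD-like participants concentrate the plosive-like fast-timescale
#' energy; TD and DD share a unit gain. Vocalization rates (per minute)
#' are ordered TD > DD > ASD.
#'
#' @param n Optional named vector of group sizes to override the
#'   reference sizes (39/26/20), e.g. `c(ASD = 8, TD = 8, DD = 8)` for
#'   scaled-down simulations.
#' @return A named list of three [group_profile]s.
#' @export
default_profiles <- function(n = NULL) {
  ref <- cohort_reference()
  sizes <- ref$group_n
  if (!is.null(n)) sizes[names(n)] <- as.integer(n)
  male_p <- ref$gender_counts["male", ] / colSums(ref$gender_counts)
  prof <- function(label, gain, sdlog, rho, vr_mean, vr_sd) {
    s <- ref$summaries[ref$summaries$group == label, ]
    group_profile(
      label = label, n = sizes[[label]],
      score_means = stats::setNames(s$mean, s$scale),
      score_sds = stats::setNames(s$sd, s$scale),
      score_lo = stats::setNames(s$lo, s$scale),
      score_hi = stats::setNames(s$hi, s$scale),
      fast_modulation_gain = gain, gain_sdlog = sdlog, gain_viq_rho = rho,
      vocalization_rate_mean = vr_mean, vocalization_rate_sd = vr_sd,
      male_prop = male_p[[label]]
    )
  }
  list(
    ASD = prof("ASD", gain = 3.0, sdlog = 0.6, rho = -0.6,
               vr_mean = 6.0, vr_sd = 2.0),
    TD  = prof("TD",  gain = 1.0, sdlog = 0.3, rho = 0,
               vr_mean = 11.0, vr_sd = 3.0),
    DD  = prof("DD",  gain = 1.0, sdlog = 0.3, rho = 0,
               vr_mean = 7.5, vr_sd = 2.5)
  )
}

#' Cohort specification
#'
#' @param profiles List of [group_profile]s (default: [default_profiles()]).
#' @param sample_rate Audio rate in Hz (default 22050).
#' @param recording_duration Per-participant recording length, seconds
#'   (default 150, within the 2-5 minute naturalistic-sample range).
#' @param seed Integer seed; a fixed seed reproduces the cohort
#'   bit-identically.
#' @param burst_base Baseline plosive burst amplitude at unit gain.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(profiles = default_profiles(), sample_rate = 22050,
                        recording_duration = 150, seed = 1,
                        burst_base = 0.06) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "group_profile")))
  stopifnot_scalar_pos(sample_rate, "sample_rate")
  stopifnot_scalar_pos(recording_duration, "recording_duration")
  structure(
    list(profiles = profiles, sample_rate = sample_rate,
         recording_duration = recording_duration, seed = seed,
         burst_base = burst_base),
    class = "cohort_spec"
  )
}

# draw one participant's scores/latents; returns a one-row data.frame
draw_participant <- function(profile, id) {
  sm <- profile$score_means; ss <- profile$score_sds
  lo <- profile$score_lo; hi <- profile$score_hi
  scores <- numeric(length(sm)); names(scores) <- names(sm)
  lat <- numeric(length(sm)); names(lat) <- names(sm)
  for (nm in names(sm)) {
    z <- stats::rnorm(1)
    lat[nm] <- z
    p <- stats::pnorm(z)
    pl <- stats::pnorm(lo[nm], sm[nm], ss[nm])
    pu <- stats::pnorm(hi[nm], sm[nm], ss[nm])
    scores[nm] <- stats::qnorm(pl + p * (pu - pl), sm[nm], ss[nm])
  }
  viq <- (scores[["mullen_rl"]] + scores[["mullen_el"]]) / 2
  z_viq <- (lat[["mullen_rl"]] + lat[["mullen_el"]]) / sqrt(2)
  rho <- profile$gain_viq_rho
  z_gain <- rho * z_viq + sqrt(1 - rho ^ 2) * stats::rnorm(1)
  gain <- stats::qlnorm(stats::pnorm(z_gain),
                        meanlog = log(max(profile$fast_modulation_gain, 1e-12)),
                        sdlog = profile$gain_sdlog)
  if (profile$fast_modulation_gain == 0) gain <- 0
  voc_rate <- max(1, stats::rnorm(1, profile$vocalization_rate_mean,
                                  profile$vocalization_rate_sd))
  sex <- if (stats::runif(1) < profile$male_prop) "male" else "female"
  cbind(
    data.frame(id = id, group = profile$label, sex = sex,
               stringsAsFactors = FALSE),
    as.data.frame(as.list(scores)),
    data.frame(viq = viq, fast_gain = gain, voc_rate_target = voc_rate)
  )
}

# utterance/pause plan filling `dur_s` seconds at `rate` utterances/min
plan_utterances <- function(rate, dur_s) {
  n_utt <- max(1L, as.integer(round(rate * dur_s / 60)))
  utt <- stats::rlnorm(n_utt, meanlog = log(1.2), sdlog = 0.35) * 1000
  total_utt <- sum(utt) / 1000
  budget <- dur_s - 0.4 * max(n_utt - 1L, 0)  # reserve >= 400 ms pauses
  if (total_utt > 0.7 * budget) utt <- utt * (0.7 * budget * 1000 / sum(utt))
  spare <- dur_s - sum(utt) / 1000 - 0.4 * max(n_utt - 1L, 0)
  if (n_utt > 1L) {
    w <- stats::rgamma(n_utt - 1L, shape = 1.5)
    pauses <- 400 + 0.85 * spare * 1000 * w / sum(w)
  } else {
    pauses <- numeric(0)
  }
  list(utterances = utt, pauses = pauses)
}

#' Generate a synthetic cohort
#'
#' Draws per-participant behavioral scores, fast-modulation gains and
#' vocalization plans from each [group_profile], and (optionally)
#' renders each participant's audio. Fully deterministic for a fixed
#' [cohort_spec] seed.
#'
#' @param spec A [cohort_spec].
#' @param audio If `FALSE`, skip waveform synthesis and return scores
#'   only (fast; useful for statistics-level simulation).
#' @return A list of class `cohort` with elements
#'   `participants` (data.frame: id, group, sex, scores, `viq`,
#'   `fast_gain`, `voc_rate_target`), `audio` (named list of
#'   [audio_sample] or `NULL`), `specs` (named list of
#'   [syllable_train_spec]) and `spec` (the input).
#' @export
generate_cohort <- function(spec = cohort_spec(), audio = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  rows <- list()
  audio_list <- list()
  spec_list <- list()
  idx <- 0L
  for (profile in spec$profiles) {
    for (i in seq_len(profile$n)) {
      idx <- idx + 1L
      id <- sprintf("%s_%02d", profile$label, i)
      pseed <- child_seed(spec$seed, idx)
      row <- with_seed(pseed, draw_participant(profile, id))
      plan <- with_seed(pseed + 1, plan_utterances(row$voc_rate_target,
                                                   spec$recording_duration))
      sts <- syllable_train_spec(
        syllable_rate = 4 + (row$viq - 40) / 40,  # mild VIQ-linked tempo
        # the gain multiplies transient energy: both the event rate and
        # the per-event amplitude grow with it
        burst_rate = 3 * row$fast_gain,
        burst_duration = 10,
        burst_level = spec$burst_base * row$fast_gain,
        carrier_f0 = 300,
        noise_snr = 60,
        utterance_durations = plan$utterances,
        pause_durations = plan$pauses
      )
      rows[[idx]] <- row
      spec_list[[id]] <- sts
      if (audio) {
        audio_list[[id]] <- generate_vocalization(
          sts, spec$sample_rate, seed = pseed + 2,
          total_duration = spec$recording_duration)
      }
    }
  }
  participants <- do.call(rbind, rows)
  rownames(participants) <- NULL
  structure(list(participants = participants,
                 audio = if (audio) audio_list else NULL,
                 specs = spec_list, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$participants$group)
  cat(sprintf("<cohort: %d participants (%s)%s>\n",
              nrow(x$participants),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              if (is.null(x$audio)) ", scores only" else ""))
  invisible(x)
}

#' Impose a target correlation between a feature and a score
#'
#' Regenerates the named score column as a Gaussian linear coupling to
#' the (standardized) feature column, preserving the score's sample
#' mean and SD, so that the population Pearson correlation between the
#' two equals `rho` (`rho = 1` reproduces the feature up to affine
#' scaling, hence sample `r = 1` exactly).
#'
#' @param records Data.frame of participant records.
#' @param feature_name,score_name Column names in `records`.
#' @param rho Target correlation in `[-1, 1]`.
#' @param seed Integer seed for the independent Gaussian component.
#' @return `records` with the score column replaced.
#' @export
inject_correlation <- function(records, feature_name, score_name, rho,
                               seed = 1) {
  stopifnot(is.data.frame(records), abs(rho) <= 1)
  if (!feature_name %in% names(records)) {
    stop("unknown feature column: ", feature_name, call. = FALSE)
  }
  if (!score_name %in% names(records)) {
    stop("unknown score column: ", score_name, call. = FALSE)
  }
  f <- records[[feature_name]]
  s <- records[[score_name]]
  if (stats::sd(f) == 0) stop("feature column is constant", call. = FALSE)
  zf <- (f - mean(f)) / stats::sd(f)
  eps <- with_seed(seed, stats::rnorm(length(f)))
  z <- rho * zf + sqrt(1 - rho ^ 2) * eps
  records[[score_name]] <- mean(s) + stats::sd(s) * z
  records
}
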