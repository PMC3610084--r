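test_that("a pure tone concentrates spectrogram energy at its frequency", {
  a <- audio_sample(sin(2 * pi * 1000 * seq(0, 1, by = 1 / FS)), FS)
  sg <- compute_spectrogram(a, spectrogram_config(amplitude_scale = "linear"))
  row_power <- rowMeans(sg$magnitude^2)
  expect_equal(sg$freq[which.max(row_power)], 1000,
               tolerance = sg$freq_step)
})

test_that("silence maps to a flat floored spectrogram", {
  a <- audio_sample(numeric(FS), FS)
  sg <- compute_spectrogram(a)
  expect_equal(length(unique(as.vector(sg$magnitude))), 1L)
})

test_that("magnitude is invariant to shifts by whole hops", {
  set.seed(14)
  hop_samp <- round(0.002 * FS)
  x <- rnorm(FS)
  a1 <- audio_sample(c(x, numeric(hop_samp * 3)), FS)
  a2 <- audio_sample(c(numeric(hop_samp * 3), x), FS)
  g1 <- compute_spectrogram(a1)
  g2 <- compute_spectrogram(a2)
  n <- ncol(g1$magnitude) - 3
  expect_equal(g1$magnitude[, 1:n], g2$magnitude[, 4:(n + 3)],
               tolerance = 1e-9)
})

test_that("too-short samples and bad configs are rejected", {
  expect_error(compute_spectrogram(audio_sample(numeric(500), FS)),
               "too short")
  expect_error(spectrogram_config(hop = 30, window_length = 25), "hop")
  expect_error(spectrogram_config(hop = 6), "Nyquist")
})

test_that("the 2-D transform conserves energy and is quadrant-symmetric", {
  for (s in 1:50) {
    set.seed(s)
    nr <- sample(10:40, 1)
    nt <- sample(20:60, 1)
    sg <- as_spectrogram(matrix(rnorm(nr * nt), nr, nt),
                         freq_step = 20, time_step = 0.005)
    ms <- compute_modulation_spectrum(sg, chunk_duration = nt * 0.005,
                                      chunk_overlap = 0)
    # Parseval: unnormalized power total equals mean-removed energy
    ch <- sg$magnitude - mean(sg$magnitude)
    expect_lt(abs(ms$total_power - sum(ch^2)) / sum(ch^2), 1e-6)
    # Hermitian symmetry of the power surface
    iwf <- match(round(-ms$wf, 9), round(ms$wf, 9))
    iwt <- match(round(-ms$wt, 9), round(ms$wt, 9))
    ok <- !is.na(iwf)
    okt <- !is.na(iwt)
    expect_equal(ms$power[ok, okt], ms$power[iwf[ok], iwt[okt]],
                 tolerance = 1e-12)
  }
})

test_that("modulation power is normalized and the marginal conserves it", {
  v <- make_vocalization(gain = 1, seed = 2)
  ms <- compute_modulation_spectrum(compute_spectrogram(v))
  expect_equal(sum(ms$power), 1, tolerance = 1e-9)
  m <- wt_marginal(ms)
  expect_equal(sum(m), sum(ms$power), tolerance = 1e-12)
  # even marginal over +/- omega_t for paired bins
  wt <- ms$wt
  neg <- match(round(-wt, 9), round(wt, 9))
  ok <- !is.na(neg)
  expect_equal(unname(m[ok]), unname(m[neg[ok]]), tolerance = 1e-9)
})

test_that("AM-tone temporal modulation appears at the modulation rate", {
  rates <- c(5, 9, 14)
  doms <- vapply(rates, function(r) {
    ms <- compute_modulation_spectrum(compute_spectrogram(make_am_tone(r)))
    m <- wt_marginal(ms)
    nz <- abs(ms$wt) > 1e-9
    abs(ms$wt[nz][which.max(m[nz])])
  }, 0)
  expect_equal(doms, rates, tolerance = 0.2)
  # faster envelopes shift the dominant bin strictly rightward
  expect_true(all(diff(doms) > 0))
})

test_that("stationary noise concentrates toward the zero-temporal-modulation column", {
  set.seed(99)
  noise <- audio_sample(rnorm(6 * FS, sd = 0.2), FS)
  ratio_for <- function(dur) {
    sg <- compute_spectrogram(audio_sample(noise$samples[1:(dur * FS)], FS))
    ms <- compute_modulation_spectrum(sg)
    dc_col <- abs(ms$wt) < 1e-9
    sum(ms$power[, !dc_col]) / sum(ms$power[, dc_col])
  }
  expect_lt(ratio_for(6), ratio_for(2))
})

test_that("chunking precondition is enforced", {
  a <- audio_sample(sin(2 * pi * 500 * seq(0, 0.3, by = 1 / FS)), FS)
  sg <- compute_spectrogram(a)
  expect_error(compute_modulation_spectrum(sg, chunk_duration = 1),
               "at least one chunk")
})
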