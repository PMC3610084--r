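test_that("the amplitude envelope fluctuates at the requested syllable rate", {
  sts <- syllable_train_spec(syllable_rate = 5,
                             vowel_duration = 200,  # full period: smooth train
                             formant_sweep = NULL, burst_rate = 0,
                             utterance_durations = 2000)
  v <- generate_vocalization(sts, FS, seed = 4)
  env <- envelope_of(v$samples)
  env <- env - mean(env)
  sp <- Mod(fft(env))^2
  hz <- (seq_along(sp) - 1) / v$duration
  half <- hz <= FS / 2
  peak_hz <- hz[half][which.max(sp[half])]
  expect_equal(peak_hz, 5, tolerance = 0.3)
})

test_that("zero utterances yield silence of the requested duration", {
  sts <- syllable_train_spec(utterance_durations = numeric(0))
  v <- generate_vocalization(sts, FS, seed = 1, total_duration = 0.5)
  expect_equal(length(v$samples), round(0.5 * FS))
  expect_true(all(v$samples == 0))
})

test_that("synthesis is deterministic per seed and leaves the RNG alone", {
  sts <- syllable_train_spec(burst_rate = 4, burst_level = 0.1,
                             noise_snr = 40,
                             utterance_durations = c(800, 600),
                             pause_durations = 400)
  set.seed(123); before <- .Random.seed
  v1 <- generate_vocalization(sts, FS, seed = 9)
  expect_identical(.Random.seed, before)
  v2 <- generate_vocalization(sts, FS, seed = 9)
  v3 <- generate_vocalization(sts, FS, seed = 10)
  expect_identical(v1$samples, v2$samples)
  expect_false(identical(v1$samples, v3$samples))
})

test_that("spec validation rejects ill-formed syllable trains", {
  expect_error(syllable_train_spec(syllable_rate = 0), "syllable_rate")
  expect_error(syllable_train_spec(syllable_rate = 150), "syllable_rate")
  expect_error(syllable_train_spec(utterance_durations = c(500, 500),
                                   pause_durations = numeric(0)),
               "pause")
  expect_error(syllable_train_spec(utterance_durations = -5), "positive")
})

test_that("cohort generation matches profile sizes and reproduces under seed", {
  coh <- generate_cohort(cohort_spec(seed = 21), audio = FALSE)
  expect_equal(nrow(coh$participants), 85)  # 39 + 26 + 20
  expect_equal(as.vector(table(coh$participants$group)[c("ASD", "TD", "DD")]),
               c(39, 26, 20))
  coh2 <- generate_cohort(cohort_spec(seed = 21), audio = FALSE)
  expect_identical(coh$participants, coh2$participants)
  coh3 <- generate_cohort(cohort_spec(seed = 22), audio = FALSE)
  expect_false(identical(coh$participants, coh3$participants))
})

test_that("behavioral scores follow the profile distributions", {
  profiles <- default_profiles(n = c(ASD = 2, TD = 1000, DD = 2))
  coh <- generate_cohort(cohort_spec(profiles = profiles, seed = 5),
                         audio = FALSE)
  td <- coh$participants[coh$participants$group == "TD", ]
  # TD expressive-language T-score: mean 48.1, SD 8.7 at n = 1000
  se <- 8.7 / sqrt(1000)
  expect_lt(abs(mean(td$mullen_el) - 48.1), 3 * se)
  expect_equal(sd(td$mullen_el), 8.7, tolerance = 0.15)
  # truncation keeps every score inside its published range
  expect_true(all(td$mullen_el >= 30 & td$mullen_el <= 68))
  expect_true(all(td$ados_severity >= 1 & td$ados_severity <= 4))
  # viq is the mean of the two language scores
  expect_equal(td$viq, (td$mullen_rl + td$mullen_el) / 2)
})

test_that("ASD-like gain is long-tailed and negatively coupled to VIQ", {
  profiles <- default_profiles(n = c(ASD = 800, TD = 2, DD = 2))
  coh <- generate_cohort(cohort_spec(profiles = profiles, seed = 31),
                         audio = FALSE)
  asd <- coh$participants[coh$participants$group == "ASD", ]
  expect_gt(mean(asd$fast_gain), median(asd$fast_gain))  # right skew
  expect_lt(cor(asd$fast_gain, asd$viq), -0.3)
  expect_equal(median(asd$fast_gain), 3, tolerance = 0.25)
})

test_that("injected correlations are recovered", {
  profiles <- default_profiles(n = c(ASD = 2, TD = 1000, DD = 2))
  rec <- generate_cohort(cohort_spec(profiles = profiles, seed = 77),
                         audio = FALSE)$participants
  rec <- rec[rec$group == "TD", ]

  r0 <- inject_correlation(rec, "fast_gain", "mullen_rl", 0, seed = 1)
  expect_lte(abs(cor(r0$fast_gain, r0$mullen_rl)), 0.1)

  r1 <- inject_correlation(rec, "fast_gain", "mullen_rl", 1, seed = 1)
  expect_equal(cor(r1$fast_gain, r1$mullen_rl), 1, tolerance = 1e-12)

  rec500 <- rec[1:500, ]
  r5 <- inject_correlation(rec500, "fast_gain", "mullen_rl", 0.5, seed = 2)
  r_obs <- cor(r5$fast_gain, r5$mullen_rl)
  ci <- tanh(atanh(r_obs) + c(-1, 1) * 1.96 / sqrt(500 - 3))
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])

  expect_error(inject_correlation(rec, "nope", "mullen_rl", 0.5), "unknown")
  expect_error(inject_correlation(rec, "fast_gain", "nope", 0.5), "unknown")
})
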