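test_that("WAV round-trip is exact to within one 16-bit quantization step", {
  set.seed(11)
  x <- runif(2205, -0.9, 0.9)
  a <- audio_sample(x, FS)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(a, path)
  b <- read_wav(path)
  expect_equal(b$sample_rate, FS)
  expect_equal(length(b$samples), length(x))
  expect_lt(max(abs(b$samples - x)), 1 / 32767)
})

test_that("a second of zeros reads back with the right duration and length", {
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(audio_sample(numeric(FS), FS), path)
  a <- read_wav(path)
  expect_equal(a$duration, 1.0)
  expect_equal(length(a$samples), FS)
  expect_true(all(a$samples == 0))
})

test_that("stereo input is mixed down to the channel mean", {
  # hand-write a minimal stereo PCM file: L = 0.5, R = -0.25 throughout
  n <- 1000
  left <- as.integer(round(0.5 * 32767))
  right <- as.integer(round(-0.25 * 32767))
  path <- withr::local_tempfile(fileext = ".wav")
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 4 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 2L), con, size = 2, endian = "little")
  writeBin(c(8000L, 32000L), con, size = 4, endian = "little")
  writeBin(c(4L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(4 * n), con, size = 4, endian = "little")
  writeBin(rep(c(left, right), n), con, size = 2, endian = "little")
  close(con)

  a <- read_wav(path)
  expect_equal(length(a$samples), n)
  expect_equal(a$samples[1], (left + right) / 2 / 32768, tolerance = 1e-12)
})

test_that("read_wav rejects non-PCM content", {
  path <- withr::local_tempfile(fileext = ".wav")
  writeBin(as.raw(1:64), path)
  expect_error(read_wav(path), "RIFF")
})

test_that("resampling preserves rate-matched input, tone power, and length", {
  a <- audio_sample(sin(2 * pi * 440 * seq(0, 1, by = 1 / FS)), FS)
  expect_identical(resample(a, FS), a)

  # 44100 -> 22050: a 1 kHz tone keeps its power within 1%
  fs1 <- 44100
  t <- seq(0, 2 - 1 / fs1, by = 1 / fs1)
  tone <- audio_sample(sin(2 * pi * 1000 * t), fs1)
  down <- resample(tone, 22050)
  expect_equal(down$sample_rate, 22050)
  expect_lt(abs(mean(down$samples^2) / mean(tone$samples^2) - 1), 0.01)
  expect_lt(abs(down$duration - tone$duration), 1 / 22050)

  # 8000 -> 22050 length scaling
  up <- resample(audio_sample(numeric(8000), 8000), 22050)
  expect_lte(abs(length(up$samples) - 22050), 1)
})

test_that("excision and concatenation conserve duration and retained content", {
  fs <- 8000
  two_min <- lapply(1:2, function(i) {
    audio_sample(sin(2 * pi * 300 * seq(0, 60, by = 1 / fs))[1:(60 * fs)], fs)
  })
  joined <- excise_and_concatenate(two_min, min_duration_s = 100)
  expect_equal(joined$duration, 120)

  # excise 10 s total from 130 s -> 120 s within one sample
  set.seed(3)
  x <- audio_sample(rnorm(130 * fs, sd = 0.1), fs)
  ann <- exclusion_annotation(rbind(c(20, 26), c(100, 104)))
  cut <- excise_and_concatenate(list(x), list(ann), min_duration_s = 100)
  expect_lt(abs(cut$duration - 120), 1 / fs)

  # with no cross-fade, retained samples pass through bit-exact
  cut0 <- excise_and_concatenate(list(x), list(ann), crossfade_ms = 0,
                                 min_duration_s = 100)
  expect_identical(cut0$samples[1:(20 * fs)], x$samples[1:(20 * fs)])

  # excising everything yields an empty, flagged sample
  all_gone <- exclusion_annotation(rbind(c(0, 200)))
  expect_warning(
    empty <- excise_and_concatenate(list(x), list(all_gone)),
    "excised")
  expect_equal(length(empty$samples), 0)
  expect_true(attr(empty, "empty"))
})

test_that("concatenation without annotations is associative", {
  fs <- 4000
  set.seed(8)
  parts <- lapply(1:3, function(i) audio_sample(rnorm(fs), fs))
  left <- excise_and_concatenate(
    list(excise_and_concatenate(parts[1:2], min_duration_s = 0),
         parts[[3]]), min_duration_s = 0)
  right <- excise_and_concatenate(
    list(parts[[1]],
         excise_and_concatenate(parts[2:3], min_duration_s = 0)),
    min_duration_s = 0)
  expect_identical(left$samples, right$samples)
})

test_that("mixed sample rates are rejected before concatenation", {
  expect_error(
    excise_and_concatenate(list(audio_sample(numeric(10), 8000),
                                audio_sample(numeric(10), 22050))),
    "share one sample rate")
})

test_that("annotation intervals are normalized and validated", {
  ann <- exclusion_annotation(rbind(c(5, 8), c(1, 3), c(2.5, 4)))
  expect_equal(ann$intervals, cbind(start = c(1, 5), end = c(4, 8)))
  expect_error(exclusion_annotation(rbind(c(3, 2))), "end > start")

  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(start = c(0, 2), end = c(1, 3)), path,
            row.names = FALSE)
  expect_equal(read_annotation_csv(path)$intervals,
               cbind(start = c(0, 2), end = c(1, 3)))
})
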