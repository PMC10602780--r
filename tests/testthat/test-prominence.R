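test_that("semitone conversion has the exact logarithmic properties", {
  expect_equal(hz_to_semitones(100, 100), 0)
  expect_equal(hz_to_semitones(200, 100), 12)
  expect_equal(hz_to_semitones(100), 12 * log2(100))
  expect_equal(round(hz_to_semitones(100), 2), 79.73)
  f <- seq(60, 300, by = 5)
  st <- hz_to_semitones(f)
  expect_true(all(diff(st) > 0))
  expect_equal(hz_to_semitones(2 * f) - st, rep(12, length(f)))
  expect_error(hz_to_semitones(-5), "positive")
  expect_error(hz_to_semitones(100, ref_hz = 0), "positive")
})

test_that("f0 recovery on harmonic tones is within 2 Hz across the range", {
  for (f in c(80, 120, 180, 250)) {
    au <- audio_signal(tone(0.8, f), 16000)
    tr <- extract_f0(au)
    v <- tr$f0[!is.na(tr$f0)]
    expect_gt(length(v), 0.9 * nrow(tr))
    expect_true(all(abs(v - f) <= 2))
  }
})

test_that("white noise is essentially unvoiced", {
  set.seed(8)
  au <- audio_signal(runif(16000, -0.5, 0.5), 16000)
  tr <- extract_f0(au)
  expect_gte(mean(is.na(tr$f0)), 0.9)
})

test_that("a rising glide tracks monotonically within tolerance", {
  sr <- 16000
  f0t <- seq(100, 200, length.out = sr)
  au <- audio_signal(0.4 * sin(2 * pi * cumsum(f0t) / sr), sr)
  tr <- extract_f0(au)
  v <- tr$f0[!is.na(tr$f0)]
  expect_gt(length(v), 50)
  expect_true(all(diff(v) > -1))
  expect_lt(min(v), 115)
  expect_gt(max(v), 185)
})

test_that("nucleus selection finds the rise-peak-fall and clamps padding", {
  sr <- 16000
  tt <- seq_len(1.2 * sr) / sr
  f0t <- 120 * 2^(3 * sin(pi * pmin(pmax((tt - 0.3) / 0.6, 0), 1)) / 12)
  au <- audio_signal(0.4 * sin(2 * pi * cumsum(f0t) / sr), sr)
  f0 <- extract_f0(au)
  syl <- data.frame(start_s = seq(0, 1.0, 0.2), end_s = seq(0.2, 1.2, 0.2))
  ns <- select_nucleus_span(f0, syl)
  expect_identical(ns$syllable_range, c(2L, 5L))
  expect_false(attr(ns, "flagged"))
  # padding is clamped at two syllables per side
  ns5 <- select_nucleus_span(f0, syl, pad_syllables = 5)
  ns2 <- select_nucleus_span(f0, syl, pad_syllables = 2)
  expect_identical(ns5$syllable_range, ns2$syllable_range)
  # flat contour: flagged fallback over the voiced run
  flat <- extract_f0(audio_signal(0.4 * sin(2 * pi * 120 * tt), sr))
  nf <- select_nucleus_span(flat, syl)
  expect_true(attr(nf, "flagged"))
  expect_identical(nf$syllable_range, c(1L, 6L))
})

test_that("spectral emphasis matches closed forms and is gain-invariant", {
  sr <- 16000
  tt <- seq_len(sr) / sr
  pure <- audio_signal(0.5 * sin(2 * pi * 100 * tt), sr)
  expect_lt(abs(spectral_emphasis(pure, cutoff_policy = 400)), 0.01)
  two <- audio_signal(0.3 * sin(2 * pi * 100 * tt) +
                        0.3 * sin(2 * pi * 1000 * tt), sr)
  expect_equal(spectral_emphasis(two, cutoff_policy = 400),
               10 * log10(2), tolerance = 1e-6)
  # raising the high component strictly raises emphasis
  prev <- -Inf
  for (a in c(0.1, 0.2, 0.3, 0.4)) {
    au <- audio_signal(0.3 * sin(2 * pi * 100 * tt) +
                         a * sin(2 * pi * 1000 * tt), sr)
    e <- spectral_emphasis(au, cutoff_policy = 400)
    expect_gt(e, prev)
    prev <- e
  }
  # overall gain cancels out of the band ratio
  e1 <- spectral_emphasis(two, cutoff_policy = 400)
  louder <- audio_signal(two$samples * 10^(6 / 20), sr)
  expect_equal(spectral_emphasis(louder, cutoff_policy = 400), e1,
               tolerance = 1e-9)
  # automatic cutoff uses the span's own f0
  e_auto <- spectral_emphasis(pure, cutoff_policy = "auto")
  expect_lt(abs(e_auto), 0.05)
  expect_error(spectral_emphasis(audio_signal(rep(0, 1000), sr)),
               "silent")
})

test_that("cvint matches its closed form and is scale-invariant", {
  itr <- data.frame(time = c(0, 0.01), db = c(60, 80))
  expect_equal(cv_intensity(itr), 100 * 10 / 70, tolerance = 1e-12)
  const <- data.frame(time = seq(0, 1, 0.01), db = rep(70, 101))
  expect_equal(cv_intensity(const), 0)
  v <- data.frame(time = seq(0, 0.9, 0.1), db = c(60, 70, 65, 80, 72,
                                                  68, 75, 66, 71, 69))
  expect_equal(cv_intensity(v),
               cv_intensity(transform(v, db = db * 3)),
               tolerance = 1e-12)
  expect_error(cv_intensity(data.frame(time = 0, db = 70)), "two")
  expect_error(cv_intensity(data.frame(time = c(0, 0.01),
                                       db = c(-10, 5))), "mean")
})

test_that("prominence profiles use per-frame semitone statistics", {
  sr <- 16000
  # constant 150 Hz span
  au <- audio_signal(tone(1, 150), sr)
  pr <- prominence_profile(au, c(0, 1))
  expect_lt(abs(pr$f0mean_hz - 150), 2)
  expect_lt(pr$f0sd_hz, 1)
  # two-level contour: semitone mean is the mean of per-frame conversions
  au2 <- audio_signal(c(tone(0.5, 100), tone(0.5, 200)), sr)
  pr2 <- prominence_profile(au2, c(0, 1))
  st_expected <- mean(c(hz_to_semitones(100), hz_to_semitones(200)))
  expect_lt(abs(pr2$f0mean_st - st_expected), 0.6)
  # conversion of the Hz mean would be distinctly larger
  expect_lt(pr2$f0mean_st + 0.4, hz_to_semitones(pr2$f0mean_hz))
  expect_gt(pr2$f0sd_st, 3)
  # unvoiced span: f0 fields absent, emphasis and cvint still computed
  set.seed(3)
  noise <- audio_signal(runif(sr, -0.3, 0.3), sr)
  pr3 <- prominence_profile(noise, c(0, 1))
  expect_true(is.na(pr3$f0mean_hz))
  expect_false(is.na(pr3$emph_db))
  expect_false(is.na(pr3$cvint))
})

test_that("group summaries pool with prominence weights", {
  prof <- data.frame(speaker = c("A", "B"), unit_role = "COM",
                     f0mean_hz = c(100, 120), f0mean_st = c(79.7, 82.9),
                     f0sd_hz = c(10, 20), f0sd_st = c(1, 2),
                     emph_db = c(2, 3), cvint = c(3, 5))
  gs <- group_summary(prof)
  pooled <- gs[gs$speaker == "POOLED", ]
  expect_equal(pooled$f0mean_hz, 110)
  # 3 prominences at 100 and 1 at 200 pool to 125, not 150
  prof2 <- data.frame(speaker = c("A", "A", "A", "B"), unit_role = "COM",
                      f0mean_hz = c(100, 100, 100, 200),
                      f0mean_st = 80, f0sd_hz = 1, f0sd_st = 1,
                      emph_db = 1, cvint = 1)
  gs2 <- group_summary(prof2)
  expect_equal(gs2$f0mean_hz[gs2$speaker == "POOLED"], 125)
  expect_identical(gs2$n[gs2$speaker == "POOLED"], 4L)
})

test_that("synthetic spans recover their planted f0 ground truth", {
  sp <- synth_spec(seed = 13, n_turns = 8,
                   audio = list(rate = 16000,
                                f0_base = c(PAT = 110, DOC = 180),
                                token_dur_s = 0.2, amp_db = -12,
                                exc_st = c(COM = 0, TOP = 0, other = 0),
                                slope = c(COM = 1.5, TOP = 1.5,
                                          other = 1.5),
                                am_db = c(COM = 0, TOP = 0, other = 0)))
  g <- gen_transcript(sp)
  au <- gen_audio(sp, g)
  pr <- prominence_profiles(au$audio, au$spans)
  expect_gt(nrow(pr), 2)
  expect_true(all(abs(pr$f0mean_hz - au$truth$spans$f0mean_hz) <= 2))
  expect_true(all(pr$f0sd_hz < 2))
})
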