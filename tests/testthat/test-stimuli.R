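test_that("tone generators are calibrated to dB SPL over the steady portion", {
  fs <- 48000
  cases <- list(list(f = 1000, lv = 100, rms = 2.0),
                list(f = 500,  lv = 40,  rms = 2.0e-3))
  for (cs in cases) {
    tone <- make_pure_tone(cs$f, 0.1, cs$lv, ramp_dur = 0.01, fs = fs)
    rms <- sqrt(mean(tone$samples[seq(0.02 * fs, 0.08 * fs)]^2))
    expect_equal(rms, cs$rms, tolerance = 0.05 / 8.686)  # 0.05 dB
  }
  # AM tone: rms calibration holds for any modulation index
  for (m in c(0, 0.5, 1)) {
    am <- make_am_tone(4000, 100, m, 0.3, 60, fs = fs)
    lvl <- seg_level(am$samples, fs, 0.05, 0.25)
    expect_lt(abs(lvl - 60), 0.05)
  }
  # complex tone: total rms calibrated, equal component peak amplitudes
  ct <- make_complex_tone(c(414, 650, 1000), 50, 0.5, fs)
  lvl <- seg_level(ct$samples, fs, 0.05, 0.45)
  expect_lt(abs(lvl - 50), 0.05)
  # equal component peak amplitudes, estimated by least-squares projection
  idx <- seq(0.05 * fs + 1, 0.45 * fs)
  t <- (idx - 1) / fs
  amps <- vapply(c(414, 650, 1000), function(f) {
    fit <- lm(ct$samples[idx] ~ sin(2 * pi * f * t) + cos(2 * pi * f * t) - 1)
    sqrt(sum(coef(fit)^2))
  }, numeric(1))
  expect_lt(diff(range(amps)) / mean(amps), 0.01)
})

test_that("degenerate stimuli reduce to simpler ones", {
  fs <- 48000
  am0 <- make_am_tone(1000, 100, 0, 0.1, 70, fs = fs)
  pt <- make_pure_tone(1000, 0.1, 70, fs = fs)
  expect_equal(am0$samples, pt$samples)
  ct1 <- make_complex_tone(500, 65, 0.1, fs)
  pt2 <- make_pure_tone(500, 0.1, 65, fs = fs)
  expect_equal(ct1$samples, pt2$samples)
  # rectangular gating: peak equals rms * sqrt(2)
  rect <- make_pure_tone(1000, 0.1, 80, ramp_dur = 0, fs = fs)
  expect_equal(max(abs(rect$samples)), spl_to_pa(80) * sqrt(2),
               tolerance = 1e-6)
})

test_that("generator preconditions are enforced", {
  expect_error(make_pure_tone(30000, 0.1, 60, fs = 48000), "Nyquist|fs/2")
  expect_error(make_pure_tone(1000, -0.1, 60), "positive")
  expect_error(make_pure_tone(1000, 0.01, 60, ramp_dur = 0.01), "ramp")
  expect_error(make_am_tone(1000, 100, 1.5, 0.1, 60), "m must")
  expect_error(make_complex_tone(numeric(0), 50, 0.1), "empty")
  expect_error(make_frozen_noise(1, 40, band = c(20, 30000), fs = 48000),
               "band")
  expect_error(make_click_train(rate = 10, click_dur = 0.2), "shorter")
})

test_that("frozen noise is seed-deterministic, flat and calibrated", {
  n1 <- make_frozen_noise(1, 40, seed = 7)
  n2 <- make_frozen_noise(1, 40, seed = 7)
  expect_identical(n1$samples, n2$samples)
  n3 <- make_frozen_noise(1, 40, seed = 8)
  expect_false(identical(n1$samples, n3$samples))
  # calibration over the steady (unramped) portion
  expect_lt(abs(stim_level(n1, c(0.02, 0.98)) - 40), 0.05)
  # third-octave band levels flat within +-1 dB over 100-10000 Hz
  fs <- 48000
  p <- Mod(fft(n1$samples))^2
  f <- (0:(length(p) - 1)) * fs / length(p)
  ctr <- 10^seq(log10(100), log10(10000), by = 0.1)
  lev <- vapply(ctr, function(fc) {
    sel <- f >= fc * 2^(-1 / 6) & f < fc * 2^(1 / 6)
    10 * log10(mean(p[sel]))
  }, numeric(1))
  expect_lt(max(lev) - min(lev), 2)  # +-1 dB about the mean
})

test_that("click trains have the stated amplitude, count and polarity", {
  fs <- 48000
  tr <- make_click_train(rate = 10, dur = 1, pe_spl = 70, fs = fs)
  expect_equal(max(tr$samples), 0.1789, tolerance = 1e-3)
  expect_equal(tr$n_clicks, 10L)
  # click 9 positive, click 10 negative (first click positive, alternating)
  c9 <- tr$samples[round(0.8 * fs) + 3L]
  c10 <- tr$samples[round(0.9 * fs) + 3L]
  expect_gt(c9, 0); expect_lt(c10, 0)
  expect_equal(abs(c9), abs(c10))
  # non-alternating train is all-positive
  tp <- make_click_train(alternating = FALSE, fs = fs)
  expect_gte(min(tp$samples), 0)
})

test_that("ramps never raise the peak and duration is exact", {
  tone <- make_pure_tone(250, 0.05, 60, ramp_dur = 0.01)
  rect <- make_pure_tone(250, 0.05, 60, ramp_dur = 0)
  expect_lte(max(abs(tone$samples)), max(abs(rect$samples)) + 1e-12)
  expect_equal(stim_duration(tone), 0.05)
})

test_that("the input level convention is applied once and only once", {
  tone <- make_pure_tone(1000, 0.05, 60)
  s1 <- apply_model_level_convention(tone, "dau1997")
  expect_equal(s1$samples, 0.5 * tone$samples)
  expect_error(apply_model_level_convention(s1, "dau1997"), "already")
  s2 <- apply_model_level_convention(tone, "zilany2014")
  expect_equal(s2$samples, tone$samples)  # Pa-convention chains: identity
})

test_that("WAV round trip preserves samples in Pascal", {
  tone <- make_pure_tone(440, 0.02, 60)
  path <- tempfile(fileext = ".wav")
  write_wav_pa(tone, path)
  back <- read_wav_pa(path)
  expect_equal(back$fs, 48000)
  expect_equal(back$samples, tone$samples, tolerance = 1e-6)
  expect_equal(back$level_db, 60)
  unlink(c(path, paste0(path, ".txt")))
})
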