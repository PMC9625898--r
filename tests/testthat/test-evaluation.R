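test_that("run_chain validates taps and is deterministic", {
  tone <- make_pure_tone(1000, 0.05, 60)
  expect_error(run_chain(tone, dau_chain, tap = "cortex"), "unknown tap")
  y1 <- run_chain(tone, dau_chain, tap = "an", cfs = 1000)
  y2 <- run_chain(tone, dau_chain, tap = "an", cfs = 1000)
  expect_identical(y1, y2)
  # a stimulus carrying another chain's convention is rejected
  pre <- apply_model_level_convention(make_pure_tone(1000, 0.05, 60),
                                      "king2019")
  expect_error(run_chain(pre, dau_chain, tap = "an", cfs = 1000),
               "convention")
  expect_error(ihc_preset("nosuchmodel"), "unknown")
})

test_that("I/O curves are 1 dB/dB for linear chains, compressive for king2019", {
  for (freq in c(500, 4000)) {
    io <- io_curves(dau_chain, freq, seq(0, 100, 20))
    slopes <- vapply(split(io, io$offset), function(d)
      unname(coef(lm(output_db ~ level_db, d))[2]), numeric(1))
    expect_equal(unname(slopes), rep(1, 3), tolerance = 1e-3)
  }
  io_k <- io_curves(king_chain, 4000, seq(0, 100, 10))
  on <- io_k[io_k$offset == "on" & io_k$level_db >= 50, ]
  local_slopes <- diff(on$output_db) / diff(on$level_db)
  expect_equal(local_slopes, rep(0.3, length(local_slopes)),
               tolerance = 0.02)  # broken-stick oracle above the knee
})

test_that("excitation patterns peak on-CF and match the I/O points", {
  tone <- make_pure_tone(500, 0.1, 70, ramp_dur = 0.01)
  cfs <- erbspace(125, 4000, 21)
  ep <- excitation_pattern(dau_chain, tone, cfs)
  expect_equal(ep$cf[which.max(ep$output_db)], cfs[which.min(abs(cfs - 500))])
  # linearity: 40- vs 100-dB patterns differ by exactly 60 dB
  t40 <- make_pure_tone(500, 0.1, 40, ramp_dur = 0.01)
  t100 <- make_pure_tone(500, 0.1, 100, ramp_dur = 0.01)
  p40 <- excitation_pattern(dau_chain, t40, cfs)
  p100 <- excitation_pattern(dau_chain, t100, cfs)
  expect_equal(p100$output_db - p40$output_db, rep(60, length(cfs)),
               tolerance = 1e-6)
  # cross-procedure consistency with the I/O curves at +-1 ERB
  off <- cf_offsets_one_erb(500)
  epo <- excitation_pattern(dau_chain, tone, unname(c(off[1], 500, off[2])))
  io <- io_curves(dau_chain, 500, 70)
  expect_equal(epo$output_db, io$output_db, tolerance = 1e-9)
})

test_that("Q estimation recovers an ideal rectangular filter exactly", {
  fs <- 48000
  noise <- make_frozen_noise(3, 40, seed = 5, fs = fs)
  cfs <- c(500, 2000); qs <- c(5, 8)
  # brick-wall oracle: band-limit the noise in the frequency domain
  response <- vapply(seq_along(cfs), function(k) {
    X <- fft(noise$samples)
    f <- (0:(length(X) - 1)) * fs / length(X)
    f <- pmin(f, fs - f)
    bw <- cfs[k] / qs[k]
    keep <- f >= cfs[k] - bw / 2 & f <= cfs[k] + bw / 2
    Re(fft(X * keep, inverse = TRUE)) / length(X)
  }, numeric(length(noise$samples)))
  qe <- estimate_q3db(dau_chain, cfs, noise, response = response)
  expect_false(any(qe$flagged))
  expect_equal(qe$q, qs, tolerance = 0.05)
})

test_that("measured gammatone tuning is level-independent and ERB_N-like", {
  cfs <- greenwood_cf(seq(372, 48, by = -36))  # 10 CFs across the range
  n40 <- make_frozen_noise(3, 40, seed = 1)
  n100 <- make_frozen_noise(3, 100, seed = 1)
  q40 <- estimate_q3db(dau_chain, cfs, n40)
  q100 <- estimate_q3db(dau_chain, cfs, n100)
  expect_equal(q40$q, q100$q, tolerance = 1e-9)  # linear chain
  # measured -3 dB bandwidth close to the 4th-order gammatone's analytic
  # 0.886 * ERB_N (so Q_-3dB sits ~13% above the ERB-based Q)
  mid <- q40$cf >= 500 & q40$cf <= 4000
  expect_equal(q40$bw_3db[mid] / erb_n(q40$cf[mid]),
               rep(0.886, sum(mid)), tolerance = 0.05)
})

test_that("filter counting matches the geometric covering closed form", {
  # constant-Q toy bank: greedy -3 dB covering has the closed-form ratio
  # (2Q+1)/(2Q-1); oracle by direct enumeration
  q0 <- 5
  qe <- structure(tibble::tibble(cf = c(100, 1000, 10000),
                                 bw_3db = c(100, 1000, 10000) / q0,
                                 q = q0, level_db = 40, flagged = FALSE),
                  class = c("q_estimates", "tbl_df", "tbl", "data.frame"))
  fcn <- count_filters(qe, 126, 8000)
  oracle_cf <- 126 / (1 - 1 / (2 * q0))
  oracle_n <- 1L
  repeat {
    if (oracle_cf * (1 + 1 / (2 * q0)) >= 8000) break
    oracle_cf <- oracle_cf * (2 * q0 + 1) / (2 * q0 - 1)
    oracle_n <- oracle_n + 1L
  }
  expect_identical(fcn$count, oracle_n)
  expect_equal(tidy(fcn)$f_lo[1], 126, tolerance = 1e-6)
  # edges abut: lower edge of each filter equals upper edge of the previous
  flt <- tidy(fcn)
  expect_equal(flt$f_lo[-1], flt$f_hi[-nrow(flt)], tolerance = 1e-6)
})

test_that("rate-level curves keep onset above steady state for all chains", {
  for (cfg in list(dau_chain, osses_chain, king_chain)) {
    rl <- rate_level_curves(cfg, 4000, seq(0, 100, 25))
    expect_true(all(rl$onset >= rl$steady - 1e-9))
  }
  # king2019 has no saturation: steady output strictly increasing
  rlk <- rate_level_curves(king_chain, 4000, seq(10, 100, 10))
  expect_true(all(diff(rlk$steady) > 0))
  expect_true(all(diff(rlk$onset) > 0))
})

test_that("off-CF channels fluctuate more than on-CF (synchrony capture)", {
  for (cfg in list(dau_chain, osses_chain)) {
    sy <- synchrony_fluctuation(cfg)
    expect_gt(mean(sy$metric[sy$role == "off"]),
              mean(sy$metric[sy$role == "on"]))
  }
  sy_k <- synchrony_fluctuation(king_chain, scale = 2e-3)
  expect_gt(mean(sy_k$metric[sy_k$role == "off"]),
            mean(sy_k$metric[sy_k$role == "on"]))
  # a perfectly flat response has zero metric
  flat <- new_stimulus(rep(1e-3, 48000 * 0.3), 48000, 50, 0, "flat")
  expect_warning(
    sy0 <- synchrony_fluctuation(king_chain, flat, cfs = 500, scale = 1),
    "fewer than two|qualifying")
})

test_that("MTFs are normalised, bandpass and tidy-able", {
  mtf <- mtf_experiment(dau_chain, 1000, 30)
  expect_equal(max(mtf$data$gain), 1)
  g <- glance(mtf)
  expect_true(g$bandpass)
  expect_s3_class(tidy(mtf), "tbl_df")
  expect_equal(nrow(tidy(mtf)), 25)
})

test_that("click responses of modulation-filterbank chains are nonnegative", {
  cl <- click_abr_response(dau_chain)
  expect_gte(min(cl$waveform$response), 0)
  expect_gt(cl$p2p_neg, cl$p2p_pos)
  expect_gte(glance(cl)$p2p_pos, 0)
})

test_that("autoplot methods return ggplot objects", {
  mtf <- mtf_experiment(dau_chain, 1000, 30, fmods = c(20, 70, 120))
  expect_s3_class(ggplot2::autoplot(mtf), "ggplot")
  io <- io_curves(dau_chain, 1000, c(40, 70))
  expect_s3_class(ggplot2::autoplot(io), "ggplot")
  rl <- rate_level_curves(dau_chain, 4000, c(30, 60, 90))
  expect_s3_class(ggplot2::autoplot(rl), "ggplot")
  cl <- click_abr_response(dau_chain)
  expect_s3_class(ggplot2::autoplot(cl), "ggplot")
})
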