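test_that("IHC cascade cutoffs match the closed form and printed values", {
  # closed-form oracle for N identical first-order sections:
  # f_total = fc * sqrt(2^(1/N) - 1)
  cases <- list(c(7, 3000), c(5, 2000), c(2, 1000), c(1, 1000))
  for (cs in cases) {
    spec <- lp_cascade_spec(cs[1], 1, cs[2])
    oracle <- cs[2] * sqrt(2^(1 / cs[1]) - 1)
    expect_equal(lp_cascade_cutoff(spec), oracle, tolerance = 0.005)
  }
  # a second-order Butterworth section keeps its -3 dB point at fc
  expect_equal(lp_cascade_cutoff(ihc_preset("relanoiborra2019")), 1000,
               tolerance = 0.002)
  # a repeated-pole "order 2" section lands near the printed 642 Hz
  expect_equal(lp_cascade_cutoff(ihc_preset("verhulst2015")), 642,
               tolerance = 0.01)
  expect_error(lp_cascade_cutoff(lp_cascade_spec(1, 1, 60000), fs = 48000),
               "Nyquist")
})

test_that("IHC envelope extraction rectifies, smooths and keeps DC", {
  fs <- 48000
  spec <- ihc_preset("dau1997")
  # constant positive input converges to itself (unity DC gain)
  y <- ihc_hwr_lp(rep(2, fs / 2), spec, fs)
  expect_equal(tail(y, 1), 2, tolerance = 1e-4)
  # negative half-cycles removed: pure negative input gives ~0
  yn <- ihc_hwr_lp(rep(-1, 1000), spec, fs)
  expect_equal(max(abs(yn)), 0)
  # 150-Hz carrier keeps cycle-by-cycle structure, 4013-Hz is mostly DC
  t <- seq(0, 0.1 - 1 / fs, 1 / fs)
  lowf <- ihc_hwr_lp(sin(2 * pi * 150 * t), spec, fs)
  highf <- ihc_hwr_lp(sin(2 * pi * 4013 * t), spec, fs)
  idx <- seq(0.05 * fs, 0.1 * fs - 1)
  depth <- function(y) (max(y[idx]) - min(y[idx])) / mean(y[idx])
  expect_gt(depth(lowf), 1.5)
  expect_lt(depth(highf), 1)
})

test_that("AC/DC metrics follow their defining formulas", {
  fs <- 48000
  # ideal half-wave-rectified sinusoid without lowpass: v_ac = A,
  # v_dc = A/2, ratio = 2 (closed form, v_rest = 0)
  t <- seq(0, 0.1 - 1 / fs, 1 / fs)
  hwr <- pmax(sin(2 * pi * 100 * t), 0) * 3
  m <- ac_dc_metrics(hwr, fs, c(0.02, 0.09))
  expect_equal(m$v_ac, 3, tolerance = 1e-4)
  expect_equal(m$v_dc, 1.5, tolerance = 1e-4)
  expect_equal(m$ratio, 2, tolerance = 1e-4)
  # ratio undefined (NA), not an error, for zero-DC input
  m0 <- ac_dc_metrics(sin(2 * pi * 100 * t), fs, c(0.02, 0.09))
  expect_true(is.na(m0$ratio))
  # linear-scaling invariance: HWR + LP are homogeneous of degree 1
  tone <- make_pure_tone(2000, 0.1, 60, fs = fs)
  y1 <- run_chain(tone, dau_chain, tap = "ihc", cfs = 2000)
  tone2 <- make_pure_tone(2000, 0.1, 80, fs = fs)
  y2 <- run_chain(tone2, dau_chain, tap = "ihc", cfs = 2000)
  r1 <- ac_dc_metrics(y1[, 1], fs, c(0.03, 0.095))$ratio
  r2 <- ac_dc_metrics(y2[, 1], fs, c(0.03, 0.095))$ratio
  expect_equal(r1, r2, tolerance = 1e-6)
})

test_that("adaptation loops compress steady levels and limit onsets", {
  fs <- 48000
  spec <- adaptation_loops_spec(overshoot_limit = 10)
  # silence maps to exactly 0 MU
  expect_equal(adaptation_loops(numeric(fs / 4), spec, fs), numeric(fs / 4))
  expect_error(adaptation_loops(c(-1, 1), spec, fs), "nonnegative")
  expect_error(adaptation_loops_spec(time_constants = c(0.5, 0.1)),
               "increasing")
  expect_error(adaptation_loops_spec(overshoot_limit = 1), "exceed")
  # steady-state output is close to linear in input dB over 20-80 dB SPL
  levels <- seq(20, 80, 10)
  steady <- vapply(levels, function(lv) {
    x <- rep(spl_to_pa(lv) * 0.5, fs)   # stationary drive, 0.5 convention
    mean(adaptation_loops(x, spec, fs)[seq(0.9 * fs, fs)])
  }, numeric(1))
  expect_true(all(diff(steady) > 0))
  fit <- lm(steady ~ levels)
  expect_lt(max(abs(residuals(fit))) / diff(range(steady)), 0.1)
})

test_that("onset responses saturate at a level-independent ceiling", {
  rl <- rate_level_curves(dau_chain, 4000, seq(40, 100, 10))
  on_hi <- rl$onset[rl$level_db >= 60]
  # dau1997-style ceiling close to 1443 MU and flat above 50 dB
  expect_equal(mean(on_hi), 1443, tolerance = 0.1)
  expect_lt(diff(range(on_hi)) / mean(on_hi), 0.01)
})

test_that("highpass adaptation removes DC and has its cutoff at 3 Hz", {
  fs <- 48000
  y <- highpass_adaptation(rep(1, 3 * fs), fc = 3, fs = fs)
  expect_lt(abs(tail(y, 1)), 0.02)          # DC fully rejected
  expect_gt(y[1], 0.9)                      # positive onset transient
  expect_true(all(diff(y[-1]) <= 1e-12))    # undershoot-free decay
  # -3 dB point of the digital filter at 3 Hz within 2%
  bt <- signal::butter(1, 3 / (fs / 2), type = "high")
  f <- seq(2.5, 3.5, 0.001)
  H <- Mod(polyval_z(bt$b, f, fs) / polyval_z(bt$a, f, fs))
  f3 <- f[which.min(abs(H - 1 / sqrt(2)))]
  expect_equal(f3, 3, tolerance = 0.02)
})

test_that("all chains show the stereotypical adaptation time course", {
  fs <- 48000
  for (cfg in list(dau_chain, osses_chain, king_chain)) {
    tr <- adaptation_trace(cfg, 4000, 70)
    r <- tr$response
    onset <- max(r[seq(floor(0.05 * fs), floor(0.15 * fs))])
    plateau <- mean(r[seq(floor(0.30 * fs), floor(0.34 * fs))])
    undershoot <- min(r[seq(floor(0.355 * fs), floor(0.42 * fs))])
    late <- mean(r[seq(floor(0.57 * fs), length(r))])
    expect_gt(onset, plateau)          # onset overshoot, decay to plateau
    expect_lt(undershoot, 0)           # post-offset undershoot
    expect_lt(abs(late), abs(undershoot))  # recovery back toward rest
  }
})
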