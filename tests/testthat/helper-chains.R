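# shared fixtures: chain presets and a frozen noise, built once per file
dau_chain <- chain_preset("dau1997")
osses_chain <- chain_preset("osses2021")
king_chain <- chain_preset("king2019")

# steady-state rms level (dB SPL) of a waveform segment
seg_level <- function(x, fs, from, to) {
  idx <- seq(floor(from * fs) + 1L, floor(to * fs))
  pa_to_spl(sqrt(mean(x[idx]^2)))
}

# evaluate a digital polynomial in z^-1 at frequencies f (Hz)
polyval_z <- function(coefs, f, fs) {
  z <- exp(-2i * pi * f / fs)
  sapply(seq_along(f), function(i) sum(coefs * z[i]^(seq_along(coefs) - 1)))
}

# simulation-derived SFIE best modulation frequency: drive the unrectified
# cascade with raised sinusoids and locate the modulation rate giving the
# largest steady-state fluctuation (independent time-domain oracle for the
# analytic transfer-function BMF)
sim_sfie_bmf <- function(cn, ic, fmods = seq(70, 100, 1), fs = 16000) {
  dur <- 0.4
  t <- seq(0, dur - 1 / fs, 1 / fs)
  resp <- vapply(fmods, function(fm) {
    x <- 1 + sin(2 * pi * fm * t)
    y <- sfie_stage(x, cn, ic, fs, rectify = FALSE)
    w <- y[seq(floor(0.25 * fs), length(y))]
    max(w) - min(w)
  }, numeric(1))
  fmods[which.max(resp)]
}
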