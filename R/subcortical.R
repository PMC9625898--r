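#' Modulation filterbank specification
#'
#' Two constructions are supported.  `style = "dau"` places resonators with
#' constant quality factor `q` so that adjacent filters meet at their -3 dB
#' points, which fixes the adjacent centre-frequency ratio at
#' `(2q + 1) / (2q - 1)` (5/3 for `q = 2`), starting from
#' `f_first_resonator`.  `style = "king"` uses wider tuning (`q = 1`) with
#' geometrically spaced, 50%-overlapped filters up to `max_bmf`
#' (adjacent spacing equal to half the filter bandwidth, i.e. ratio
#' `1 + 1/(2q)`).  Optional features: `lp150` inserts a first-order 150-Hz
#' lowpass before the bank, and `cf_quarter_rule` drops filters whose best
#' modulation frequency (BMF) is not below a quarter of the audio-channel
#' CF.
#'
#' @param style `"dau"` or `"king"`
#' @param q resonator quality factor
#' @param f_first_resonator lowest resonator BMF (Hz, dau style)
#' @param max_bmf highest BMF retained (Hz)
#' @param lp150 apply the 150-Hz lowpass in front of the bank?
#' @param cf_quarter_rule limit BMFs to below CF/4?
#' @param n_filters number of filters (king style)
#' @return a list of class `mod_filterbank_spec`
#' @export
mod_filterbank_spec <- function(style = c("dau", "king"), q = 2,
                                f_first_resonator = 10, max_bmf = 1000,
                                lp150 = FALSE, cf_quarter_rule = FALSE,
                                n_filters = 10L) {
  style <- match.arg(style)
  if (q <= 0) abort("q must be positive")
  structure(list(style = style, q = q,
                 f_first_resonator = f_first_resonator, max_bmf = max_bmf,
                 lp150 = lp150, cf_quarter_rule = cf_quarter_rule,
                 n_filters = as.integer(n_filters)),
            class = "mod_filterbank_spec")
}

#' Build the modulation filterbank descriptors
#'
#' @param spec a [mod_filterbank_spec()]
#' @param cf audio-channel CF (Hz), needed when `cf_quarter_rule` is set
#' @return a tibble with columns `bmf` (Hz) and `bw_3db` (Hz)
#' @export
build_modulation_filterbank <- function(spec = mod_filterbank_spec(),
                                        cf = NULL) {
  if (spec$style == "dau") {
    ratio <- (2 * spec$q + 1) / (2 * spec$q - 1)
    bmf <- spec$f_first_resonator
    centers <- c()
    while (bmf <= spec$max_bmf + 1e-9) {
      centers <- c(centers, bmf)
      bmf <- bmf * ratio
    }
  } else {
    ratio <- 1 + 1 / (2 * spec$q)
    centers <- spec$max_bmf / ratio^((spec$n_filters - 1):0)
  }
  if (spec$cf_quarter_rule) {
    if (is.null(cf)) abort("cf is required when cf_quarter_rule is set")
    centers <- centers[centers < cf / 4]
  }
  if (!length(centers))
    abort("modulation filterbank is empty after applying the CF/4 rule")
  tibble(bmf = centers, bw_3db = centers / spec$q)
}

#' Modulation filter with a given best modulation frequency nearest a target
#'
#' @param spec a [mod_filterbank_spec()]
#' @param target target BMF (Hz)
#' @param cf audio-channel CF (Hz) for the CF/4 rule
#' @return one-row tibble (the bank filter whose BMF is closest to `target`)
#' @export
modulation_filter_near <- function(spec = mod_filterbank_spec(),
                                   target = 80, cf = NULL) {
  bank <- build_modulation_filterbank(spec, cf)
  bank[which.min(abs(bank$bmf - target)), ]
}

#' Apply one modulation filter to a (demodulated) drive signal
#'
#' The resonator is realised as a second-order complex filter (two cascaded
#' identical complex one-pole sections) centred at the BMF with overall
#' -3 dB bandwidth `bmf / q`.  For BMFs at or above 10 Hz the output is the
#' phase-insensitive envelope magnitude ("venelope", nonnegative
#' everywhere); below 10 Hz the signed real output is returned.
#'
#' @param x numeric vector or samples-by-channels matrix
#' @param bmf filter centre (best modulation) frequency (Hz)
#' @param q quality factor
#' @param fs sampling rate (Hz)
#' @param sections number of cascaded complex one-pole sections
#' @return object of the same shape
#' @export
apply_modulation_filter <- function(x, bmf, q = 2, fs, sections = 2L) {
  half_bw <- bmf / (2 * q)
  gamma <- half_bw / sqrt(2^(1 / sections) - 1)
  a <- exp(complex(real = -2 * pi * gamma / fs, imaginary = 2 * pi * bmf / fs))
  h_bmf <- (1 / (1 - a * exp(-2i * pi * bmf / fs)))^sections
  g <- 2 / Mod(h_bmf)
  run1 <- function(col) {
    y <- cpp_complex_cascade(col, Re(a), Im(a), sections)
    if (bmf >= 10) g * Mod(y) else g * Re(y)
  }
  if (is.matrix(x)) {
    at <- attributes(x)
    y <- apply(x, 2, run1)
    attributes(y) <- at
    y
  } else run1(x)
}

## first-order lowpass at 150 Hz used in front of some modulation banks
lp150_filter <- function(x, fs) {
  sp <- lp_cascade_spec(1, 1, 150)
  if (is.matrix(x)) {
    at <- attributes(x)
    y <- apply(x, 2, lp_cascade_apply, spec = sp, fs = fs)
    attributes(y) <- at
    y
  } else lp_cascade_apply(x, sp, fs)
}

#' SFIE stage parameters
#'
#' Excitation/inhibition time constants, inhibition delay and inhibition
#' strength of one same-frequency inhibition-excitation (SFIE) stage.
#'
#' @param tau_exc excitatory alpha-kernel time constant (s)
#' @param tau_inh inhibitory alpha-kernel time constant (s)
#' @param delay inhibition delay (s)
#' @param strength inhibition strength S (dimensionless)
#' @return a list of class `sfie_params`
#' @export
sfie_params <- function(tau_exc = 0.5e-3, tau_inh = 2e-3, delay = 1e-3,
                        strength = 0.6) {
  if (any(c(tau_exc, tau_inh, delay, strength) <= 0))
    abort("all SFIE parameters must be positive")
  structure(list(tau_exc = tau_exc, tau_inh = tau_inh, delay = delay,
                 strength = strength),
            class = "sfie_params")
}

#' CN/IC SFIE parameter presets
#'
#' `"verhulst"`: CN 0.5/2 ms, D = 1 ms, S = 0.6; IC 0.5/2 ms, D = 2 ms,
#' S = 1.5 (inhibition-dominated IC).  `"carney"`: same CN; IC 1.11/1.67 ms,
#' D = 1.1 ms, S = 0.9 (excitation-dominated IC).
#'
#' @param which `"verhulst"` or `"carney"`
#' @return `list(cn = , ic = )` of [sfie_params()]
#' @export
sfie_preset <- function(which = c("verhulst", "carney")) {
  which <- match.arg(which)
  cn <- sfie_params(0.5e-3, 2e-3, 1e-3, 0.6)
  ic <- switch(which,
               verhulst = sfie_params(0.5e-3, 2e-3, 2e-3, 1.5),
               carney   = sfie_params(1.11e-3, 1.67e-3, 1.1e-3, 0.9))
  list(cn = cn, ic = ic)
}

## convolve with a unit-area alpha kernel t*exp(-t/tau) (FFT overlap-free)
alpha_conv <- function(x, tau, fs) {
  L <- ceiling(12 * tau * fs)
  t <- (0:(L - 1)) / fs
  h <- t * exp(-t / tau)
  h <- h / sum(h)
  n <- length(x)
  nfft <- 2^ceiling(log2(n + L - 1))
  y <- Re(fft(fft(c(x, numeric(nfft - n))) * fft(c(h, numeric(nfft - L))),
              inverse = TRUE)) / nfft
  y[seq_len(n)]
}

sfie_one_stage <- function(x, p, fs, rectify) {
  exc <- alpha_conv(x, p$tau_exc, fs)
  inh <- alpha_conv(x, p$tau_inh, fs)
  d <- round(p$delay * fs)
  inh <- c(numeric(d), inh[seq_len(length(inh) - d)])
  y <- exc - p$strength * inh
  if (rectify) pmax(y, 0) else y
}

#' Same-frequency inhibition-excitation (SFIE) CN + IC cascade
#'
#' Each stage convolves its nonnegative drive with unit-area alpha kernels
#' (`t * exp(-t/tau) / tau^2`), subtracts the delayed, scaled inhibitory
#' branch from the excitatory branch and (by default) half-wave rectifies
#' the result; the cochlear-nucleus (CN) output feeds the inferior-colliculus
#' (IC) stage.  The cascade acts as a widely tuned modulation filter
#' (Q of roughly 1).
#'
#' @param rate nonnegative drive waveform (vector or samples-by-channels
#'   matrix)
#' @param cn,ic [sfie_params()] for the two stages
#' @param fs sampling rate (Hz)
#' @param rectify half-wave rectify each stage output?
#' @return IC output, same shape as the input
#' @export
sfie_stage <- function(rate, cn = sfie_preset("verhulst")$cn,
                       ic = sfie_preset("verhulst")$ic, fs, rectify = TRUE) {
  if (any(rate < 0)) abort("SFIE input must be nonnegative")
  run1 <- function(col)
    sfie_one_stage(sfie_one_stage(col, cn, fs, rectify), ic, fs, rectify)
  if (is.matrix(rate)) {
    at <- attributes(rate)
    y <- apply(rate, 2, run1)
    attributes(y) <- at
    y
  } else run1(rate)
}

#' Analytic best modulation frequency of the SFIE cascade
#'
#' The modulation transfer magnitude of the linearised (unrectified)
#' cascade is `|H_CN(f) * H_IC(f)|` with
#' `H(f) = E(f) - S * I(f) * exp(-i 2 pi f D)` and
#' `E, I = 1 / (1 + i 2 pi f tau)^2` (unit-area alpha kernels).  The BMF is
#' located by a grid search over 1-500 Hz at 0.1-Hz resolution.
#'
#' @param cn,ic [sfie_params()] for the two stages
#' @return the best modulation frequency (Hz)
#' @export
sfie_bmf <- function(cn = sfie_preset("verhulst")$cn,
                     ic = sfie_preset("verhulst")$ic) {
  f <- seq(1, 500, by = 0.1)
  mag <- Mod(sfie_transfer(f, cn) * sfie_transfer(f, ic))
  f[which.max(mag)]
}

#' Analytic transfer function of one SFIE stage
#' @param f modulation frequency (Hz), vectorised
#' @param p an [sfie_params()]
#' @return complex transfer values
#' @export
sfie_transfer <- function(f, p) {
  e <- 1 / (1 + 2i * pi * f * p$tau_exc)^2
  i <- 1 / (1 + 2i * pi * f * p$tau_inh)^2
  e - p$strength * i * exp(-2i * pi * f * p$delay)
}
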