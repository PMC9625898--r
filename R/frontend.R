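#' Middle-ear filter specification
#'
#' A minimum-phase Butterworth bandpass (second order per skirt) matched to
#' the published -3 dB cutoffs and passband gain of the middle-ear stage.
#' Only the cutoffs and the mid-band gain are contractual; the detailed
#' magnitude response between them is an approximation.
#'
#' @param passband_gain mid-band gain (dB)
#' @param f_lo,f_hi lower/upper -3 dB frequencies (Hz)
#' @param enabled disabled specs act as identity
#' @return a list of class `middle_ear_spec`
#' @export
middle_ear_spec <- function(passband_gain = 0, f_lo = 474.8, f_hi = 1230.2,
                            enabled = TRUE) {
  if (f_lo >= f_hi) abort("f_lo must be below f_hi")
  structure(list(passband_gain = passband_gain, f_lo = f_lo, f_hi = f_hi,
                 enabled = enabled),
            class = "middle_ear_spec")
}

#' Apply the middle-ear bandpass to a stimulus
#'
#' @param stim a [new_stimulus()] object
#' @param spec a [middle_ear_spec()]
#' @return the filtered stimulus
#' @export
middle_ear_filter <- function(stim, spec = middle_ear_spec()) {
  if (!spec$enabled) return(stim)
  if (spec$f_hi >= stim$fs / 2) abort("f_hi must lie below Nyquist")
  bt <- signal::butter(2, c(spec$f_lo, spec$f_hi) / (stim$fs / 2), type = "pass")
  g <- 10^(spec$passband_gain / 20)
  stim$samples <- g * cpp_iir(bt$b, bt$a, stim$samples)
  stim$label <- paste(stim$label, "+ middle ear")
  stim
}

## per-section decay (Hz) giving a 4th-order all-pole gammatone an
## equivalent rectangular bandwidth of exactly `erb` Hz:
## ERB = gamma * pi * (2n-3)!! / (2n-2)!!  ->  gamma = erb / 0.98175 (n = 4)
gammatone_bw_factor <- function(order = 4) {
  num <- prod(seq(2 * order - 3, 1, by = -2))
  den <- prod(seq(2 * order - 2, 2, by = -2))
  1 / (pi * num / den)
}

## complex pole and normalising gain of one gammatone channel
gammatone_coefs <- function(cf, fs, order = 4) {
  b_hz <- gammatone_bw_factor(order) * erb_n(cf)
  a <- exp(complex(real = -2 * pi * b_hz / fs,
                   imaginary = 2 * pi * cf / fs))
  h_cf <- (1 / (1 - a * exp(-2i * pi * cf / fs)))^order
  list(a = a, gain = 2 / Mod(h_cf))
}

#' Linear gammatone filterbank
#'
#' All-pole gammatone filters realised as a cascade of `order` identical
#' complex one-pole resonators; the real part of the cascade output is
#' taken and each channel is normalised to 0 dB gain at its CF.  Bandwidths
#' follow the Glasberg-Moore `ERB_N` (broad) tuning; the filter is linear
#' and time-invariant, so its tuning is level-independent.
#'
#' @param stim a [new_stimulus()] object (or a bare numeric vector)
#' @param cfs channel centre frequencies (Hz), all below Nyquist
#' @param fs sampling rate (Hz); defaults to `stim$fs`
#' @param order filter order (default 4)
#' @return a samples-by-channels numeric matrix with attributes `cfs` and
#'   `fs`
#' @export
gammatone_filterbank <- function(stim, cfs, fs = NULL, order = 4) {
  x <- if (inherits(stim, "stimulus")) stim$samples else stim
  fs <- fs %||% if (inherits(stim, "stimulus")) stim$fs else
    abort("fs is required for bare numeric input")
  if (any(cfs >= fs / 2)) abort("all cfs must lie below Nyquist")
  out <- matrix(0, nrow = length(x), ncol = length(cfs))
  for (k in seq_along(cfs)) {
    co <- gammatone_coefs(cfs[k], fs, order)
    y <- cpp_complex_cascade(x, Re(co$a), Im(co$a), order)
    out[, k] <- co$gain * Re(y)
  }
  attr(out, "cfs") <- cfs
  attr(out, "fs") <- fs
  out
}

## group delay (s) of the gammatone at its CF: order / (2*pi*b)
gammatone_group_delay <- function(cf, fs, order = 4) {
  b_hz <- gammatone_bw_factor(order) * erb_n(cf)
  order / (2 * pi * b_hz)
}

## advance each channel by its gammatone group delay (zero-padded at the
## end); an approximate across-channel alignment used by the osses2021-style
## chain
compensate_group_delay <- function(x, order = 4) {
  cfs <- attr(x, "cfs"); fs <- attr(x, "fs")
  for (k in seq_along(cfs)) {
    d <- round(gammatone_group_delay(cfs[k], fs, order) * fs)
    if (d > 0 && d < nrow(x))
      x[, k] <- c(x[-seq_len(d), k], rep(0, d))
  }
  x
}

#' Broken-stick compression specification
#'
#' Instantaneous, sign-preserving piecewise power law: identity below the
#' knee amplitude, `|y| = knee^(1-exponent) * |x|^exponent` above it
#' (continuous at the knee).  The knee is an instantaneous-amplitude
#' threshold equal to the peak amplitude of a `knee_db` dB SPL sinusoid
#' after the 0.5 input-scaling convention of the chains that use it.
#'
#' @param knee_db knee point (dB SPL-equivalent)
#' @param exponent compression exponent in (0, 1]
#' @param convention_factor input-scaling factor entering the knee amplitude
#' @return a list of class `broken_stick_spec`
#' @export
broken_stick_spec <- function(knee_db = 30, exponent = 0.3,
                              convention_factor = 0.5) {
  if (exponent <= 0 || exponent > 1) abort("exponent must lie in (0, 1]")
  knee_amp <- spl_to_pa(knee_db) * sqrt(2) * convention_factor
  structure(list(knee_db = knee_db, exponent = exponent,
                 knee_amp = knee_amp),
            class = "broken_stick_spec")
}

#' Apply broken-stick compression to a waveform matrix
#'
#' @param x numeric vector or samples-by-channels matrix
#' @param spec a [broken_stick_spec()]
#' @return object of the same shape
#' @export
broken_stick_compress <- function(x, spec = broken_stick_spec()) {
  k <- spec$knee_amp; e <- spec$exponent
  ax <- abs(x)
  above <- ax > k
  y <- x
  y[above] <- sign(x[above]) * k^(1 - e) * ax[above]^e
  y
}
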