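#' Adaptation-loops specification
#'
#' Five cascaded divisive feedback loops compress stationary inputs almost
#' logarithmically while transmitting fast fluctuations nearly linearly.
#' Each loop divides its input by a lowpass-filtered copy of its own
#' output; onset overshoots are limited by a smooth (sigmoidal) limiter
#' expressed as a multiple of the steady-state response.  The output is
#' mapped affinely to model units (MU) so that silence maps to 0 MU and a
#' stationary full-scale input (amplitude 1, i.e. a 100-dB signal under the
#' 0.5 input convention) maps to 100 MU.
#'
#' @param time_constants loop time constants (s), strictly increasing
#' @param overshoot_limit onset overshoot limit as a factor of the
#'   steady-state response (> 1 to engage; 10 for dau1997-style chains,
#'   5 for osses2021-style chains)
#' @param min_input input floor: the pressure-equivalent amplitude of a
#'   0-dB-SPL signal under the 0.5 input convention
#' @return a list of class `adaptation_loops_spec`; fields `mu_offset` and
#'   `mu_gain` hold the affine model-unit map
#' @export
adaptation_loops_spec <- function(time_constants = c(0.005, 0.050, 0.129,
                                                     0.253, 0.500),
                                  overshoot_limit = 10,
                                  min_input = 1e-5) {
  if (is.unsorted(time_constants, strictly = TRUE))
    abort("time_constants must be strictly increasing")
  if (overshoot_limit <= 1) abort("overshoot_limit must exceed 1")
  nloops <- length(time_constants)
  state0 <- min_input^(1 / 2^seq_len(nloops))
  corr <- state0[nloops]
  structure(list(time_constants = time_constants,
                 overshoot_limit = overshoot_limit,
                 min_input = min_input,
                 state0 = state0,
                 mu_offset = corr,
                 mu_gain = 100 / (1 - corr)),
            class = "adaptation_loops_spec")
}

#' Run the adaptation loops
#'
#' @param x nonnegative numeric vector or samples-by-channels matrix
#'   (post-IHC envelope)
#' @param spec an [adaptation_loops_spec()]
#' @param fs sampling rate (Hz)
#' @return object of the same shape, in model units (MU); silence maps to
#'   0 MU
#' @export
adaptation_loops <- function(x, spec = adaptation_loops_spec(), fs) {
  if (any(x < 0)) abort("adaptation loops require nonnegative input (run the IHC stage first)")
  a1 <- exp(-1 / (spec$time_constants * fs))
  run1 <- function(col) {
    y <- cpp_adaptation_loops(col, a1, spec$state0, spec$overshoot_limit,
                              spec$min_input)
    (y - spec$mu_offset) * spec$mu_gain
  }
  if (is.matrix(x)) {
    at <- attributes(x)
    y <- apply(x, 2, run1)
    attributes(y) <- at
    y
  } else run1(x)
}

#' First-order highpass adaptation
#'
#' The king2019-style alternative to the adaptation loops: a first-order
#' highpass (cutoff 3 Hz by default) that removes the DC component of the
#' IHC envelope in steady state.
#'
#' @param x numeric vector or samples-by-channels matrix
#' @param fc -3 dB cutoff (Hz)
#' @param fs sampling rate (Hz)
#' @return object of the same shape
#' @export
highpass_adaptation <- function(x, fc = 3, fs) {
  if (fc >= fs / 2) abort("fc must lie below Nyquist")
  bt <- signal::butter(1, fc / (fs / 2), type = "high")
  if (is.matrix(x)) {
    at <- attributes(x)
    y <- apply(x, 2, function(col) cpp_iir(bt$b, bt$a, col))
    attributes(y) <- at
    y
  } else cpp_iir(bt$b, bt$a, x)
}
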