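#' Human base-to-apex cochlear map parameters
#'
#' Parameters of the exponential frequency-position map used to convert a
#' cochlear section index into a characteristic frequency (CF).  The
#' defaults describe a 401-section human cochlea spanning 12010 Hz (base,
#' section 1) to 113 Hz (apex, section 401).
#'
#' @param A0 scale frequency (Hz)
#' @param a decay constant (1/m)
#' @param k dimensionless offset factor
#' @param A offset frequency (Hz)
#' @param dx section spacing (mm)
#' @param x1 distance of the first section from the base (mm)
#' @param n_sections number of sections
#' @return a list of map parameters, class `cochlear_map_params`
#' @export
cochlear_map_params <- function(A0 = 20682, a = 61.765, k = 0.85,
                                A = 165.4188, dx = 0.068, x1 = 3.74,
                                n_sections = 401L) {
  structure(list(A0 = A0, a = a, k = k, A = A, dx = dx, x1 = x1,
                 n_sections = as.integer(n_sections)),
            class = "cochlear_map_params")
}

#' Characteristic frequency of a cochlear section
#'
#' `CF_n = A0 * 10^(-a * x_n / 1000) - A * k` with `x_n = x1 + dx*(n-1)` in
#' mm.  CF decreases strictly with the section index (base to apex).
#'
#' @param n section index (vectorised), `1 <= n <= n_sections`
#' @param params a [cochlear_map_params()] list
#' @return CF in Hz (full precision; round only for display)
#' @examples
#' round(greenwood_cf(c(1, 112, 305, 401)))  # 12010 4013 502 113
#' @export
greenwood_cf <- function(n, params = cochlear_map_params()) {
  if (any(n < 1 | n > params$n_sections)) abort("section index out of range")
  x <- params$x1 + params$dx * (n - 1)
  params$A0 * 10^(-params$a * x / 1000) - params$A * params$k
}

#' Cochlear-section index whose CF is closest to a target frequency
#' @param freq target frequency (Hz), vectorised
#' @param params a [cochlear_map_params()] list
#' @return integer section index
#' @export
greenwood_section <- function(freq, params = cochlear_map_params()) {
  cfs <- greenwood_cf(seq_len(params$n_sections), params)
  vapply(freq, function(f) which.min(abs(cfs - f)), integer(1))
}

#' Q-factor of cochlear tuning
#'
#' Two tuning conventions: `"sharp"` gives `Q = 12.7 * (CF/1000)^0.3`
#' (otoacoustic/behavioural sharp tuning); `"broad"` gives
#' `Q = CF / ERB_N(CF)` with the Glasberg-Moore bandwidth (the tuning of the
#' linear gammatone chains).
#'
#' @param cf characteristic frequency (Hz), vectorised
#' @param flavor `"sharp"` or `"broad"`
#' @return dimensionless Q
#' @export
q_erb <- function(cf, flavor = c("sharp", "broad")) {
  if (any(cf <= 0)) abort("cf must be positive")
  flavor <- match.arg(flavor)
  switch(flavor,
         sharp = 12.7 * (cf / 1000)^0.3,
         broad = cf / erb_n(cf))
}

#' Equivalent rectangular bandwidth of the normal auditory filter
#'
#' `ERB_N = 24.7 * (4.37 * cf/1000 + 1)` Hz.
#'
#' @param cf centre frequency (Hz), vectorised
#' @return bandwidth in Hz
#' @export
erb_n <- function(cf) {
  if (any(cf <= 0)) abort("cf must be positive")
  24.7 * (4.37 * cf / 1000 + 1)
}

#' ERB-number (Cam) scale conversions
#'
#' The ERB-number scale `E(f) = 21.4 * log10(1 + 0.00437 * f)` integrates
#' the reciprocal ERB and is the standard companion of [erb_n()]; it is a
#' bijection on positive frequencies.
#'
#' @param f frequency (Hz)
#' @return ERB number (Cam)
#' @export
hz_to_erbnum <- function(f) 21.4 * log10(1 + 0.00437 * f)

#' @rdname hz_to_erbnum
#' @param e ERB number (Cam)
#' @export
erbnum_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' Frequencies spaced uniformly on the ERB-number scale
#' @param f_lo,f_hi range endpoints (Hz)
#' @param n number of frequencies
#' @return numeric vector of length `n`
#' @export
erbspace <- function(f_lo, f_hi, n) {
  erbnum_to_hz(seq(hz_to_erbnum(f_lo), hz_to_erbnum(f_hi), length.out = n))
}

#' CFs one ERB-number step below and above a centre frequency
#'
#' Offsets are taken on the ERB-number scale (not linear Hz), so the two
#' neighbours are asymmetric in Hz.
#'
#' @param cf centre frequency (Hz)
#' @return named numeric vector `c(below = , above = )`
#' @export
cf_offsets_one_erb <- function(cf) {
  if (cf <= 0) abort("cf must be positive")
  e <- hz_to_erbnum(cf)
  below <- erbnum_to_hz(e - 1)
  if (below <= 0) abort("cf is too low for a one-ERB step below")
  c(below = below, above = erbnum_to_hz(e + 1))
}
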