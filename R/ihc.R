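#' Inner-hair-cell lowpass cascade specification
#'
#' The IHC stage is modelled as half-wave rectification followed by a
#' cascade of lowpass filter sections.  `section_type = "pole"` realises an
#' order-`m` section as `m` cascaded identical first-order poles (each with
#' its -3 dB point at `section_fc`); `"butterworth"` realises it as a
#' maximally-flat section with the -3 dB point of the whole section at
#' `section_fc`.  The two coincide for first-order sections.
#'
#' @param n_sections number of cascaded sections
#' @param section_order order of each section
#' @param section_fc -3 dB cutoff of each section (Hz)
#' @param section_type `"pole"` or `"butterworth"`
#' @return a list of class `lp_cascade_spec`
#' @export
lp_cascade_spec <- function(n_sections = 1L, section_order = 1L,
                            section_fc = 1000,
                            section_type = c("pole", "butterworth")) {
  if (n_sections < 1 || section_fc <= 0) abort("invalid lowpass cascade spec")
  structure(list(n_sections = as.integer(n_sections),
                 section_order = as.integer(section_order),
                 section_fc = section_fc,
                 section_type = match.arg(section_type)),
            class = "lp_cascade_spec")
}

#' IHC lowpass presets of the compared model chains
#'
#' @param model one of `"dau1997"`, `"zilany2014"`, `"bruce2018"`,
#'   `"verhulst2015"`, `"king2019"`, `"relanoiborra2019"`, `"osses2021"`
#' @return an [lp_cascade_spec()]
#' @export
ihc_preset <- function(model) {
  switch(model,
    dau1997          = lp_cascade_spec(1, 1, 1000),
    zilany2014       = lp_cascade_spec(7, 1, 3000),
    bruce2018        = lp_cascade_spec(7, 1, 3000),
    verhulst2015     = lp_cascade_spec(1, 2, 1000, "pole"),
    king2019         = lp_cascade_spec(1, 1, 1000),
    relanoiborra2019 = lp_cascade_spec(1, 2, 1000, "butterworth"),
    osses2021        = lp_cascade_spec(5, 1, 2000),
    abort(sprintf("unknown IHC preset '%s'", model)))
}

## digital (b, a) of ONE first-order pole or butterworth section, unity DC
## gain, -3 dB at fc by bilinear prewarping
lp_section_coefs <- function(spec, fs) {
  if (spec$section_fc >= fs / 2) abort("section_fc must lie below Nyquist")
  if (spec$section_type == "pole" || spec$section_order == 1) {
    wa <- tan(pi * spec$section_fc / fs)
    list(b = c(wa, wa) / (1 + wa), a = c(1, (wa - 1) / (1 + wa)),
         reps = spec$n_sections * spec$section_order)
  } else {
    bt <- signal::butter(spec$section_order, spec$section_fc / (fs / 2))
    list(b = bt$b, a = bt$a, reps = spec$n_sections)
  }
}

## apply the full cascade to one numeric vector
lp_cascade_apply <- function(x, spec, fs) {
  co <- lp_section_coefs(spec, fs)
  for (i in seq_len(co$reps)) x <- cpp_iir(co$b, co$a, x)
  x
}

#' IHC envelope extraction: half-wave rectification + lowpass cascade
#'
#' Negative half-cycles are removed before filtering; the cascade has unity
#' DC gain, so a constant positive input converges to itself.  Low-frequency
#' carriers keep their cycle-by-cycle structure while high-frequency
#' carriers are reduced to a mostly-DC envelope (the loss of phase locking).
#'
#' @param x numeric vector or samples-by-channels matrix
#' @param spec an [lp_cascade_spec()]
#' @param fs sampling rate (Hz)
#' @return object of the same shape
#' @export
ihc_hwr_lp <- function(x, spec = ihc_preset("dau1997"), fs) {
  if (is.matrix(x)) {
    at <- attributes(x)
    y <- apply(x, 2, function(col) lp_cascade_apply(pmax(col, 0), spec, fs))
    attributes(y) <- at
    y
  } else {
    lp_cascade_apply(pmax(x, 0), spec, fs)
  }
}

#' Measured -3 dB cutoff of a digital lowpass cascade
#'
#' Evaluates the amplitude response of the full cascade on a fine frequency
#' grid and interpolates the -3 dB crossing, i.e. the cutoff of the total
#' filter structure rather than of its sections.  For `N` identical
#' first-order sections this agrees with the closed form
#' `fc * sqrt(2^(1/N) - 1)` up to bilinear warping.
#'
#' @param spec an [lp_cascade_spec()]
#' @param fs sampling rate (Hz) at which the digital cascade is realised;
#'   the default is the native rate of the high-rate auditory-nerve
#'   implementations the multi-section cascades describe
#' @param df grid resolution (Hz)
#' @return the -3 dB frequency (Hz)
#' @export
lp_cascade_cutoff <- function(spec, fs = 100000, df = 0.25) {
  co <- lp_section_coefs(spec, fs)
  f <- seq(0, fs / 2 - df, by = df)
  z <- exp(-2i * pi * f / fs)
  h_sec <- outer(z, seq_along(co$b) - 1, `^`) %*% co$b /
    (outer(z, seq_along(co$a) - 1, `^`) %*% co$a)
  mag_db <- 20 * co$reps * log10(Mod(h_sec))
  below <- which(mag_db <= -20 * log10(sqrt(2)))
  if (!length(below)) abort("cascade has no -3 dB point below Nyquist")
  i <- below[1]
  target <- -20 * log10(sqrt(2))
  approx(mag_db[c(i - 1, i)], f[c(i - 1, i)], xout = target)$y
}

#' AC and DC components of an IHC response
#'
#' Over a steady-state analysis window (onset excluded by the caller's
#' window choice), `v_peak_max`/`v_peak_min` are the extreme values of the
#' waveform, and `v_ac = v_peak_max - v_peak_min`,
#' `v_dc = (v_peak_max + v_peak_min)/2 - v_rest`.  Their ratio is a proxy
#' for phase locking to temporal fine structure; it is reported as `NA`
#' (undefined) when `v_dc <= 0`.
#'
#' @param waveform single-channel response (numeric vector)
#' @param fs sampling rate (Hz)
#' @param window `c(from, to)` analysis window (s)
#' @param v_rest resting value of the response
#' @return a one-row tibble with columns `v_peak_max`, `v_peak_min`,
#'   `v_rest`, `v_ac`, `v_dc`, `ratio`
#' @export
ac_dc_metrics <- function(waveform, fs, window, v_rest = 0) {
  idx <- seq(max(1L, floor(window[1] * fs) + 1L),
             min(length(waveform), ceiling(window[2] * fs)))
  if (!length(idx)) abort("analysis window lies outside the waveform")
  w <- waveform[idx]
  v_max <- max(w); v_min <- min(w)
  v_ac <- v_max - v_min
  v_dc <- (v_max + v_min) / 2 - v_rest
  tibble(v_peak_max = v_max, v_peak_min = v_min, v_rest = v_rest,
         v_ac = v_ac, v_dc = v_dc,
         ratio = if (v_dc > 0) v_ac / v_dc else NA_real_)
}
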