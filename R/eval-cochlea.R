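## steady-state analysis window of a ramped tone: final 50% of the tone,
## offset ramp excluded
steady_window <- function(dur, ramp_dur) c(dur / 2, dur - ramp_dur)

rms_db_window <- function(y, fs, window) {
  idx <- seq(max(1L, floor(window[1] * fs) + 1L),
             min(length(y), floor(window[2] * fs)))
  pa_to_spl(sqrt(mean(y[idx]^2)))
}

#' Cochlear input-output curves at and around a probe frequency
#'
#' For each stimulus level, a 100-ms pure tone is processed to the cochlear
#' tap and the steady-state rms output level is measured at the on-frequency
#' CF and at the CFs one ERB-number step below and above it.  Output levels
#' are shifted by the chain reference gain ([chain_reference_gain()]).
#' Linear chains give slope 1 dB/dB everywhere; a broken-stick chain gives
#' a local slope near its compression exponent above the knee on-CF.
#'
#' @param cfg a [chain_config()]
#' @param freq probe frequency (Hz)
#' @param levels stimulus levels (dB SPL)
#' @param dur tone duration (s)
#' @param ramp_dur ramp duration (s)
#' @return a tibble of class `io_curves` with columns `offset`
#'   (`"-1 ERB"`, `"on"`, `"+1 ERB"`), `cf`, `level_db`, `output_db`
#' @export
io_curves <- function(cfg, freq, levels = seq(0, 100, 10), dur = 0.1,
                      ramp_dur = 0.01) {
  off <- cf_offsets_one_erb(freq)
  cfs <- c(off["below"], on = freq, off["above"])
  labels <- c("-1 ERB", "on", "+1 ERB")
  ref <- chain_reference_gain(cfg)
  win <- steady_window(dur, ramp_dur)
  rows <- purrr::map_dfr(levels, function(lv) {
    tone <- make_pure_tone(freq, dur, lv, ramp_dur, cfg$fs)
    y <- run_chain(tone, cfg, tap = "cochlea", cfs = unname(cfs))
    tibble(offset = labels, cf = unname(cfs), level_db = lv,
           output_db = vapply(seq_len(ncol(y)), function(k)
             rms_db_window(y[, k], cfg$fs, win), numeric(1)) + ref)
  })
  structure(rows, class = c("io_curves", class(rows)),
            freq = freq, reference_gain = ref, label = cfg$label)
}

#' Excitation pattern of a stimulus across CFs
#'
#' Steady-state rms output level (dB, shifted by the chain reference gain)
#' of the cochlear tap at each requested CF.
#'
#' @param cfg a [chain_config()]
#' @param stim a [new_stimulus()] object
#' @param cfs CFs to evaluate (Hz); default the chain's CF grid
#' @param window analysis window (s); default the central steady portion
#' @return a tibble of class `excitation_pattern` with columns `cf`,
#'   `output_db`
#' @export
excitation_pattern <- function(cfg, stim, cfs = NULL, window = NULL) {
  cfs <- cfs %||% cfg$cf_grid
  window <- window %||% steady_window(stim_duration(stim), stim$ramp_dur)
  ref <- chain_reference_gain(cfg)
  y <- run_chain(stim, cfg, tap = "cochlea", cfs = cfs)
  out <- tibble(cf = cfs,
                output_db = vapply(seq_len(ncol(y)), function(k)
                  rms_db_window(y[, k], cfg$fs, window), numeric(1)) + ref)
  structure(out, class = c("excitation_pattern", class(out)),
            reference_gain = ref, label = cfg$label)
}

## fractional-octave moving average of a power spectrum; `width` in octaves
smooth_octave <- function(f, p, width = 1 / 24) {
  lo <- f * 2^(-width / 2); hi <- f * 2^(width / 2)
  i_lo <- findInterval(lo, f) + 1L
  i_hi <- findInterval(hi, f)
  cs <- cumsum(p)
  n <- i_hi - i_lo + 1L
  ok <- n >= 1 & i_lo >= 1
  out <- p
  out[ok] <- (cs[i_hi[ok]] - c(0, cs)[i_lo[ok]]) / n[ok]
  out
}

#' Estimate cochlear-filter Q factors from a frozen-noise response
#'
#' The noise response of each channel at the cochlear tap is cut into
#' 500-ms non-overlapping windows; magnitude-squared FFT spectra are
#' averaged across windows, smoothed with a narrow (1/24-octave) moving
#' average that suppresses the residual spectral ripple without widening
#' the filter peak, and the -3 dB points around the peak are interpolated.
#' The quality factor is `Q = CF / BW` with `BW` the -3 dB bandwidth.
#'
#' @param cfg a [chain_config()]
#' @param cfs CFs to analyse (Hz)
#' @param noise a frozen-noise stimulus of at least 3 s
#'   ([make_frozen_noise()])
#' @param window_dur analysis window duration (s)
#' @param smooth_width moving-average width (octaves)
#' @param response optional precomputed samples-by-channels response matrix
#'   (bypasses the chain run; used to validate the estimator against
#'   filters of known bandwidth)
#' @return a tibble of class `q_estimates` with columns `cf`, `bw_3db`,
#'   `q`, `level_db`, `flagged`
#' @export
estimate_q3db <- function(cfg, cfs, noise, window_dur = 0.5,
                          smooth_width = 1 / 24, response = NULL) {
  fs <- cfg$fs
  nwin <- floor(window_dur * fs)
  n_seg <- floor(length(noise$samples) / nwin)
  if (n_seg < 2) abort("noise must contain at least two analysis windows")
  y <- response %||% run_chain(noise, cfg, tap = "cochlea", cfs = cfs)
  freqs <- (0:(nwin - 1)) * fs / nwin
  keep <- freqs > 0 & freqs <= fs / 2
  rows <- purrr::map_dfr(seq_along(cfs), function(k) {
    p <- Reduce(`+`, lapply(seq_len(n_seg), function(s) {
      seg <- y[((s - 1) * nwin + 1):(s * nwin), k]
      Mod(fft(seg))^2
    })) / n_seg
    f <- freqs[keep]; p <- p[keep]
    p_s <- smooth_octave(f, p, smooth_width)
    db <- 10 * log10(p_s / max(p_s))
    ipk <- which.max(db)
    cross <- function(side) {
      idx <- if (side == "lo") rev(seq_len(ipk)) else ipk:length(db)
      below <- which(db[idx] <= -3.0103)
      if (!length(below)) return(NA_real_)
      j <- idx[below[1]]; jp <- if (side == "lo") j + 1L else j - 1L
      approx(db[c(jp, j)], f[c(jp, j)], xout = -3.0103)$y
    }
    f_lo <- cross("lo"); f_hi <- cross("hi")
    bw <- f_hi - f_lo
    tibble(cf = cfs[k], bw_3db = bw, q = cfs[k] / bw,
           level_db = noise$level_db,
           flagged = is.na(f_lo) || is.na(f_hi))
  })
  structure(rows, class = c("q_estimates", class(rows)), label = cfg$label)
}

#' Number of -3 dB-overlapping filters needed to cover a frequency range
#'
#' Greedy covering: the first filter has its lower -3 dB edge at `f_start`;
#' each next CF is placed so its lower edge equals the previous filter's
#' upper edge; placement stops with the first filter whose upper edge
#' reaches `f_stop`.  Bandwidths come from the measured Q factors,
#' interpolated linearly in log-CF vs log-Q.
#'
#' @param q_estimates a [estimate_q3db()] result (rows with `flagged` are
#'   dropped)
#' @param f_start,f_stop covered range (Hz)
#' @return a list of class `filter_count` with `count`, `mean_bw_erb`, and
#'   the placed `filters` tibble (`cf`, `bw`, `f_lo`, `f_hi`)
#' @export
count_filters <- function(q_estimates, f_start = 126, f_stop = 8000) {
  qe <- q_estimates[!q_estimates$flagged, ]
  if (nrow(qe) < 2) abort("need at least two usable Q estimates")
  qfun <- function(cf) {
    lq <- approx(log(qe$cf), log(qe$q), xout = log(cf), rule = 2)$y
    exp(lq)
  }
  bw_at <- function(cf) cf / qfun(cf)
  place_next <- function(edge, first = FALSE) {
    cf <- edge * 1.05
    for (i in 1:60) cf <- edge + bw_at(cf) / 2
    cf
  }
  cfs <- c(); edge <- f_start
  repeat {
    cf <- place_next(edge)
    cfs <- c(cfs, cf)
    edge <- cf + bw_at(cf) / 2
    if (edge >= f_stop) break
    if (length(cfs) > 500) abort("filter covering did not terminate")
  }
  bw <- bw_at(cfs)
  filters <- tibble(cf = cfs, bw = bw, f_lo = cfs - bw / 2, f_hi = cfs + bw / 2)
  structure(list(count = length(cfs),
                 mean_bw_erb = mean(bw / erb_n(cfs)),
                 filters = filters),
            class = "filter_count")
}

#' @export
print.filter_count <- function(x, ...) {
  cat(sprintf("<filter_count> %d filters, mean bandwidth %.3f ERB_N\n",
              x$count, x$mean_bw_erb))
  invisible(x)
}
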