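## pad a stimulus with leading/trailing silence (keeps calibration metadata)
pad_silence <- function(stim, before = 0.05, after = 0.1) {
  stim$samples <- c(numeric(round(before * stim$fs)), stim$samples,
                    numeric(round(after * stim$fs)))
  stim$label <- paste(stim$label, "(padded)")
  stim
}

#' Rate-level functions at the auditory-nerve tap
#'
#' A 300-ms pure tone (2.5-ms cosine ramps, 50 ms of leading silence so the
#' tone spans 50-350 ms of the trace) is processed to the adaptation output
#' at the on-frequency channel for each level.  The onset response is the
#' maximum of the trace; the steady response is the mean over the 300-340 ms
#' plateau window.
#'
#' @param cfg a [chain_config()]
#' @param freq tone frequency (Hz)
#' @param levels stimulus levels (dB SPL)
#' @param dur tone duration (s)
#' @return a tibble of class `rate_level_result` with columns `level_db`,
#'   `onset`, `steady`; attribute `units`
#' @export
rate_level_curves <- function(cfg, freq = 4000, levels = seq(0, 100, 10),
                              dur = 0.3) {
  units <- NULL
  rows <- purrr::map_dfr(levels, function(lv) {
    tone <- pad_silence(make_pure_tone(freq, dur, lv, ramp_dur = 0.0025,
                                       fs = cfg$fs))
    y <- run_chain(tone, cfg, tap = "an", cfs = freq)
    units <<- attr(y, "units")
    idx <- seq(floor(0.300 * cfg$fs) + 1L, floor(0.340 * cfg$fs))
    tibble(level_db = lv, onset = max(y[, 1]), steady = mean(y[idx, 1]))
  })
  structure(rows, class = c("rate_level_result", class(rows)),
            units = units, freq = freq, label = cfg$label)
}

#' Adaptation trace for a single tone
#'
#' Convenience wrapper returning the on-CF adaptation-stage trace for a
#' tone with 50 ms of leading silence, mirroring the onset-overshoot /
#' plateau / offset-undershoot analyses.
#'
#' @param cfg a [chain_config()]
#' @param freq tone frequency (Hz)
#' @param level_db level (dB SPL)
#' @param dur tone duration (s)
#' @return a tibble with columns `time` (s) and `response`
#' @export
adaptation_trace <- function(cfg, freq = 4000, level_db = 70, dur = 0.3) {
  tone <- pad_silence(make_pure_tone(freq, dur, level_db, ramp_dur = 0.0025,
                                     fs = cfg$fs), after = 0.25)
  y <- run_chain(tone, cfg, tap = "an", cfs = freq)
  tibble(time = (seq_len(nrow(y)) - 1) / cfg$fs, response = y[, 1])
}

#' Synchrony-capture envelope-fluctuation metric
#'
#' For a three-component complex tone, on-frequency channels are expected to
#' be dominated by a single component (flat envelope; synchrony capture)
#' while off-frequency channels fluctuate at the beat rate.  Per channel,
#' local maxima above the mean response within the analysis window are
#' connected by linear interpolation; the fluctuation metric is the
#' standard deviation of that envelope divided by `scale / 30`.
#'
#' @param cfg a [chain_config()]
#' @param stim the complex-tone stimulus; default three components at
#'   414, 650 and 1000 Hz, 50 dB SPL, 300 ms
#' @param cfs channel CFs (Hz); default seven cochlear-map CFs spaced about
#'   one ERB_N apart straddling the three components
#' @param scale amplitude scale of the chain output (800 MU for
#'   adaptation-loop chains)
#' @param window analysis window (s)
#' @return a tibble of class `sync_fluctuation` with columns `cf`, `role`
#'   (`"on"`/`"off"`), `metric`
#' @export
synchrony_fluctuation <- function(cfg, stim = NULL, cfs = NULL, scale = 800,
                                  window = c(0.220, 0.250)) {
  stim <- stim %||% make_complex_tone(c(414, 650, 1000), 50, 0.3, cfg$fs)
  components <- c(414, 650, 1000)
  if (is.null(cfs)) {
    n <- greenwood_section(c(415, 489, 574, 662, 769, 881, 1007))
    cfs <- greenwood_cf(n)
  }
  role <- ifelse(vapply(cfs, function(cf)
    min(abs(hz_to_erbnum(cf) - hz_to_erbnum(components))), numeric(1)) < 0.5,
    "on", "off")
  y <- run_chain(stim, cfg, tap = "an", cfs = cfs)
  fs <- cfg$fs
  idx <- seq(floor(window[1] * fs) + 1L, min(nrow(y), floor(window[2] * fs)))
  metric <- vapply(seq_along(cfs), function(k) {
    w <- y[idx, k]
    im <- which(diff(sign(diff(w))) < 0) + 1L
    im <- im[w[im] > mean(w)]
    if (length(im) < 2) {
      warning("fewer than two qualifying maxima; metric set to 0")
      return(0)
    }
    env <- approx(im, w[im], xout = seq_along(w), rule = 2)$y
    sd(env) / (scale / 30)
  }, numeric(1))
  out <- tibble(cf = cfs, role = role, metric = metric)
  structure(out, class = c("sync_fluctuation", class(out)),
            scale = scale, label = cfg$label)
}
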