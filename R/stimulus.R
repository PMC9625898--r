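#' Stimulus objects
#'
#' A `stimulus` is a calibrated sound-pressure waveform: a numeric vector of
#' instantaneous pressures in Pascal together with its sampling rate and level
#' metadata.  All generators in the package return this class.  Steady
#' stimuli are calibrated so that the rms of the waveform equals
#' `20e-6 * 10^(level_db/20)` Pa; calibration is measured over the whole
#' signal, ramps included (ramps are kept at or below 10% of the duration so
#' the difference stays well under the 0.05-dB contract).
#'
#' @param samples numeric vector of sound pressures (Pa)
#' @param fs sampling rate (Hz)
#' @param level_db nominal level (dB SPL re 20 uPa); `NA` for uncalibrated
#' @param ramp_dur onset/offset ramp duration (s)
#' @param label free-text description
#' @return an object of class `stimulus`
#' @export
new_stimulus <- function(samples, fs, level_db = NA_real_, ramp_dur = 0,
                         label = "") {
  stopifnot(is.numeric(samples), all(is.finite(samples)), fs > 0)
  structure(
    list(samples = as.numeric(samples), fs = fs, level_db = level_db,
         ramp_dur = ramp_dur, label = label, convention = NA_character_),
    class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("<stimulus> %s\n", x$label))
  cat(sprintf("  %d samples @ %g Hz (%.4g s), nominal level %s dB SPL\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              format(x$level_db)))
  if (!is.na(x$convention))
    cat(sprintf("  level convention applied: %s\n", x$convention))
  invisible(x)
}

#' @export
as_tibble.stimulus <- function(x, ...) {
  tibble(time = (seq_along(x$samples) - 1) / x$fs, pressure = x$samples)
}

#' Duration of a stimulus in seconds
#' @param stim a [new_stimulus()] object
#' @return duration in s
#' @export
stim_duration <- function(stim) length(stim$samples) / stim$fs

#' Measured rms level of a stimulus in dB SPL
#' @param stim a [new_stimulus()] object
#' @param window optional `c(from, to)` time window in s
#' @return measured level in dB SPL
#' @export
stim_level <- function(stim, window = NULL) {
  x <- stim$samples
  if (!is.null(window)) {
    idx <- seq(max(1L, floor(window[1] * stim$fs) + 1L),
               min(length(x), ceiling(window[2] * stim$fs)))
    x <- x[idx]
  }
  pa_to_spl(sqrt(mean(x^2)))
}

## raised-cosine (hann-flank) on/off ramps, in place
apply_ramps <- function(x, fs, ramp_dur) {
  if (ramp_dur <= 0) return(x)
  nr <- round(ramp_dur * fs)
  if (2 * nr > length(x))
    abort("2 * ramp_dur must not exceed the stimulus duration")
  if (nr == 0) return(x)
  w <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
  x[seq_len(nr)] <- x[seq_len(nr)] * w
  n <- length(x)
  x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(w)
  x
}

## scale a waveform to a target rms level in dB SPL (whole-signal rms)
calibrate_rms <- function(x, level_db) x / sqrt(mean(x^2)) * spl_to_pa(level_db)

#' Generate a calibrated pure tone
#'
#' @param freq tone frequency (Hz), must lie below Nyquist
#' @param dur duration (s)
#' @param level_db level (dB SPL)
#' @param ramp_dur raised-cosine on/off ramp duration (s)
#' @param fs sampling rate (Hz)
#' @return a [new_stimulus()] object
#' @examples
#' tone <- make_pure_tone(1000, 0.1, 100)
#' stim_level(tone)  # ~100 dB SPL
#' @export
make_pure_tone <- function(freq, dur, level_db, ramp_dur = 0.005, fs = 48000) {
  if (freq <= 0 || freq >= fs / 2) abort("freq must lie in (0, fs/2)")
  if (dur <= 0) abort("dur must be positive")
  if (2 * ramp_dur > dur) abort("2 * ramp_dur must not exceed dur")
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * freq * t)
  x <- calibrate_rms(x, level_db)
  x <- apply_ramps(x, fs, ramp_dur)
  new_stimulus(x, fs, level_db, ramp_dur,
               sprintf("pure tone %g Hz, %g dB SPL", freq, level_db))
}

#' Generate a sinusoidally amplitude-modulated tone
#'
#' The waveform `(1 + m*sin(2*pi*fmod*t)) * sin(2*pi*fc*t)` is scaled to the
#' requested rms level and ramped.
#'
#' @param fc carrier frequency (Hz)
#' @param fmod modulation rate (Hz), must be below `fc`
#' @param m modulation index in `[0, 1]`
#' @param dur duration (s)
#' @param level_db level (dB SPL)
#' @param ramp_dur ramp duration (s)
#' @param fs sampling rate (Hz)
#' @return a [new_stimulus()] object
#' @export
make_am_tone <- function(fc, fmod, m, dur, level_db, ramp_dur = 0.005,
                         fs = 48000) {
  if (m < 0 || m > 1) abort("modulation index m must lie in [0, 1]")
  if (fmod >= fc) abort("fmod must be below the carrier frequency")
  if (fc >= fs / 2) abort("fc must lie below Nyquist")
  if (2 * ramp_dur > dur) abort("2 * ramp_dur must not exceed dur")
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- (1 + m * sin(2 * pi * fmod * t)) * sin(2 * pi * fc * t)
  x <- calibrate_rms(x, level_db)
  x <- apply_ramps(x, fs, ramp_dur)
  new_stimulus(x, fs, level_db, ramp_dur,
               sprintf("AM tone fc=%g Hz, fmod=%g Hz, m=%g, %g dB SPL",
                       fc, fmod, m, level_db))
}

#' Generate a frozen (seed-deterministic) band-limited white noise
#'
#' The noise is synthesised in the frequency domain with unit magnitude for
#' every FFT bin inside the band and uniformly random phases drawn from the
#' seed, which guarantees the flat long-term spectrum the analyses assume.
#'
#' @param dur duration (s)
#' @param level_db level (dB SPL)
#' @param band `c(f_lo, f_hi)` passband (Hz)
#' @param seed integer seed freezing the waveform
#' @param fs sampling rate (Hz)
#' @param ramp_dur ramp duration (s), default 10 ms
#' @return a [new_stimulus()] object
#' @export
make_frozen_noise <- function(dur, level_db, band = c(20, 20000), seed = 1,
                              fs = 48000, ramp_dur = 0.010) {
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    abort("band must lie within (0, fs/2)")
  n <- round(dur * fs)
  freqs <- (0:(n - 1)) * fs / n
  keep <- freqs >= band[1] & freqs <= band[2] & freqs <= fs / 2
  mag <- as.numeric(keep)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  ph <- runif(n, 0, 2 * pi)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  spec <- mag * exp(1i * ph)
  ## hermitian symmetry for a real waveform
  spec_full <- spec
  if (n %% 2 == 0) {
    spec_full[(n / 2 + 2):n] <- Conj(rev(spec[2:(n / 2)]))
    spec_full[n / 2 + 1] <- abs(spec[n / 2 + 1])
  } else {
    spec_full[((n + 1) / 2 + 1):n] <- Conj(rev(spec[2:((n + 1) / 2)]))
  }
  spec_full[1] <- 0
  x <- Re(fft(spec_full, inverse = TRUE)) / n
  x <- calibrate_rms(x, level_db)
  x <- apply_ramps(x, fs, ramp_dur)
  new_stimulus(x, fs, level_db, ramp_dur,
               sprintf("frozen noise %g-%g Hz, %g dB SPL, seed %d",
                       band[1], band[2], level_db, seed))
}

#' Generate a click train of alternating polarity
#'
#' Rectangular clicks of amplitude
#' `A = 20e-6 * 10^(pe_spl/20) * 2 * sqrt(2)` Pa, i.e. the peak-to-peak
#' amplitude of a sinusoid at the given peak-equivalent SPL (a 70-dB-peSPL
#' click has `A = 0.1789` Pa).  The first click is positive; with
#' `alternating = TRUE` polarity alternates.
#'
#' @param rate repetition rate (Hz)
#' @param dur train duration (s)
#' @param click_dur single-click duration (s)
#' @param pe_spl peak-equivalent level (dB peSPL)
#' @param alternating alternate click polarity?
#' @param fs sampling rate (Hz)
#' @return a [new_stimulus()] object; `level_db` is `NA` (transient signal)
#' @export
make_click_train <- function(rate = 10, dur = 1, click_dur = 100e-6,
                             pe_spl = 70, alternating = TRUE, fs = 48000) {
  if (click_dur >= 1 / rate) abort("click_dur must be shorter than the period")
  n_click <- round(click_dur * fs)
  if (n_click < 1)
    abort(sprintf("click_dur %g s is not representable at fs = %g Hz",
                  click_dur, fs))
  amp <- spl_to_pa(pe_spl) * 2 * sqrt(2)
  n <- round(dur * fs)
  x <- numeric(n)
  onsets <- seq(0, dur - 1 / rate + 1e-12, by = 1 / rate)
  for (k in seq_along(onsets)) {
    i0 <- round(onsets[k] * fs) + 1L
    pol <- if (alternating && k %% 2 == 0) -1 else 1
    x[i0:min(n, i0 + n_click - 1L)] <- pol * amp
  }
  s <- new_stimulus(x, fs, NA_real_, 0,
                    sprintf("click train %g Hz, %g dB peSPL%s", rate, pe_spl,
                            if (alternating) ", alternating" else ""))
  s$pe_spl <- pe_spl
  s$n_clicks <- length(onsets)
  s
}

#' Generate a complex tone from equal-peak-amplitude sinusoids
#'
#' @param freqs component frequencies (Hz)
#' @param level_db total level (dB SPL)
#' @param dur duration (s)
#' @param fs sampling rate (Hz)
#' @param ramp_dur ramp duration (s)
#' @return a [new_stimulus()] object
#' @export
make_complex_tone <- function(freqs, level_db, dur, fs = 48000,
                              ramp_dur = 0.005) {
  if (length(freqs) == 0) abort("freqs must not be empty")
  if (any(freqs >= fs / 2)) abort("all component frequencies must be < fs/2")
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- rowSums(vapply(freqs, function(f) sin(2 * pi * f * t), numeric(length(t))))
  x <- calibrate_rms(x, level_db)
  x <- apply_ramps(x, fs, ramp_dur)
  new_stimulus(x, fs, level_db, ramp_dur,
               sprintf("complex tone [%s] Hz, %g dB SPL",
                       paste(freqs, collapse = ", "), level_db))
}

## chains that interpret +-1 Pa as +-0.5 full scale
HALVING_MODELS <- c("dau1997", "king2019", "osses2021")

#' Apply a model's input level convention to a stimulus
#'
#' Chains whose internal calibration maps pressures of +-1 Pa to amplitudes
#' of +-0.5 (dau1997-, king2019- and osses2021-style chains) require the
#' input scaled by 0.5 (a 6-dB attenuation); other model labels leave the
#' waveform untouched.  The scaling is tracked in metadata and applying it
#' twice is an error.
#'
#' @param stim a [new_stimulus()] object
#' @param model_label chain label, e.g. `"dau1997"`
#' @return the (possibly rescaled) stimulus
#' @export
apply_model_level_convention <- function(stim, model_label) {
  if (!is.na(stim$convention))
    abort(sprintf("level convention already applied (%s)", stim$convention))
  if (model_label %in% HALVING_MODELS) stim$samples <- 0.5 * stim$samples
  stim$convention <- model_label
  stim
}

#' Write a stimulus as a 32-bit float WAV file (samples in Pascal)
#'
#' The samples are written unscaled, so the file stores physical pressures.
#' A plain-text sidecar (`<path>.txt`) records the metadata.
#'
#' @param stim a [new_stimulus()] object
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_wav_pa <- function(stim, path) {
  x <- stim$samples
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(x) * 4L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")   # IEEE float
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(stim$fs), con, size = 4, endian = "little")
  writeBin(as.integer(stim$fs * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(x, con, size = 4, endian = "little")
  meta <- c(sprintf("fs: %g", stim$fs), sprintf("level_db: %g", stim$level_db),
            sprintf("ramp_dur: %g", stim$ramp_dur),
            sprintf("label: %s", stim$label))
  writeLines(meta, paste0(path, ".txt"))
  invisible(path)
}

#' Read a stimulus written by [write_wav_pa()]
#' @param path WAV file path
#' @return a [new_stimulus()] object
#' @export
read_wav_pa <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 4)                                  # RIFF
  readBin(con, "integer", 1, 4, endian = "little")
  readChar(con, 8)                                  # WAVEfmt
  readBin(con, "integer", 1, 4, endian = "little")
  fmt <- readBin(con, "integer", 1, 2, endian = "little")
  readBin(con, "integer", 1, 2, endian = "little")
  fs <- readBin(con, "integer", 1, 4, endian = "little")
  readBin(con, "integer", 1, 4, endian = "little")
  readBin(con, "integer", 1, 2, endian = "little")
  bits <- readBin(con, "integer", 1, 2, endian = "little")
  if (fmt != 3 || bits != 32) abort("only 32-bit float WAV is supported")
  readChar(con, 4)                                  # data
  nb <- readBin(con, "integer", 1, 4, endian = "little")
  x <- readBin(con, "double", nb / 4, size = 4, endian = "little")
  level <- NA_real_
  meta_path <- paste0(path, ".txt")
  if (file.exists(meta_path)) {
    meta <- readLines(meta_path)
    lv <- sub("^level_db: ", "", grep("^level_db: ", meta, value = TRUE))
    if (length(lv)) level <- suppressWarnings(as.numeric(lv))
  }
  new_stimulus(x, fs, level, 0, sprintf("read from %s", basename(path)))
}
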