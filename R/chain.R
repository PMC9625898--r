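#' Chain configuration
#'
#' An ordered description of one effective auditory-model chain: input level
#' convention, optional middle-ear bandpass, linear gammatone cochlea,
#' optional broken-stick compression, IHC envelope extraction, adaptation
#' (divisive loops or 3-Hz highpass), and a subcortical modulation stage
#' (resonator modulation filter or SFIE cascade).  Use [chain_preset()] for
#' the ready-made dau1997-, osses2021- and king2019-style chains.
#'
#' @param label chain label; also selects the input level convention
#' @param fs sampling rate (Hz)
#' @param cf_grid default CF grid (Hz); `NULL` for 31 ERB-spaced channels
#'   between 80 and 8000 Hz
#' @param middle_ear a [middle_ear_spec()] or `NULL`
#' @param gammatone_order gammatone filter order
#' @param group_delay_comp advance channels by their gammatone group delay?
#' @param compression a [broken_stick_spec()] or `NULL`
#' @param ihc an [lp_cascade_spec()]
#' @param adaptation `list(variant = "loops"|"highpass"|"none", spec = ,
#'   fc = )`
#' @param subcortical `list(variant = "modfb"|"sfie"|"none", spec = ,
#'   target_bmf = , sfie = , rectify = )`
#' @return a list of class `chain_config`
#' @export
chain_config <- function(label, fs = 48000, cf_grid = NULL,
                         middle_ear = NULL, gammatone_order = 4,
                         group_delay_comp = FALSE, compression = NULL,
                         ihc = ihc_preset("dau1997"),
                         adaptation = list(variant = "loops",
                                           spec = adaptation_loops_spec()),
                         subcortical = list(variant = "modfb",
                                            spec = mod_filterbank_spec(),
                                            target_bmf = 80)) {
  structure(list(label = label, fs = fs,
                 cf_grid = cf_grid %||% erbspace(80, 8000, 31),
                 middle_ear = middle_ear,
                 gammatone_order = gammatone_order,
                 group_delay_comp = group_delay_comp,
                 compression = compression, ihc = ihc,
                 adaptation = adaptation, subcortical = subcortical),
            class = "chain_config")
}

#' @export
print.chain_config <- function(x, ...) {
  cat(sprintf("<chain_config> %s (fs = %g Hz, %d channels)\n", x$label, x$fs,
              length(x$cf_grid)))
  cat(sprintf("  middle ear: %s | compression: %s | ihc: %dx order %d @ %g Hz\n",
              if (is.null(x$middle_ear)) "none" else "bandpass",
              if (is.null(x$compression)) "none" else
                sprintf("broken stick (knee %g dB, exp %g)",
                        x$compression$knee_db, x$compression$exponent),
              x$ihc$n_sections, x$ihc$section_order, x$ihc$section_fc))
  cat(sprintf("  adaptation: %s | subcortical: %s\n", x$adaptation$variant,
              x$subcortical$variant))
  invisible(x)
}

#' Ready-made effective chain configurations
#'
#' * `"dau1997"`: gammatone, HWR + first-order 1-kHz lowpass, adaptation
#'   loops (overshoot limit 10), Q = 2 modulation filter.
#' * `"osses2021"`: middle-ear bandpass (0 dB, 474.8-1230.2 Hz), gammatone
#'   with group-delay compensation, HWR + five first-order 2-kHz lowpass
#'   sections, adaptation loops (limit 5), Q = 2 modulation filterbank with
#'   a 150-Hz lowpass and the CF/4 rule.
#' * `"king2019"`: gammatone, broken-stick compression (knee 30 dB,
#'   exponent 0.3), HWR + first-order 1-kHz lowpass, 3-Hz highpass
#'   adaptation, Q = 1 king-style modulation filterbank (max BMF 120 Hz).
#'
#' All chains use the 0.5 input-scaling convention and a single modulation
#' filter targeting a BMF of about 80 Hz at the final stage.
#'
#' @param model `"dau1997"`, `"osses2021"` or `"king2019"`
#' @param fs sampling rate (Hz)
#' @param cf_grid optional CF grid override (Hz)
#' @return a [chain_config()]
#' @export
chain_preset <- function(model = c("dau1997", "osses2021", "king2019"),
                         fs = 48000, cf_grid = NULL) {
  model <- match.arg(model)
  switch(model,
    dau1997 = chain_config(
      "dau1997", fs, cf_grid,
      ihc = ihc_preset("dau1997"),
      adaptation = list(variant = "loops",
                        spec = adaptation_loops_spec(overshoot_limit = 10)),
      subcortical = list(variant = "modfb",
                         spec = mod_filterbank_spec("dau", q = 2),
                         target_bmf = 80)),
    osses2021 = chain_config(
      "osses2021", fs, cf_grid,
      middle_ear = middle_ear_spec(0, 474.8, 1230.2),
      group_delay_comp = TRUE,
      ihc = ihc_preset("osses2021"),
      adaptation = list(variant = "loops",
                        spec = adaptation_loops_spec(overshoot_limit = 5)),
      subcortical = list(variant = "modfb",
                         spec = mod_filterbank_spec("dau", q = 2,
                                                    lp150 = TRUE,
                                                    cf_quarter_rule = TRUE),
                         target_bmf = 80)),
    king2019 = chain_config(
      "king2019", fs, cf_grid,
      compression = broken_stick_spec(knee_db = 30, exponent = 0.3),
      ihc = ihc_preset("king2019"),
      adaptation = list(variant = "highpass", fc = 3),
      subcortical = list(variant = "modfb",
                         spec = mod_filterbank_spec("king", q = 1,
                                                    max_bmf = 120),
                         target_bmf = 80)))
}

CHAIN_TAPS <- c("cochlea", "ihc", "an", "ic")

#' Run a chain up to a given tap
#'
#' Executes the configured stages in order and returns the per-channel
#' output at the requested evaluation point: `"cochlea"` (after filterbank
#' and compression), `"ihc"` (after envelope extraction), `"an"` (after
#' adaptation) or `"ic"` (after the subcortical modulation stage).  The
#' input level convention of the chain is applied exactly once; the result
#' is deterministic for identical inputs.
#'
#' @param stim a [new_stimulus()] object
#' @param cfg a [chain_config()]
#' @param tap one of `"cochlea"`, `"ihc"`, `"an"`, `"ic"`
#' @param cfs optional CF grid override for this run (Hz)
#' @return samples-by-channels matrix with attributes `cfs`, `fs`, `tap`,
#'   `units` (and `mod_bmf` at the `"ic"` tap)
#' @export
run_chain <- function(stim, cfg, tap = "an", cfs = NULL) {
  if (!tap %in% CHAIN_TAPS)
    abort(sprintf("unknown tap '%s' (use %s)", tap,
                  paste(CHAIN_TAPS, collapse = ", ")))
  if (stim$fs != cfg$fs) abort("stimulus and chain sampling rates differ")
  cfs <- cfs %||% cfg$cf_grid
  if (is.na(stim$convention)) {
    stim <- apply_model_level_convention(stim, cfg$label)
  } else if (!identical(stim$convention, cfg$label)) {
    abort("stimulus carries a different chain's level convention")
  }
  if (!is.null(cfg$middle_ear)) stim <- middle_ear_filter(stim, cfg$middle_ear)
  x <- gammatone_filterbank(stim, cfs, order = cfg$gammatone_order)
  if (cfg$group_delay_comp) x <- compensate_group_delay(x, cfg$gammatone_order)
  if (!is.null(cfg$compression)) x <- broken_stick_compress(x, cfg$compression)
  units <- "Pa-eq"
  if (tap == "cochlea") return(tag_tap(x, tap, units))
  x <- ihc_hwr_lp(x, cfg$ihc, cfg$fs)
  if (tap == "ihc") return(tag_tap(x, tap, units))
  ad <- cfg$adaptation
  if (identical(ad$variant, "loops")) {
    x <- adaptation_loops(x, ad$spec, cfg$fs)
    units <- "MU"
  } else if (identical(ad$variant, "highpass")) {
    x <- highpass_adaptation(x, ad$fc %||% 3, cfg$fs)
    units <- "a.u."
  }
  if (tap == "an") return(tag_tap(x, tap, units))
  sub <- cfg$subcortical
  if (identical(sub$variant, "modfb")) {
    if (isTRUE(sub$spec$lp150)) x <- lp150_filter(x, cfg$fs)
    bmfs <- numeric(ncol(x))
    for (k in seq_len(ncol(x))) {
      filt <- modulation_filter_near(sub$spec, sub$target_bmf %||% 80,
                                     cf = attr(x, "cfs")[k])
      bmfs[k] <- filt$bmf
      x[, k] <- apply_modulation_filter(x[, k], filt$bmf, sub$spec$q, cfg$fs)
    }
    attr(x, "mod_bmf") <- bmfs
  } else if (identical(sub$variant, "sfie")) {
    sf <- sub$sfie %||% sfie_preset("verhulst")
    if (any(x < 0)) x <- pmax(x, 0)
    x <- sfie_stage(x, sf$cn, sf$ic, cfg$fs,
                    rectify = !isFALSE(sub$rectify))
    attr(x, "mod_bmf") <- rep(sfie_bmf(sf$cn, sf$ic), ncol(x))
  }
  tag_tap(x, "ic", units)
}

tag_tap <- function(x, tap, units) {
  attr(x, "tap") <- tap
  attr(x, "units") <- units
  x
}

#' Reference gain of a chain
#'
#' The vertical shift (dB) that places the on-CF cochlear-tap response to a
#' 1000-Hz pure tone of 100 dB SPL at 100 dB on the output scale.  Used to
#' align excitation patterns and I/O curves across chains.
#'
#' @param cfg a [chain_config()]
#' @return reference gain (dB)
#' @export
chain_reference_gain <- function(cfg) {
  tone <- make_pure_tone(1000, 0.1, 100, ramp_dur = 0.005, fs = cfg$fs)
  y <- run_chain(tone, cfg, tap = "cochlea", cfs = 1000)
  idx <- seq(floor(0.025 * cfg$fs), floor(0.095 * cfg$fs))
  100 - pa_to_spl(sqrt(mean(y[idx, 1]^2)))
}
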