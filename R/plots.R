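#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   scale_x_log10 facet_wrap
#' @export
ggplot2::autoplot

#' Plot a modulation transfer function
#' @param object an `mtf_curve`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.mtf_curve <- function(object, ...) {
  ggplot(object$data, aes(x = .data$fmod, y = .data$gain)) +
    geom_line() + geom_point() +
    labs(x = "modulation rate (Hz)", y = "normalised response",
         title = sprintf("%s MTF (carrier %g Hz, %g dB SPL): BMF %g Hz",
                         object$label, object$carrier, object$level_db,
                         object$bmf))
}

#' Plot cochlear input-output curves
#' @param object an `io_curves` tibble
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.io_curves <- function(object, ...) {
  ggplot(object, aes(x = .data$level_db, y = .data$output_db,
                     colour = .data$offset)) +
    geom_line() + geom_point() +
    labs(x = "input level (dB SPL)", y = "output level (dB)",
         title = sprintf("%s I/O curves at %g Hz", attr(object, "label"),
                         attr(object, "freq")))
}

#' Plot estimated Q factors against the tuning formulas
#' @param object a `q_estimates` tibble
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.q_estimates <- function(object, ...) {
  ref <- tibble(cf = exp(seq(log(min(object$cf)), log(max(object$cf)),
                             length.out = 100)))
  ref <- dplyr::mutate(ref, sharp = q_erb(.data$cf, "sharp"),
                       broad = q_erb(.data$cf, "broad"))
  ggplot(object, aes(x = .data$cf, y = .data$q)) +
    geom_line(data = ref, aes(y = .data$sharp), linetype = 2,
              colour = "grey60") +
    geom_line(data = ref, aes(y = .data$broad), linetype = 3,
              colour = "grey40") +
    geom_point() + scale_x_log10() +
    labs(x = "CF (Hz)", y = expression(Q[-3 * dB]),
         title = sprintf("%s frequency selectivity (%g dB SPL noise)",
                         attr(object, "label"), object$level_db[1]))
}

#' Plot rate-level curves
#' @param object a `rate_level_result` tibble
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.rate_level_result <- function(object, ...) {
  long <- tidyr_pivot(object)
  ggplot(long, aes(x = .data$level_db, y = .data$response,
                   colour = .data$which)) +
    geom_line() + geom_point() +
    labs(x = "level (dB SPL)", y = sprintf("response (%s)",
                                           attr(object, "units")),
         title = sprintf("%s rate-level at %g Hz", attr(object, "label"),
                         attr(object, "freq")))
}

## small manual pivot to avoid a tidyr dependency for one call
tidyr_pivot <- function(x) {
  dplyr::bind_rows(
    tibble(level_db = x$level_db, which = "onset", response = x$onset),
    tibble(level_db = x$level_db, which = "steady", response = x$steady))
}

#' Plot an excitation pattern
#' @param object an `excitation_pattern` tibble
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.excitation_pattern <- function(object, ...) {
  ggplot(object, aes(x = .data$cf, y = .data$output_db)) +
    geom_line() + geom_point() + scale_x_log10() +
    labs(x = "CF (Hz)", y = "output level (dB)",
         title = sprintf("%s excitation pattern", attr(object, "label")))
}

#' Plot a broadband click-train response
#' @param object a `click_response`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.click_response <- function(object, ...) {
  ggplot(object$waveform, aes(x = .data$time, y = .data$response)) +
    geom_line() +
    labs(x = "time (s)", y = sprintf("response (%s)", object$units),
         title = sprintf("%s broadband click response", object$label))
}

#' @importFrom rlang .data
NULL
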