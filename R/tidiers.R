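#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a modulation transfer function
#' @param x an `mtf_curve`
#' @param ... unused
#' @return tibble with `fmod`, `response`, `gain`
#' @export
tidy.mtf_curve <- function(x, ...) x$data

#' One-row summary of a modulation transfer function
#' @param x an `mtf_curve`
#' @param ... unused
#' @return tibble with `bmf`, `carrier`, `level_db`, `n_fmod`, `bandpass`
#'   (gain below 1 at both grid ends)
#' @export
glance.mtf_curve <- function(x, ...) {
  g <- x$data$gain
  tibble(bmf = x$bmf, carrier = x$carrier, level_db = x$level_db,
         n_fmod = nrow(x$data),
         bandpass = g[1] < 1 && g[length(g)] < 1)
}

#' Tidy a click-train response
#' @param x a `click_response`
#' @param ... unused
#' @return the broadband waveform tibble
#' @export
tidy.click_response <- function(x, ...) x$waveform

#' One-row summary of a click-train response
#' @param x a `click_response`
#' @param ... unused
#' @return tibble with `p2p_pos`, `p2p_neg`, `units`
#' @export
glance.click_response <- function(x, ...) {
  tibble(p2p_pos = x$p2p_pos, p2p_neg = x$p2p_neg, units = x$units)
}

#' Tidy a filter-count result
#' @param x a `filter_count`
#' @param ... unused
#' @return the placed-filters tibble
#' @export
tidy.filter_count <- function(x, ...) x$filters

#' One-row summary of a filter-count result
#' @param x a `filter_count`
#' @param ... unused
#' @return tibble with `count`, `mean_bw_erb`
#' @export
glance.filter_count <- function(x, ...) {
  tibble(count = x$count, mean_bw_erb = x$mean_bw_erb)
}

#' One-row summary of rate-level curves
#' @param x a `rate_level_result`
#' @param ... unused
#' @return tibble with the onset saturation ceiling and dynamic ranges
#' @export
glance.rate_level_result <- function(x, ...) {
  tibble(max_onset = max(x$onset), max_steady = max(x$steady),
         onset_ge_steady = all(x$onset >= x$steady),
         units = attr(x, "units"))
}
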