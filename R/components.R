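#' Define an evoked-response component
#'
#' Components are Gaussian bumps in time: a smooth unimodal shape whose
#' analytic peak makes amplitude/latency recovery checkable. Subject-level
#' variability enters through the latency and amplitude standard deviations.
#'
#' @param label component name (e.g. `"N100"`, `"P300"`, `"MMN-early"`).
#' @param polarity +1 or -1.
#' @param mean_latency_ms,latency_sd_ms latency distribution (ms).
#' @param mean_amplitude_uV,amplitude_sd_uV amplitude distribution (uV,
#'   positive; the sign comes from `polarity`).
#' @param width_ms Gaussian temporal spread (ms), > 0.
#' @param channels optional character vector restricting the component to a
#'   subset of channels (default: present on all channels).
#' @return object of class `component_spec`.
#' @export
component_spec <- function(label, polarity, mean_latency_ms,
                           latency_sd_ms = 0, mean_amplitude_uV = 1,
                           amplitude_sd_uV = 0, width_ms = 30,
                           channels = NULL) {
  abort_if(!polarity %in% c(-1, 1), "`polarity` must be +1 or -1")
  abort_if(width_ms <= 0, "`width_ms` must be > 0")
  abort_if(latency_sd_ms < 0 || amplitude_sd_uV < 0,
           "standard deviations must be >= 0")
  structure(list(label = label, polarity = polarity,
                 mean_latency_ms = mean_latency_ms,
                 latency_sd_ms = latency_sd_ms,
                 mean_amplitude_uV = mean_amplitude_uV,
                 amplitude_sd_uV = amplitude_sd_uV,
                 width_ms = width_ms, channels = channels),
            class = "component_spec")
}

# One realized (amplitude, latency) draw per component; amplitudes are
# truncated at 0 so polarity is never flipped by a large negative draw.
draw_component_params <- function(components) {
  lapply(components, function(co) {
    a <- co$mean_amplitude_uV
    l <- co$mean_latency_ms
    if (co$amplitude_sd_uV > 0) a <- max(0, rnorm(1, a, co$amplitude_sd_uV))
    if (co$latency_sd_ms > 0) l <- rnorm(1, l, co$latency_sd_ms)
    list(label = co$label, polarity = co$polarity, amplitude = a,
         latency = l, width = co$width_ms, channels = co$channels)
  })
}

# Sum of Gaussian bumps evaluated at times t_ms for one channel.
template_from_params <- function(params, t_ms, channel = NULL) {
  w <- numeric(length(t_ms))
  for (p in params) {
    if (!is.null(channel) && !is.null(p$channels) &&
        !(channel %in% p$channels)) next
    w <- w + p$polarity * p$amplitude *
      exp(-(t_ms - p$latency)^2 / (2 * p$width^2))
  }
  w
}

#' Build an evoked-response template on an epoch grid
#'
#' `waveform(t) = sum_c polarity_c * a_c * exp(-(t - l_c)^2 / (2 width_c^2))`
#' sampled at `floor(t_min fs/1000) .. floor(t_max fs/1000)` (the same grid
#' the preprocessing uses). With `draw = TRUE`, amplitudes and latencies are
#' drawn from each component's mean/sd (sd 0 means fixed).
#'
#' @param components list of [component_spec()] (empty list gives a zero
#'   waveform).
#' @param window_ms length-2 epoch window `c(t_min_ms, t_max_ms)`.
#' @param fs_hz sampling rate.
#' @param channel optional channel name for channel-restricted components.
#' @param draw draw subject-level amplitude/latency (uses current RNG).
#' @return numeric waveform with attribute `t_ms` (sample times).
#' @export
erp_template <- function(components, window_ms, fs_hz, channel = NULL,
                         draw = FALSE) {
  lat <- vapply(components, function(co) co$mean_latency_ms, numeric(1))
  abort_if(length(lat) > 0 &&
             (min(lat) < window_ms[1] || max(lat) > window_ms[2]),
           "epoch window must cover all component latencies")
  idx <- floor(window_ms[1] * fs_hz / 1000):floor(window_ms[2] * fs_hz / 1000)
  t_ms <- idx / fs_hz * 1000
  params <- if (draw) draw_component_params(components)
            else draw_fixed_params(components)
  w <- template_from_params(params, t_ms, channel)
  attr(w, "t_ms") <- t_ms
  w
}

draw_fixed_params <- function(components) {
  lapply(components, function(co)
    list(label = co$label, polarity = co$polarity,
         amplitude = co$mean_amplitude_uV, latency = co$mean_latency_ms,
         width = co$width_ms, channels = co$channels))
}
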