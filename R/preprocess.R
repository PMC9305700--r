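#' Epoch window on the sample grid
#'
#' The sample index range relative to the event-onset sample is
#' `floor(t_min fs/1000) .. floor(t_max fs/1000)`, both ends inclusive --
#' the convention that yields 257 samples for -200..800 ms and 155 samples
#' for -100..500 ms at 256 Hz.
#'
#' @param t_min_ms,t_max_ms window bounds in ms (`t_min_ms` < 0 <=
#'   `t_max_ms` so a pre-onset baseline exists).
#' @param fs_hz sampling rate.
#' @return `epoch_window` with the index range, sample times and count.
#' @export
epoch_window <- function(t_min_ms, t_max_ms, fs_hz) {
  abort_if(t_min_ms > 0 || t_max_ms < 0,
           "need t_min_ms <= 0 <= t_max_ms")
  abort_if(fs_hz <= 0, "`fs_hz` must be > 0")
  i0 <- as.integer(floor(t_min_ms * fs_hz / 1000))
  i1 <- as.integer(floor(t_max_ms * fs_hz / 1000))
  structure(list(t_min_ms = t_min_ms, t_max_ms = t_max_ms, fs_hz = fs_hz,
                 idx = i0:i1, t_ms = (i0:i1) / fs_hz * 1000,
                 n_samples = i1 - i0 + 1L),
            class = "epoch_window")
}

#' Extract per-class epoch stacks from a continuous recording
#'
#' Event onsets map to sample `round(onset_s * fs) + 1`; epochs whose window
#' would leave the recording are dropped with a warning.
#'
#' @param x numeric matrix (samples x channels) or vector.
#' @param events data.frame with `onset_s` and `label`.
#' @param window an [epoch_window()].
#' @param classes labels to keep (default: all present).
#' @return named list per class of arrays `[samples, channels, trials]`.
#' @export
extract_epochs <- function(x, events, window, classes = NULL) {
  stopifnot(inherits(window, "epoch_window"))
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  if (is.null(classes)) classes <- unique(events$label)
  n <- nrow(x)
  out <- list()
  for (cls in classes) {
    ev <- events[events$label == cls, , drop = FALSE]
    onset_samples <- round(ev$onset_s * window$fs_hz) + 1
    lo <- onset_samples + window$idx[1]
    hi <- onset_samples + window$idx[length(window$idx)]
    ok <- lo >= 1 & hi <= n
    if (any(!ok))
      warning(sum(!ok), " epoch(s) of class '", cls,
              "' outside the recording were dropped", call. = FALSE)
    onset_samples <- onset_samples[ok]
    ep <- array(0, dim = c(window$n_samples, ncol(x), length(onset_samples)),
                dimnames = list(NULL, colnames(x), NULL))
    for (k in seq_along(onset_samples))
      ep[, , k] <- x[onset_samples[k] + window$idx, , drop = FALSE]
    out[[cls]] <- ep
  }
  out
}

#' Baseline-correct an epoch
#'
#' Subtracts the mean of the pre-onset samples (times < 0) from the whole
#' epoch, per channel. Idempotent.
#'
#' @param epoch matrix (samples x channels), vector, or 3-d epoch stack.
#' @param window the [epoch_window()] the epoch was cut with.
#' @return corrected epoch, same shape.
#' @export
baseline_correct <- function(epoch, window) {
  stopifnot(inherits(window, "epoch_window"))
  pre <- window$t_ms < 0
  abort_if(!any(pre), "no pre-onset samples available for baseline")
  if (is.array(epoch) && length(dim(epoch)) == 3) {
    for (k in seq_len(dim(epoch)[3]))
      epoch[, , k] <- baseline_correct(epoch[, , k, drop = FALSE][, , 1],
                                       window)
    return(epoch)
  }
  if (!is.matrix(epoch)) {
    return(epoch - mean(epoch[pre]))
  }
  sweep(epoch, 2, colMeans(epoch[pre, , drop = FALSE]))
}

#' Reject epochs by absolute amplitude
#'
#' Removes epochs with any `|sample| > threshold_uV` on any channel.
#'
#' @param epochs 3-d array `[samples, channels, trials]`.
#' @param threshold_uV rejection threshold (> 0).
#' @param class_label used in the error message when everything is rejected.
#' @return list with `epochs` (kept) and `rejected` (count).
#' @export
reject_artifacts <- function(epochs, threshold_uV = 100,
                             class_label = "epochs") {
  abort_if(threshold_uV <= 0, "`threshold_uV` must be > 0")
  stopifnot(length(dim(epochs)) == 3)
  peak <- apply(abs(epochs), 3, max)
  keep <- peak <= threshold_uV
  abort_if(!any(keep), "all epochs rejected for class '", class_label,
           "' at threshold ", threshold_uV, " uV")
  list(epochs = epochs[, , keep, drop = FALSE],
       rejected = as.integer(sum(!keep)))
}

#' Average epochs into one evoked response
#'
#' Samplewise mean per channel, then 30 Hz lowpass and baseline correction
#' are re-applied.
#'
#' @param epochs 3-d array `[samples, channels, trials]` (>= 1 trial).
#' @param window the [epoch_window()].
#' @param lowpass_hz re-applied lowpass cut-off (`NULL` disables).
#' @return matrix (samples x channels).
#' @export
average_epochs <- function(epochs, window, lowpass_hz = 30) {
  stopifnot(length(dim(epochs)) == 3)
  abort_if(dim(epochs)[3] < 1, "cannot average an empty epoch stack")
  avg <- rowMeans(epochs, dims = 2)
  if (!is.null(lowpass_hz))
    avg <- lowpass_filter(avg, window$fs_hz, high_hz = lowpass_hz)
  baseline_correct(avg, window)
}

#' Preprocess one continuous recording into per-class averaged ERPs
#'
#' Pipeline: zero-phase Butterworth bandpass (0.1--30 Hz, order 4) ->
#' epoching -> baseline correction -> absolute-amplitude artifact rejection
#' -> per-class averaging with lowpass and baseline re-applied.
#' Re-referencing is a pass-through for the synthetic 3-channel montage.
#'
#' @param recording an `erp_recording` (fields `x`, `fs_hz`, `events`,
#'   `window_ms`), e.g. from the cohort simulator.
#' @param classes stimulus classes to average (default: all in the events).
#' @param low_hz,high_hz,order bandpass settings.
#' @param artifact_threshold_uV rejection threshold (`Inf` disables).
#' @param max_epochs_per_class optional cap: only the first k surviving
#'   epochs per class are averaged.
#' @return named list per class of averaged waveform matrices
#'   (samples x channels), with attribute `n_epochs`.
#' @export
preprocess_recording <- function(recording, classes = NULL, low_hz = 0.1,
                                 high_hz = 30, order = 4,
                                 artifact_threshold_uV = 100,
                                 max_epochs_per_class = NULL) {
  fs <- recording$fs_hz
  xf <- bandpass_filter(recording$x, fs, low_hz, high_hz, order)
  win <- epoch_window(recording$window_ms[1], recording$window_ms[2], fs)
  stacks <- extract_epochs(xf, recording$events, win, classes)
  out <- list()
  for (cls in names(stacks)) {
    ep <- baseline_correct(stacks[[cls]], win)
    if (is.finite(artifact_threshold_uV)) {
      ep <- reject_artifacts(ep, artifact_threshold_uV, cls)$epochs
    }
    if (!is.null(max_epochs_per_class) &&
        dim(ep)[3] > max_epochs_per_class)
      ep <- ep[, , seq_len(max_epochs_per_class), drop = FALSE]
    abort_if(dim(ep)[3] == 0, "no epochs left for class '", cls, "'")
    avg <- average_epochs(ep, win, lowpass_hz = high_hz)
    attr(avg, "n_epochs") <- dim(ep)[3]
    out[[cls]] <- avg
  }
  out
}
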