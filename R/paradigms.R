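#' Define an oddball paradigm
#'
#' A paradigm is a set of stimulus classes with presentation proportions and
#' durations, an inter-stimulus interval (ISI) and a total stimulus count.
#'
#' @param name paradigm label, one of `"auditory_p300"`, `"visual_p300"`,
#'   `"mmn"` (free-form labels are allowed for custom paradigms).
#' @param classes data.frame with columns `label`, `proportion`,
#'   `duration_ms`; proportions must sum to 1.
#' @param isi_ms ISI in milliseconds: length-2 numeric `c(lo, hi)` for a
#'   uniform draw, or a single value for a fixed ISI.
#' @param n_stimuli number of stimuli in one session.
#' @param rare_classes labels of the rare (deviant/target) classes whose
#'   averaged responses feed feature extraction.
#' @return an object of class `paradigm_spec`.
#' @export
paradigm_spec <- function(name, classes, isi_ms, n_stimuli,
                          rare_classes = NULL) {
  abort_if(!is.data.frame(classes) ||
             !all(c("label", "proportion", "duration_ms") %in% names(classes)),
           "`classes` needs columns label, proportion, duration_ms")
  abort_if(abs(sum(classes$proportion) - 1) > 1e-12,
           "stimulus class proportions must sum to 1 (got ",
           sum(classes$proportion), ")")
  abort_if(any(classes$proportion < 0), "proportions must be non-negative")
  abort_if(any(classes$duration_ms <= 0), "stimulus durations must be > 0")
  if (length(isi_ms) == 1) isi_ms <- c(isi_ms, isi_ms)
  abort_if(length(isi_ms) != 2 || isi_ms[1] > isi_ms[2] || isi_ms[1] < 0,
           "`isi_ms` must be a fixed value or an interval [lo, hi], lo <= hi")
  abort_if(n_stimuli < 0 || n_stimuli != round(n_stimuli),
           "`n_stimuli` must be a non-negative integer")
  if (is.null(rare_classes)) {
    rare_classes <- classes$label[classes$proportion <
                                    max(classes$proportion)]
  }
  structure(list(name = name, classes = classes, isi_ms = as.numeric(isi_ms),
                 n_stimuli = as.integer(n_stimuli),
                 rare_classes = rare_classes),
            class = "paradigm_spec")
}

#' Standard oddball paradigms
#'
#' The three sessions used throughout the package: auditory and visual P300
#' oddballs (400 stimuli, 10% targets, 10% distractors, 80% standards,
#' 100 ms stimuli, ISI uniform on 1--1.5 s) and a mismatch-negativity (MMN)
#' sequence (1800 tones, 5% duration deviants of 250 ms, 5% frequency
#' deviants, 90% standards of 100 ms, fixed 300 ms ISI).
#'
#' @return named list of [paradigm_spec()] objects.
#' @export
default_paradigms <- function() {
  p300_classes <- data.frame(
    label = c("Target", "Distractor", "Standard"),
    proportion = c(0.10, 0.10, 0.80),
    duration_ms = c(100, 100, 100))
  mmn_classes <- data.frame(
    label = c("DurationDeviant", "FrequencyDeviant", "Standard"),
    proportion = c(0.05, 0.05, 0.90),
    duration_ms = c(250, 100, 100))
  list(
    auditory_p300 = paradigm_spec("auditory_p300", p300_classes,
                                  isi_ms = c(1000, 1500), n_stimuli = 400,
                                  rare_classes = c("Target", "Distractor")),
    visual_p300 = paradigm_spec("visual_p300", p300_classes,
                                isi_ms = c(1000, 1500), n_stimuli = 400,
                                rare_classes = c("Target", "Distractor")),
    mmn = paradigm_spec("mmn", mmn_classes, isi_ms = 300, n_stimuli = 1800,
                        rare_classes = c("DurationDeviant",
                                         "FrequencyDeviant")))
}

# Largest-remainder apportionment of n among proportions (deterministic).
largest_remainder_counts <- function(proportions, n) {
  raw <- proportions * n
  base <- floor(raw)
  left <- round(n - sum(base))
  if (left > 0) {
    rem <- raw - base
    extra <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate an oddball stimulus schedule
#'
#' Per-class counts are apportioned exactly (largest-remainder rounding of
#' `proportion * n_stimuli`), the order is a seeded uniform shuffle, and the
#' gap between consecutive onsets is the previous stimulus duration plus a
#' uniform ISI draw.
#'
#' @param spec a [paradigm_spec()].
#' @param seed integer seed (optional; uses the current RNG state if `NULL`).
#' @return an `event_schedule`: data.frame `events` with `onset_s`, `label`,
#'   plus `total_duration_s` (sum of all stimulus durations and ISIs).
#' @export
simulate_schedule <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "paradigm_spec"))
  abort_if(spec$n_stimuli < 1, "schedule needs n_stimuli >= 1")
  with_seed(seed, {
    counts <- largest_remainder_counts(spec$classes$proportion,
                                       spec$n_stimuli)
    labels <- rep(spec$classes$label, counts)
    labels <- labels[sample.int(length(labels))]
    dur_s <- spec$classes$duration_ms[match(labels, spec$classes$label)] / 1000
    isi_s <- runif(spec$n_stimuli, spec$isi_ms[1], spec$isi_ms[2]) / 1000
    gaps <- dur_s + isi_s
    onsets <- c(0, cumsum(gaps[-length(gaps)]))
    structure(list(events = data.frame(onset_s = onsets, label = labels,
                                       stringsAsFactors = FALSE),
                   total_duration_s = sum(gaps),
                   paradigm = spec$name),
              class = "event_schedule")
  })
}

#' Expected session duration of a paradigm, in whole seconds
#'
#' Deterministic expectation (no sampling): the sum over classes of
#' `proportion * n_stimuli * duration` plus `n_stimuli` times the mean ISI,
#' floored to whole seconds. With the default paradigms this gives 540 s for
#' either P300 session and 733 s for the MMN session.
#'
#' @param spec a [paradigm_spec()].
#' @return integer number of seconds.
#' @export
expected_session_duration <- function(spec) {
  stopifnot(inherits(spec, "paradigm_spec"))
  stim_s <- sum(spec$classes$proportion * spec$n_stimuli *
                  spec$classes$duration_ms) / 1000
  isi_s <- spec$n_stimuli * mean(spec$isi_ms) / 1000
  as.integer(floor(stim_s + isi_s))
}
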