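CHANNELS <- c("Fz", "Cz", "Pz")

#' Default epoch windows per paradigm
#'
#' -200..800 ms for the P300 paradigms (257 samples at 256 Hz) and
#' -100..500 ms for MMN (155 samples at 256 Hz).
#' @return named list of length-2 numeric windows (ms).
#' @export
default_epoch_windows <- function() {
  list(auditory_p300 = c(-200, 800), visual_p300 = c(-200, 800),
       mmn = c(-100, 500))
}

# Evoked components for one group. The schizophrenia ("SZ") variant of the
# p300_deficit scenario carries a P300 with 40% reduced amplitude and +30 ms
# latency restricted to Cz/Pz; Fz keeps the control P300.
default_components <- function(group = c("HC", "SZ"),
                               effect = c("p300_deficit", "none"),
                               p300_amp_reduction = 0.4,
                               p300_latency_shift_ms = 30,
                               deficit_channels = c("Cz", "Pz")) {
  group <- match.arg(group)
  effect <- match.arg(effect)
  n1 <- component_spec("N100", -1, 100, 10, 5, 1, 20)
  p2 <- component_spec("P200", +1, 200, 12, 6, 1, 25)
  n2 <- component_spec("N200", -1, 260, 15, 4, 1, 25)
  p3_hc <- component_spec("P300", +1, 350, 25, 12, 2, 45)
  p300_rare <- list(n1, p2, n2, p3_hc)
  if (group == "SZ" && effect == "p300_deficit") {
    keep <- setdiff(CHANNELS, deficit_channels)
    p3_deficit <- component_spec(
      "P300", +1, 350 + p300_latency_shift_ms, 25,
      12 * (1 - p300_amp_reduction), 2, 45, channels = deficit_channels)
    p300_rare <- c(list(n1, p2, n2, p3_deficit),
                   if (length(keep))
                     list(component_spec("P300", +1, 350, 25, 12, 2, 45,
                                         channels = keep)))
  }
  p300_standard <- list(n1, p2)
  mmn_rare <- list(component_spec("MMN-early", -1, 170, 15, 4, 1, 30),
                   component_spec("MMN-late", +1, 320, 20, 5, 1, 40))
  mmn_standard <- list(component_spec("N100", -1, 120, 10, 2, 0.5, 25))
  p300 <- list(Target = p300_rare, Distractor = p300_rare,
               Standard = p300_standard)
  list(auditory_p300 = p300, visual_p300 = p300,
       mmn = list(DurationDeviant = mmn_rare, FrequencyDeviant = mmn_rare,
                  Standard = mmn_standard))
}

#' Calibrate white-noise sd for a target averaged-ERP component SNR
#'
#' The generator adds white Gaussian noise which the preprocessing restricts
#' to the filter passband; averaging `n_trials` epochs divides the residual
#' sd by `sqrt(n_trials)`. Using the ideal-band approximation, white noise
#' of sd `s0` leaves in-band sd `s0 * sqrt((hi - lo) / (fs/2))`, so
#' `s0 = amplitude * sqrt(n_trials) / (snr * sqrt((hi - lo) / (fs/2)))`.
#'
#' @param target_snr desired component amplitude / residual-noise sd on the
#'   single-subject averaged ERP.
#' @param amplitude_uV component amplitude the SNR refers to.
#' @param n_trials number of epochs averaged per class.
#' @param fs_hz sampling rate.
#' @param band filter passband (Hz).
#' @return white-noise standard deviation in uV.
#' @export
calibrate_noise_sd <- function(target_snr = 2, amplitude_uV = 12,
                               n_trials = 40, fs_hz = 256,
                               band = c(0.1, 30)) {
  frac <- sqrt((band[2] - band[1]) / (fs_hz / 2))
  amplitude_uV * sqrt(n_trials) / (target_snr * frac)
}

#' Configure a two-group synthetic ERP cohort
#'
#' @param n_per_group subjects per group (>= 2).
#' @param components_by_group nested list: group -> paradigm -> stimulus
#'   class -> list of [component_spec()].
#' @param channel_gains named scalar gain per channel (Fz, Cz, Pz).
#' @param noise_sd_uV white-noise sd added to the continuous recording.
#' @param n_trials_per_class optional cap on rare-class epochs used when
#'   averaging (`NULL` = all scheduled; 0 is invalid).
#' @param fs_hz sampling rate (Hz).
#' @param paradigms named list of [paradigm_spec()].
#' @param epoch_windows named list of epoch windows (ms) per paradigm.
#' @param trial_amp_jitter_sd trial-level multiplicative amplitude jitter sd
#'   (fraction; 0 disables).
#' @param trial_lat_jitter_ms trial-level latency jitter sd (ms; 0 disables).
#' @param seed integer master seed; every subject gets a derived sub-seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group,
                          components_by_group,
                          channel_gains = c(Fz = 0.7, Cz = 1, Pz = 0.9),
                          noise_sd_uV = 0,
                          n_trials_per_class = NULL,
                          fs_hz = 256,
                          paradigms = default_paradigms(),
                          epoch_windows = default_epoch_windows(),
                          trial_amp_jitter_sd = 0.1,
                          trial_lat_jitter_ms = 5,
                          seed = 1) {
  abort_if(length(components_by_group) < 2 ||
             is.null(names(components_by_group)),
           "`components_by_group` must name both groups")
  abort_if(n_per_group < 2, "`n_per_group` must be >= 2")
  abort_if(fs_hz <= 0, "`fs_hz` must be > 0")
  abort_if(!is.null(n_trials_per_class) && n_trials_per_class < 1,
           "`n_trials_per_class` must be >= 1 (or NULL for all scheduled)")
  abort_if(!all(names(paradigms) %in% names(epoch_windows)),
           "every paradigm needs an epoch window")
  abort_if(is.null(names(channel_gains)),
           "`channel_gains` must be named by channel")
  structure(list(n_per_group = as.integer(n_per_group),
                 components_by_group = components_by_group,
                 channel_gains = channel_gains,
                 noise_sd_uV = noise_sd_uV,
                 n_trials_per_class = n_trials_per_class,
                 fs_hz = fs_hz, paradigms = paradigms,
                 epoch_windows = epoch_windows,
                 trial_amp_jitter_sd = trial_amp_jitter_sd,
                 trial_lat_jitter_ms = trial_lat_jitter_ms,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Ready-made cohort configuration for the planted-P300-deficit scenario
#'
#' Controls ("HC") carry N100/P200/N200/P300 (P300: 12 uV at 350 ms before
#' channel gains) and two MMN-window components; the "SZ" group has the P300
#' amplitude reduced by `p300_amp_reduction` and delayed by
#' `p300_latency_shift_ms` at Cz/Pz. Noise is calibrated so the averaged-ERP
#' P300 SNR is about `target_snr` (40 rare epochs per class).
#'
#' @param n_per_group subjects per group.
#' @param effect `"p300_deficit"` (planted group difference) or `"none"`
#'   (null cohort: both groups identical).
#' @param target_snr averaged-ERP component SNR the noise is calibrated to.
#' @param seed master seed.
#' @param ... passed on to [cohort_config()].
#' @param p300_amp_reduction fractional P300 amplitude reduction in SZ.
#' @param p300_latency_shift_ms P300 latency delay (ms) in SZ.
#' @return a `cohort_config`.
#' @export
default_cohort_config <- function(n_per_group = 30,
                                  effect = c("p300_deficit", "none"),
                                  target_snr = 2, seed = 1,
                                  p300_amp_reduction = 0.4,
                                  p300_latency_shift_ms = 30, ...) {
  effect <- match.arg(effect)
  comps <- list(
    HC = default_components("HC", effect),
    SZ = default_components("SZ", effect,
                            p300_amp_reduction = p300_amp_reduction,
                            p300_latency_shift_ms = p300_latency_shift_ms))
  cohort_config(n_per_group = n_per_group, components_by_group = comps,
                noise_sd_uV = calibrate_noise_sd(target_snr), seed = seed,
                ...)
}

# Continuous 3-channel recording for one subject and one paradigm:
# white noise + per-trial evoked templates inserted at event onsets.
simulate_subject_recording <- function(config, group, paradigm_name,
                                       seed = NULL) {
  spec <- config$paradigms[[paradigm_name]]
  window_ms <- config$epoch_windows[[paradigm_name]]
  comps_by_class <- config$components_by_group[[group]][[paradigm_name]]
  fs <- config$fs_hz
  channels <- names(config$channel_gains)
  with_seed(seed, {
    sched <- simulate_schedule(spec)
    subj_params <- lapply(comps_by_class, draw_component_params)
    lead_s <- abs(min(window_ms[1], 0)) / 1000 + 0.5
    tail_s <- max(window_ms[2], 0) / 1000 + 0.5
    n <- ceiling((lead_s + sched$total_duration_s + tail_s) * fs)
    x <- matrix(if (config$noise_sd_uV > 0)
                  rnorm(n * length(channels), 0, config$noise_sd_uV)
                else 0, n, length(channels),
                dimnames = list(NULL, channels))
    idx <- floor(window_ms[1] * fs / 1000):floor(window_ms[2] * fs / 1000)
    t_ms <- idx / fs * 1000
    events <- sched$events
    events$onset_s <- events$onset_s + lead_s
    for (e in seq_len(nrow(events))) {
      par0 <- subj_params[[events$label[e]]]
      if (is.null(par0) || length(par0) == 0) next
      par <- par0
      if (config$trial_amp_jitter_sd > 0 || config$trial_lat_jitter_ms > 0) {
        for (k in seq_along(par)) {
          if (config$trial_amp_jitter_sd > 0)
            par[[k]]$amplitude <- par[[k]]$amplitude *
              max(0, rnorm(1, 1, config$trial_amp_jitter_sd))
          if (config$trial_lat_jitter_ms > 0)
            par[[k]]$latency <- par[[k]]$latency +
              rnorm(1, 0, config$trial_lat_jitter_ms)
        }
      }
      restricted <- vapply(par, function(p) !is.null(p$channels), logical(1))
      w_shared <- template_from_params(par[!restricted], t_ms)
      onset_sample <- round(events$onset_s[e] * fs) + 1
      rows <- onset_sample + idx
      for (ch in channels) {
        w <- w_shared
        if (any(restricted))
          w <- w + template_from_params(par[restricted], t_ms, ch)
        x[rows, ch] <- x[rows, ch] + config$channel_gains[[ch]] * w
      }
    }
    structure(list(x = x, fs_hz = fs, events = events,
                   window_ms = window_ms, paradigm = paradigm_name,
                   schedule_total_s = sched$total_duration_s),
              class = "erp_recording")
  })
}

cohort_subject_table <- function(config) {
  groups <- names(config$components_by_group)
  data.frame(
    id = sprintf("S%03d", seq_len(2 * config$n_per_group)),
    group = rep(groups, each = config$n_per_group),
    stringsAsFactors = FALSE)
}

#' Simulate a two-group cohort of continuous recordings
#'
#' Every subject gets one continuous 3-channel recording per paradigm
#' (noise plus evoked templates at scheduled onsets). Reproducible: the
#' config seed is split deterministically per subject and paradigm, so the
#' same config yields bit-identical output. For large cohorts prefer
#' [build_cohort_erps()], which streams subjects through preprocessing
#' without keeping all recordings in memory.
#'
#' @param config a [cohort_config()].
#' @return `erp_cohort_recordings`: list with `subjects` (each holding
#'   `id`, `group`, `recordings` per paradigm) and `labels`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  tab <- cohort_subject_table(config)
  subjects <- lapply(seq_len(nrow(tab)), function(i) {
    sseed <- derive_seed(config$seed, i)
    recs <- lapply(seq_along(config$paradigms), function(j) {
      simulate_subject_recording(config, tab$group[i],
                                 names(config$paradigms)[j],
                                 seed = derive_seed(sseed, j))
    })
    names(recs) <- names(config$paradigms)
    list(id = tab$id[i], group = tab$group[i], recordings = recs)
  })
  structure(list(subjects = subjects, labels = tab$group,
                 config_hash = config_hash(unclass(config)[
                   c("n_per_group", "noise_sd_uV", "fs_hz", "seed")])),
            class = "erp_cohort_recordings")
}

#' Simulate and preprocess a cohort into averaged ERPs (streaming)
#'
#' Identical draws to [simulate_cohort()] (same per-subject seeds), but each
#' subject's recordings are preprocessed and discarded immediately, keeping
#' memory flat. Only the rare-class responses are retained by default, since
#' those are the inputs to feature extraction.
#'
#' @param config a [cohort_config()].
#' @param artifact_threshold_uV absolute-amplitude rejection threshold
#'   applied to epochs. Default `Inf`: the synthetic noise level needed for
#'   realistic averaged-ERP SNR makes a fixed 100 uV cut reject nearly all
#'   clean epochs, and the generator plants no artifacts unless asked.
#' @param classes `"rare"` (default) or `"all"` stimulus classes to retain.
#' @param verbose print per-subject progress.
#' @return `erp_cohort`: list with `subjects` (list of `subject_erp`),
#'   `labels`, `fs_hz`, `windows`, `seed`.
#' @export
build_cohort_erps <- function(config, artifact_threshold_uV = Inf,
                              classes = c("rare", "all"), verbose = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  classes <- match.arg(classes)
  tab <- cohort_subject_table(config)
  subjects <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    sseed <- derive_seed(config$seed, i)
    waves <- list()
    for (j in seq_along(config$paradigms)) {
      pname <- names(config$paradigms)[j]
      rec <- simulate_subject_recording(config, tab$group[i], pname,
                                        seed = derive_seed(sseed, j))
      keep <- if (classes == "rare") config$paradigms[[pname]]$rare_classes
              else config$paradigms[[pname]]$classes$label
      keep_n <- config$n_trials_per_class
      waves[[pname]] <- preprocess_recording(
        rec, classes = keep, artifact_threshold_uV = artifact_threshold_uV,
        max_epochs_per_class = keep_n)
    }
    subjects[[i]] <- structure(
      list(id = tab$id[i], group = tab$group[i], waveforms = waves,
           windows = config$epoch_windows[names(config$paradigms)],
           fs_hz = config$fs_hz),
      class = "subject_erp")
    if (verbose) message("subject ", tab$id[i], " (", tab$group[i], ") done")
  }
  structure(list(subjects = subjects, labels = tab$group,
                 fs_hz = config$fs_hz,
                 windows = config$epoch_windows[names(config$paradigms)],
                 seed = config$seed),
            class = "erp_cohort")
}

#' Write / read an averaged-ERP cohort as delimited text plus manifest
#'
#' One TSV per (subject, paradigm, stimulus class) with one column per
#' channel, and a JSON manifest recording sampling rate, windows, group
#' labels and seed. `read_cohort_erps()` restores the exact structure.
#'
#' @param cohort an `erp_cohort` from [build_cohort_erps()].
#' @param dir output directory (created if missing).
#' @return `write_cohort_erps()` the directory, invisibly;
#'   `read_cohort_erps()` an `erp_cohort`.
#' @export
write_cohort_erps <- function(cohort, dir) {
  stopifnot(inherits(cohort, "erp_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(fs_hz = cohort$fs_hz, windows = cohort$windows,
                   seed = cohort$seed, subjects = list())
  for (s in cohort$subjects) {
    files <- list()
    for (pname in names(s$waveforms)) {
      for (cls in names(s$waveforms[[pname]])) {
        fn <- sprintf("%s_%s_%s.tsv", s$id, pname, cls)
        write_numeric_tsv(s$waveforms[[pname]][[cls]], file.path(dir, fn))
        files[[pname]][[cls]] <- fn
      }
    }
    manifest$subjects[[length(manifest$subjects) + 1]] <-
      list(id = s$id, group = s$group, files = files)
  }
  write_json_file(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_cohort_erps
#' @export
read_cohort_erps <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  windows <- lapply(manifest$windows, function(w) unlist(w))
  subjects <- lapply(manifest$subjects, function(s) {
    waves <- lapply(s$files, function(pfiles) {
      lapply(pfiles, function(fn) {
        m <- as.matrix(read.table(file.path(dir, fn), header = TRUE,
                                  sep = "\t", check.names = FALSE))
        m
      })
    })
    structure(list(id = s$id, group = s$group, waveforms = waves,
                   windows = windows[names(waves)],
                   fs_hz = manifest$fs_hz),
              class = "subject_erp")
  })
  structure(list(subjects = subjects,
                 labels = vapply(manifest$subjects, function(s) s$group,
                                 character(1)),
                 fs_hz = manifest$fs_hz, windows = windows,
                 seed = manifest$seed),
            class = "erp_cohort")
}
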