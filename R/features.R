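PEAK_FEATURES <- c("Amplitude", "Latency", "absAmplitude", "Ratio",
                   "absRatio", "avgAbsSlope", "slopeSignChanges")
P2P_FEATURES <- c("ampDiff", "latDiff", "slope")
SIGNAL_FEATURES <- c("PositiveArea", "NegativeArea", "TotalArea",
                     "absTotalArea", "ZeroCrossing", "ZeroCrossDensity",
                     "ModeFreq", "MedianFreq", "MeanFreq", "RMS")

#' Peak search windows per paradigm
#'
#' Intervals (ms) around the average latency of each component, used to
#' locate peaks on averaged responses. The P300 paradigms carry four peaks
#' (N1, P2, N2, P3); the MMN paradigm carries two, addressed positionally
#' (`mmn1`, `mmn2`) because their naming is ambiguous in the field.
#'
#' @return nested named list: paradigm -> peak label -> `c(start, end)` ms.
#' @export
peak_window_table <- function() {
  p300 <- list(N1 = c(70, 160), P2 = c(150, 260), N2 = c(200, 330),
               P3 = c(280, 600))
  list(auditory_p300 = p300, visual_p300 = p300,
       mmn = list(mmn1 = c(100, 250), mmn2 = c(250, 450)))
}

#' Feature-table schema
#'
#' Enumerates the full column set: for every (paradigm, rare stimulus class,
#' channel), 7 features per peak, 3 per adjacent peak pair and 10
#' whole-signal features. With the default three paradigms this yields
#' 282 + 282 + 162 = 726 columns.
#'
#' @param paradigms named list of [paradigm_spec()] (rare classes are read
#'   from each spec).
#' @param channels channel names.
#' @param peaks named list: paradigm -> character vector of peak labels.
#' @return `feature_schema` with a `columns` data.frame (paradigm, stimulus,
#'   channel, peak, feature, name).
#' @export
feature_schema <- function(paradigms = default_paradigms(),
                           channels = CHANNELS,
                           peaks = lapply(peak_window_table(), names)) {
  abort_if(!all(names(paradigms) %in% names(peaks)),
           "every paradigm needs peak labels")
  rows <- list()
  for (pname in names(paradigms)) {
    pk <- peaks[[pname]]
    for (cls in paradigms[[pname]]$rare_classes) {
      for (ch in channels) {
        rows[[length(rows) + 1]] <- data.frame(
          paradigm = pname, stimulus = cls, channel = ch,
          peak = c(rep(pk, each = length(PEAK_FEATURES)),
                   if (length(pk) > 1)
                     rep(paste(pk[-length(pk)], pk[-1], sep = "-"),
                         each = length(P2P_FEATURES)),
                   rep("signal", length(SIGNAL_FEATURES))),
          feature = c(rep(PEAK_FEATURES, length(pk)),
                      if (length(pk) > 1)
                        rep(P2P_FEATURES, length(pk) - 1),
                      SIGNAL_FEATURES),
          stringsAsFactors = FALSE)
      }
    }
  }
  columns <- do.call(rbind, rows)
  columns$name <- with(columns, paste(paradigm, stimulus, channel, peak,
                                      feature, sep = "."))
  structure(list(paradigms = names(paradigms),
                 rare_classes = lapply(paradigms, function(p)
                   p$rare_classes),
                 channels = channels, peaks = peaks, columns = columns),
            class = "feature_schema")
}

#' Locate a peak as the largest absolute value in a window
#'
#' Ties are broken by the earliest sample; the amplitude keeps its sign.
#' `after_index` supports sequential peak picking: because neighbouring
#' search windows overlap, each peak is constrained to lie strictly after
#' the previously detected one, which keeps the peak sequence in increasing
#' latency order on noisy waveforms.
#'
#' @param waveform numeric vector.
#' @param t_ms sample times (ms) of the waveform.
#' @param window `c(start_ms, end_ms)` search interval.
#' @param after_index only samples after this index are searched (0 = all).
#' @return `peak_measurement`: `amplitude`, `latency_ms`, `index` (into the
#'   waveform).
#' @export
detect_peak <- function(waveform, t_ms, window, after_index = 0) {
  sel <- which(t_ms >= window[1] & t_ms <= window[2])
  sel <- sel[sel > after_index]
  abort_if(length(sel) == 0, "peak window [", window[1], ", ", window[2],
           "] ms is outside the epoch")
  i <- sel[which.max(abs(waveform[sel]))]
  structure(list(amplitude = waveform[i], latency_ms = t_ms[i],
                 index = i, window = window),
            class = "peak_measurement")
}

#' Seven peak-related features
#'
#' Amplitude (signed), latency, absolute amplitude, latency/amplitude ratio,
#' absolute ratio, average absolute slope within the search window, and the
#' number of slope sign changes within the window. A zero amplitude would
#' make the ratios undefined; they are set to 0 with a warning.
#'
#' @param pm a `peak_measurement` from [detect_peak()].
#' @param waveform,t_ms the waveform and its sample times (ms).
#' @return named numeric vector of length 7.
#' @export
peak_features <- function(pm, waveform, t_ms) {
  sel <- which(t_ms >= pm$window[1] & t_ms <= pm$window[2])
  seg <- waveform[sel]
  dt <- diff(t_ms[sel])
  dv <- diff(seg)
  if (pm$amplitude == 0) {
    warning("zero peak amplitude: ratio features set to 0", call. = FALSE)
    ratio <- 0
  } else ratio <- pm$latency_ms / pm$amplitude
  c(Amplitude = pm$amplitude, Latency = pm$latency_ms,
    absAmplitude = abs(pm$amplitude), Ratio = ratio, absRatio = abs(ratio),
    avgAbsSlope = if (length(dv)) mean(abs(dv) / dt) else 0,
    slopeSignChanges = count_sign_changes(dv))
}

count_sign_changes <- function(v) {
  v <- v[v != 0]
  if (length(v) < 2) return(0)
  sum(v[-1] * v[-length(v)] < 0)
}

#' Three peak-to-peak features for adjacent peaks
#'
#' Absolute amplitude difference, latency difference, and the signal slope
#' between the two peaks.
#'
#' @param pm_a,pm_b `peak_measurement`s with `pm_a$latency_ms <
#'   pm_b$latency_ms`.
#' @return named numeric vector of length 3.
#' @export
peak_to_peak_features <- function(pm_a, pm_b) {
  dl <- pm_b$latency_ms - pm_a$latency_ms
  abort_if(dl <= 0, "peaks must be in increasing latency order")
  da <- pm_b$amplitude - pm_a$amplitude
  c(ampDiff = abs(da), latDiff = dl, slope = da / dl)
}

#' Area features of a waveform
#'
#' Positive, negative (<= 0), total and absolute-total area, with
#' `dt = 1/fs` as the sample weight (units uV.s when `dt_s` is in seconds).
#'
#' @param waveform numeric vector.
#' @param dt_s sample spacing in seconds.
#' @return named numeric vector of length 4.
#' @export
area_features <- function(waveform, dt_s) {
  pos <- sum(pmax(waveform, 0)) * dt_s
  neg <- sum(pmin(waveform, 0)) * dt_s
  c(PositiveArea = pos, NegativeArea = neg, TotalArea = pos + neg,
    absTotalArea = sum(abs(waveform)) * dt_s)
}

#' Zero-crossing count and density between the first and last peak
#'
#' Counts strict sign changes between consecutive samples over the span from
#' the first to the last detected peak; density is the count divided by the
#' span duration in seconds. Spans shorter than 2 samples give `(0, 0)`.
#'
#' @param waveform numeric vector.
#' @param first_index,last_index sample indices of the outermost peaks.
#' @param dt_s sample spacing in seconds.
#' @return named numeric vector of length 2.
#' @export
zero_crossing_features <- function(waveform, first_index, last_index, dt_s) {
  abort_if(first_index > last_index, "need first_index <= last_index")
  span <- waveform[first_index:last_index]
  if (length(span) < 2) return(c(ZeroCrossing = 0, ZeroCrossDensity = 0))
  zc <- sum(span[-1] * span[-length(span)] < 0)
  c(ZeroCrossing = zc,
    ZeroCrossDensity = zc / ((last_index - first_index) * dt_s))
}

#' Spectral features from a periodogram restricted to the passband
#'
#' Raw periodogram of the mean-removed waveform, restricted to (0, 30] Hz
#' (the preprocessing suppresses everything above). Mode = bin with the
#' largest power (ties: lowest frequency), median = smallest frequency whose
#' cumulative power reaches half the total, mean = power-weighted mean
#' frequency. An all-zero waveform returns zeros.
#'
#' @param waveform numeric vector (length >= 8).
#' @param fs_hz sampling rate.
#' @param max_hz upper band edge.
#' @return named numeric vector: `ModeFreq`, `MedianFreq`, `MeanFreq`.
#' @export
spectral_features <- function(waveform, fs_hz, max_hz = 30) {
  n <- length(waveform)
  abort_if(n < 8, "waveform too short for spectral features")
  if (all(waveform == 0))
    return(c(ModeFreq = 0, MedianFreq = 0, MeanFreq = 0))
  v <- waveform - mean(waveform)
  spec <- Mod(fft(v))^2
  k <- seq_len(floor(n / 2))
  f <- k * fs_hz / n
  keep <- f <= max_hz
  f <- f[keep]
  p <- spec[k + 1][keep]
  tot <- sum(p)
  if (tot == 0) return(c(ModeFreq = 0, MedianFreq = 0, MeanFreq = 0))
  c(ModeFreq = f[which.max(p)],
    MedianFreq = f[which(cumsum(p) >= tot / 2)[1]],
    MeanFreq = sum(f * p) / tot)
}

#' Recenter peak search windows on a grand-average waveform
#'
#' Keeps each window's width but moves its center to the peak detected on
#' the supplied grand average (sequentially, like feature extraction), so
#' cohort-specific average latencies can replace the built-in defaults.
#'
#' @param waveform grand-average waveform (one channel).
#' @param t_ms its sample times (ms).
#' @param windows named list of `c(start, end)` windows in label order.
#' @return list of recentered windows with the same names and widths.
#' @export
recenter_peak_windows <- function(waveform, t_ms, windows) {
  out <- windows
  prev <- 0
  for (lab in names(windows)) {
    w <- windows[[lab]]
    pm <- detect_peak(waveform, t_ms, w, prev)
    half <- (w[2] - w[1]) / 2
    out[[lab]] <- c(pm$latency_ms - half, pm$latency_ms + half)
    prev <- pm$index
  }
  out
}

# All features for one waveform (one paradigm/class/channel).
# Peaks are picked sequentially (each strictly after the previous) so the
# latency order is guaranteed even where search windows overlap.
waveform_features <- function(waveform, t_ms, fs_hz, windows) {
  pk_labels <- names(windows)
  pms <- list()
  prev <- 0
  for (lab in pk_labels) {
    pms[[lab]] <- detect_peak(waveform, t_ms, windows[[lab]], prev)
    prev <- pms[[lab]]$index
  }
  out <- numeric(0)
  for (lab in pk_labels)
    out <- c(out, peak_features(pms[[lab]], waveform, t_ms))
  if (length(pms) > 1)
    for (i in seq_len(length(pms) - 1))
      out <- c(out, peak_to_peak_features(pms[[i]], pms[[i + 1]]))
  dt_s <- 1 / fs_hz
  first_i <- min(vapply(pms, function(p) p$index, numeric(1)))
  last_i <- max(vapply(pms, function(p) p$index, numeric(1)))
  c(out, area_features(waveform, dt_s),
    zero_crossing_features(waveform, first_i, last_i, dt_s),
    spectral_features(waveform, fs_hz),
    RMS = sqrt(mean(waveform^2)))
}

#' Build the subjects x features table from an averaged-ERP cohort
#'
#' Columns are enumerated deterministically: paradigm -> stimulus class ->
#' channel -> (peak features per peak, peak-to-peak per adjacent pair,
#' whole-signal block). With the default schema: 726 columns, split
#' 282 / 282 / 162 across the paradigms.
#'
#' @param cohort an `erp_cohort` (from [build_cohort_erps()] or
#'   [read_cohort_erps()]).
#' @param schema a [feature_schema()].
#' @param windows a [peak_window_table()]-style nested list.
#' @return `feature_table`: list with matrix `x` (named columns), `columns`
#'   data.frame, `labels`, and the schema.
#' @export
build_feature_table <- function(cohort, schema = feature_schema(),
                                windows = peak_window_table()) {
  subjects <- cohort$subjects
  cols <- schema$columns
  x <- matrix(NA_real_, length(subjects), nrow(cols),
              dimnames = list(vapply(subjects, function(s) s$id,
                                     character(1)),
                              cols$name))
  for (si in seq_along(subjects)) {
    s <- subjects[[si]]
    vals <- numeric(0)
    for (pname in schema$paradigms) {
      win <- s$windows[[pname]]
      fs <- s$fs_hz
      ew <- epoch_window(win[1], win[2], fs)
      for (cls in schema$rare_classes[[pname]]) {
        wave_m <- s$waveforms[[pname]][[cls]]
        abort_if(is.null(wave_m), "subject ", s$id, " is missing ", pname,
                 "/", cls)
        for (ch in schema$channels) {
          abort_if(!(ch %in% colnames(wave_m)), "subject ", s$id,
                   " is missing channel ", ch, " for ", pname, "/", cls)
          vals <- c(vals, waveform_features(wave_m[, ch], ew$t_ms, fs,
                                            windows[[pname]]))
        }
      }
    }
    x[si, ] <- vals
  }
  structure(list(x = x, columns = cols,
                 labels = vapply(subjects, function(s) s$group,
                                 character(1)),
                 schema = schema),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$x), "subjects x", ncol(x$x), "features\n")
  cat("paradigm split:",
      paste(names(table(x$columns$paradigm)),
            table(x$columns$paradigm), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a feature table (TSV + JSON schema sidecar)
#'
#' Lossless round trip: values are written with 15 significant digits and
#' the sidecar restores column metadata and labels.
#'
#' @param ft a `feature_table`.
#' @param path TSV path; the sidecar is `<path>.schema.json`.
#' @return `write_feature_table()` the path, invisibly;
#'   `read_feature_table()` a `feature_table`.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  df <- cbind(data.frame(subject = rownames(ft$x), label = ft$labels,
                         stringsAsFactors = FALSE),
              as.data.frame(ft$x, check.names = FALSE))
  write_numeric_tsv(df, path)
  write_json_file(list(columns = ft$columns,
                       paradigms = ft$schema$paradigms,
                       channels = ft$schema$channels,
                       peaks = ft$schema$peaks,
                       rare_classes = ft$schema$rare_classes),
                  paste0(path, ".schema.json"))
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  side <- read_json_file(paste0(path, ".schema.json"))
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(x) <- df$subject
  schema <- structure(list(paradigms = side$paradigms,
                           rare_classes = side$rare_classes,
                           channels = side$channels, peaks = side$peaks,
                           columns = side$columns),
                      class = "feature_schema")
  structure(list(x = x, columns = side$columns, labels = df$label,
                 schema = schema),
            class = "feature_table")
}
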