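test_that("default schema enumerates 726 named columns with the right
           paradigm split", {
  sch <- feature_schema()
  expect_identical(nrow(sch$columns), 726L)
  split <- table(sch$columns$paradigm)
  expect_identical(unname(split[c("auditory_p300", "visual_p300", "mmn")]),
                   c(282L, 282L, 162L), ignore_attr = TRUE)
  expect_false(any(duplicated(sch$columns$name)))
  # restricted schemas follow 6 * (7P + 3(P-1) + 10) without hard-coding
  mmn_only <- feature_schema(paradigms = default_paradigms()["mmn"],
                             peaks = list(mmn = c("mmn1", "mmn2")))
  expect_identical(nrow(mmn_only$columns), 162L)
  single <- feature_schema(paradigms = list(auditory_p300 = mini_paradigm()),
                           channels = "Cz",
                           peaks = list(auditory_p300 = c("a", "b", "c")))
  expect_identical(nrow(single$columns), 7L * 3L + 3L * 2L + 10L)
})

test_that("detect_peak matches a brute-force scan and keeps sign", {
  set.seed(8)
  t_ms <- seq(-200, 800, length.out = 257)
  for (i in 1:20) {
    w <- rnorm(257)
    win <- sort(runif(2, -150, 750))
    sel <- which(t_ms >= win[1] & t_ms <= win[2])
    if (length(sel) == 0) next
    pm <- detect_peak(w, t_ms, win)
    j <- sel[which.max(abs(w[sel]))]
    expect_identical(pm$index, j)
    expect_identical(pm$amplitude, w[j])
  }
  # sign symmetry: a negated bump has negative amplitude, same latency
  g <- exp(-(t_ms - 180)^2 / (2 * 25^2))
  up <- detect_peak(g, t_ms, c(100, 260))
  dn <- detect_peak(-g, t_ms, c(100, 260))
  expect_equal(dn$amplitude, -up$amplitude)
  expect_equal(dn$latency_ms, up$latency_ms)
  # ties break to the earliest sample
  flat <- rep(c(0, 1, 1, 0), each = 10)
  tm <- seq_along(flat)
  expect_identical(detect_peak(flat, tm, c(1, 40))$index, 11L)
  expect_error(detect_peak(g, t_ms, c(900, 1000)), "outside")
})

test_that("peak features follow their closed forms", {
  t_ms <- seq(0, 400, by = 4)
  ramp <- t_ms / 30 # peak value 400/30 at the end; use window to get 10@300
  pm <- detect_peak(ramp, t_ms, c(0, 300))
  expect_equal(pm$amplitude, 10)
  expect_equal(pm$latency_ms, 300)
  f <- peak_features(pm, ramp, t_ms)
  expect_equal(unname(f["Ratio"]), 30) # 300 ms / 10 uV
  expect_equal(unname(f["absRatio"]), 30)
  expect_equal(unname(f["avgAbsSlope"]), 1 / 30)
  expect_equal(unname(f["slopeSignChanges"]), 0) # monotone
  # a full sine period has two slope sign changes
  ts <- seq(0, 1000, by = 4)
  s <- sin(2 * pi * ts / 1000)
  pms <- detect_peak(s, ts, c(0, 1000))
  fs <- peak_features(pms, s, ts)
  expect_equal(unname(fs["slopeSignChanges"]), 2)
  # zero amplitude: ratios fall back to 0 with a warning
  z <- rep(0, 11)
  pmz <- detect_peak(z, 0:10, c(0, 10))
  expect_warning(fz <- peak_features(pmz, z, 0:10), "zero peak")
  expect_equal(unname(fz[c("Ratio", "absRatio")]), c(0, 0))
})

test_that("peak-to-peak features equal the direct formulas", {
  pa <- structure(list(amplitude = -5, latency_ms = 100, index = 1),
                  class = "peak_measurement")
  pb <- structure(list(amplitude = 10, latency_ms = 300, index = 2),
                  class = "peak_measurement")
  expect_equal(peak_to_peak_features(pa, pb),
               c(ampDiff = 15, latDiff = 200, slope = 0.075))
  pb$amplitude <- -5
  expect_equal(unname(peak_to_peak_features(pa, pb)[c("ampDiff", "slope")]),
               c(0, 0))
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(1); b <- rnorm(1); l <- sort(runif(2, 0, 500))
    pa$amplitude <- a; pa$latency_ms <- l[1]
    pb$amplitude <- b; pb$latency_ms <- l[2]
    got <- peak_to_peak_features(pa, pb)
    expect_equal(unname(got), c(abs(b - a), l[2] - l[1],
                                (b - a) / (l[2] - l[1])))
  }
  pb$latency_ms <- pa$latency_ms
  expect_error(peak_to_peak_features(pa, pb), "latency order")
})

test_that("area and zero-crossing features are exact on constructed
           signals", {
  n <- 100
  dt <- 1 / n
  expect_equal(area_features(rep(1, n), dt),
               c(PositiveArea = 1, NegativeArea = 0, TotalArea = 1,
                 absTotalArea = 1))
  odd <- sin(2 * pi * seq(0, 1 - dt, by = dt))
  a <- area_features(odd, dt)
  expect_equal(unname(a["TotalArea"]), 0, tolerance = 1e-12)
  expect_equal(unname(a["absTotalArea"]), 2 * unname(a["PositiveArea"]))
  set.seed(6)
  r <- rnorm(77)
  ar <- area_features(r, 1 / 256)
  expect_equal(unname(ar["absTotalArea"]),
               unname(ar["PositiveArea"] - ar["NegativeArea"]))

  expect_equal(zero_crossing_features(abs(r) + 1, 5, 70, dt),
               c(ZeroCrossing = 0, ZeroCrossDensity = 0))
  # peak-to-peak span covering two full periods: 4 zero crossings
  two_periods <- cos(2 * pi * 2 * seq(0, 1, length.out = 201))
  zc <- zero_crossing_features(two_periods, 1, 201, dt)
  expect_equal(unname(zc["ZeroCrossing"]), 4)
  flip <- c(rep(1, 10), rep(-1, 10))
  zf <- zero_crossing_features(flip, 1, 20, 0.01)
  expect_equal(unname(zf), c(1, 1 / (19 * 0.01)))
})

test_that("spectral features agree with a direct DFT", {
  fs <- 256
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  tone <- sin(2 * pi * 10 * t)
  sf <- spectral_features(tone, fs)
  expect_equal(unname(sf["ModeFreq"]), 10) # exact bin at 1 s window
  expect_equal(unname(sf["MedianFreq"]), 10)
  expect_equal(unname(sf["MeanFreq"]), 10, tolerance = 0.2)
  mix <- sin(2 * pi * 5 * t) + sin(2 * pi * 15 * t)
  sm <- spectral_features(mix, fs)
  expect_equal(unname(sm["MeanFreq"]), 10, tolerance = 1) # one bin width
  # against the quadratic-time DFT oracle on a short random signal
  set.seed(9)
  x <- rnorm(64)
  p_oracle <- dft_power(x - mean(x))
  f <- seq_len(32) * fs / 64
  keep <- f <= 30
  want_mode <- f[keep][which.max(p_oracle[keep])]
  got <- spectral_features(x, fs)
  expect_equal(unname(got["ModeFreq"]), want_mode)
  expect_equal(unname(got["MeanFreq"]),
               sum(f[keep] * p_oracle[keep]) / sum(p_oracle[keep]),
               tolerance = 1e-8)
  expect_equal(unname(spectral_features(rep(0, 64), fs)), c(0, 0, 0))
})

test_that("feature tables are deterministic, order-invariant and
           round-trip", {
  cfg <- mini_cohort_config(n_per_group = 2, noise_sd = 2, seed = 21)
  coh <- build_cohort_erps(cfg)
  sch <- feature_schema(paradigms = list(auditory_p300 = mini_paradigm()),
                        peaks = list(auditory_p300 = c("N1", "P3")))
  wins <- list(auditory_p300 = list(N1 = c(50, 200), P3 = c(200, 500)))
  ft <- build_feature_table(coh, sch, wins)
  expect_identical(dim(ft$x), c(4L, nrow(sch$columns)))
  expect_false(any(is.na(ft$x)))
  # subject order does not change per-subject values
  coh_rev <- coh
  coh_rev$subjects <- rev(coh$subjects)
  ft_rev <- build_feature_table(coh_rev, sch, wins)
  expect_equal(ft_rev$x[4, ], ft$x[1, ])
  # lossless text round trip
  path <- tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(back$x, ft$x, tolerance = 1e-12)
  expect_identical(back$labels, ft$labels)
  expect_identical(back$columns$name, ft$columns$name)
  unlink(c(path, paste0(path, ".schema.json")))
})

test_that("peak windows recenter on a grand average", {
  cos2 <- list(component_spec("N100", -1, 120, 0, 5, 0, 15),
               component_spec("P300", +1, 420, 0, 12, 0, 30))
  w <- erp_template(cos2, c(-200, 800), 256)
  t_ms <- attr(w, "t_ms")
  old <- list(N1 = c(70, 160), P3 = c(280, 600))
  new <- recenter_peak_windows(w, t_ms, old)
  expect_equal(mean(new$N1), 120, tolerance = 1000 / 256)
  expect_equal(mean(new$P3), 420, tolerance = 1000 / 256)
  expect_equal(diff(new$N1), diff(old$N1))
  expect_equal(diff(new$P3), diff(old$P3))
})

test_that("missing waveforms are reported with their address", {
  cfg <- mini_cohort_config(n_per_group = 2, seed = 2)
  coh <- build_cohort_erps(cfg)
  sch <- feature_schema(paradigms = list(auditory_p300 = mini_paradigm()),
                        peaks = list(auditory_p300 = c("N1", "P3")))
  wins <- list(auditory_p300 = list(N1 = c(50, 200), P3 = c(200, 500)))
  coh$subjects[[2]]$waveforms$auditory_p300$Target <- NULL
  expect_error(build_feature_table(coh, sch, wins), "S002.*Target")
})
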