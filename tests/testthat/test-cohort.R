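test_that("erp_template places Gaussian components analytically", {
  co <- component_spec("P300", +1, 300, 0, 10, 0, 45)
  w <- erp_template(list(co), c(-200, 800), 256)
  t_ms <- attr(w, "t_ms")
  i <- which.max(w)
  expect_equal(t_ms[i], t_ms[which.min(abs(t_ms - 300))])
  expect_equal(max(w), 10, tolerance = 1e-3) # grid point near 300 ms
  # two well-separated components recovered by detect_peak within 1%
  cos2 <- list(component_spec("N100", -1, 100, 0, 5, 0, 15),
               component_spec("P300", +1, 400, 0, 12, 0, 30))
  w2 <- erp_template(cos2, c(-200, 800), 256)
  p1 <- detect_peak(w2, attr(w2, "t_ms"), c(50, 200))
  p2 <- detect_peak(w2, attr(w2, "t_ms"), c(300, 500))
  expect_equal(p1$amplitude, -5, tolerance = 0.01)
  expect_equal(p2$amplitude, 12, tolerance = 0.01)
  expect_lt(abs(p1$latency_ms - 100), 1000 / 256)
  expect_lt(abs(p2$latency_ms - 400), 1000 / 256)
})

test_that("empty or zero-amplitude component lists give zero waveforms", {
  expect_true(all(erp_template(list(), c(-100, 500), 256) == 0))
  co <- component_spec("x", 1, 200, 0, 0, 0, 30)
  expect_true(all(erp_template(list(co), c(-100, 500), 256) == 0))
})

test_that("zero-noise deterministic cohort returns the template through the
           full preprocessing chain", {
  cfg <- deterministic_config(n_per_group = 2, seed = 7)
  coh <- build_cohort_erps(cfg)
  s <- coh$subjects[[1]]
  tmpl <- erp_template(cfg$components_by_group$HC$auditory_p300$Target,
                       c(-200, 800), 256)
  for (ch in c("Fz", "Cz", "Pz")) {
    got <- s$waveforms$auditory_p300$Target[, ch]
    want <- cfg$channel_gains[[ch]] * tmpl
    # equality up to bandpass edge effects (0.1 Hz highpass slightly bends
    # slow components)
    expect_lt(max(abs(got - want)), 0.05 * max(abs(want)))
  }
})

test_that("cohort generation is a pure function of the config seed", {
  cfg <- mini_cohort_config(noise_sd = 5, seed = 9)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$subjects[[1]]$recordings$auditory_p300$x,
                   c2$subjects[[1]]$recordings$auditory_p300$x)
  # streamed ERPs use the same per-subject seeds as the raw simulator
  e1 <- build_cohort_erps(cfg)
  e2 <- build_cohort_erps(cfg)
  expect_identical(e1$subjects[[2]]$waveforms, e2$subjects[[2]]$waveforms)
})

test_that("a planted 50% P300 amplitude reduction is recovered in the group
           means", {
  # Monte-Carlo over 50 + 50 subjects on a short session; subject-level
  # amplitude sd 1, no measurement noise
  cfg <- cohort_config(
    n_per_group = 50,
    components_by_group = list(
      HC = list(auditory_p300 = mini_components(amp = 10, amp_sd = 1)),
      SZ = list(auditory_p300 = mini_components(amp = 5, amp_sd = 1))),
    noise_sd_uV = 0,
    paradigms = list(auditory_p300 = mini_paradigm(20)),
    epoch_windows = list(auditory_p300 = c(-200, 800)),
    trial_amp_jitter_sd = 0, trial_lat_jitter_ms = 0, seed = 31)
  coh <- build_cohort_erps(cfg)
  amp <- vapply(coh$subjects, function(s) {
    w <- s$waveforms$auditory_p300$Target[, "Cz"]
    ew <- epoch_window(-200, 800, 256)
    detect_peak(w, ew$t_ms, c(200, 450))$amplitude
  }, numeric(1))
  m_hc <- mean(amp[coh$labels == "HC"])
  m_sz <- mean(amp[coh$labels == "SZ"])
  expect_equal((m_hc - m_sz) / m_hc, 0.5, tolerance = 0.1)
})

test_that("cohort config validation catches bad inputs", {
  expect_error(mini_cohort_config(n_per_group = 1), "n_per_group")
  expect_error(mini_cohort_config(n_trials_per_class = 0),
               "n_trials_per_class")
})

test_that("averaged-ERP cohorts round-trip through the text format", {
  cfg <- mini_cohort_config(n_per_group = 2, noise_sd = 3, seed = 5)
  coh <- build_cohort_erps(cfg)
  dir <- tempfile("cohort")
  write_cohort_erps(coh, dir)
  back <- read_cohort_erps(dir)
  expect_identical(back$labels, coh$labels)
  expect_equal(back$subjects[[1]]$waveforms$auditory_p300$Target,
               coh$subjects[[1]]$waveforms$auditory_p300$Target,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$subjects[[3]]$group, "SZ")
  unlink(dir, recursive = TRUE)
})

test_that("noise calibration hits the averaged-ERP SNR it promises", {
  # pure-noise cohort at the calibrated level: residual sd on the averaged
  # ERP should be about amplitude / SNR
  cfg <- default_cohort_config(n_per_group = 2, effect = "none", seed = 33)
  for (g in names(cfg$components_by_group))
    for (p in names(cfg$components_by_group[[g]]))
      for (cl in names(cfg$components_by_group[[g]][[p]]))
        cfg$components_by_group[[g]][[p]][[cl]] <- lapply(
          cfg$components_by_group[[g]][[p]][[cl]],
          function(co) {
            co$mean_amplitude_uV <- 0
            co$amplitude_sd_uV <- 0
            co
          })
  coh <- build_cohort_erps(cfg)
  w <- coh$subjects[[1]]$waveforms$auditory_p300$Target
  snr <- 12 / sd(w[, "Cz"])
  expect_equal(snr, 2, tolerance = 0.35)
})
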