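# Shared fixtures. The expensive acceptance cohorts are built lazily once
# per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# short single-paradigm setup for fast simulator tests
mini_paradigm <- function(n_stimuli = 30) {
  paradigm_spec("auditory_p300",
                data.frame(label = c("Target", "Standard"),
                           proportion = c(0.3, 0.7),
                           duration_ms = c(100, 100)),
                isi_ms = c(300, 400), n_stimuli = n_stimuli,
                rare_classes = "Target")
}

mini_components <- function(amp = 10, lat = 300, amp_sd = 0, lat_sd = 0) {
  list(Target = list(component_spec("P300", +1, lat, lat_sd, amp, amp_sd,
                                    45)),
       Standard = list())
}

mini_cohort_config <- function(n_per_group = 2, noise_sd = 0, seed = 1,
                               sz_amp = 10, n_stimuli = 30, ...) {
  cohort_config(
    n_per_group = n_per_group,
    components_by_group = list(HC = list(auditory_p300 = mini_components()),
                               SZ = list(auditory_p300 =
                                           mini_components(amp = sz_amp))),
    noise_sd_uV = noise_sd,
    paradigms = list(auditory_p300 = mini_paradigm(n_stimuli)),
    epoch_windows = list(auditory_p300 = c(-200, 800)),
    trial_amp_jitter_sd = 0, trial_lat_jitter_ms = 0, seed = seed, ...)
}

# deterministic components (all sds zero) on the full default config
deterministic_config <- function(n_per_group = 2, seed = 1) {
  cfg <- default_cohort_config(n_per_group = n_per_group, effect = "none",
                               seed = seed)
  cfg$noise_sd_uV <- 0
  cfg$trial_amp_jitter_sd <- 0
  cfg$trial_lat_jitter_ms <- 0
  for (g in names(cfg$components_by_group))
    for (p in names(cfg$components_by_group[[g]]))
      for (cl in names(cfg$components_by_group[[g]][[p]]))
        cfg$components_by_group[[g]][[p]][[cl]] <- lapply(
          cfg$components_by_group[[g]][[p]][[cl]],
          function(co) {
            co$latency_sd_ms <- 0
            co$amplitude_sd_uV <- 0
            co
          })
  cfg
}

# acceptance-scale cohorts (30 + 30 subjects, full Table-2-style sessions)
acceptance_ft_informative <- function() cached("ft_inf", function() {
  cfg <- default_cohort_config(n_per_group = 30, effect = "p300_deficit",
                               seed = 101)
  build_feature_table(build_cohort_erps(cfg))
})

acceptance_ft_null <- function() cached("ft_null", function() {
  cfg <- default_cohort_config(n_per_group = 30, effect = "none",
                               seed = 202)
  build_feature_table(build_cohort_erps(cfg))
})

# reduced hyperparameter grid used by the long-running acceptance runs to
# stay inside the test-time budget (scaling down compute, not the cohort)
acceptance_cv_config <- function(seed = 5, ...) {
  cv_config(C_grid = c(0.5, 1.5, 10), sigma_grid = c(5, 1),
            kernels = c("linear", "gaussian"), seed = seed, ...)
}

# small synthetic feature_table with valid schema metadata for CV tests
make_mini_ft <- function(seed = 1, n = 24, d = 2) {
  schema <- feature_schema(
    paradigms = list(auditory_p300 = mini_paradigm()),
    channels = c("Fz", "Cz"),
    peaks = list(auditory_p300 = c("N1", "P3")))
  set.seed(seed)
  p <- nrow(schema$columns)
  labels <- rep(c("HC", "SZ"), each = n / 2)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, schema$columns$name))
  x[, 1:4] <- x[, 1:4] + ifelse(labels == "SZ", d / 2, -d / 2)
  structure(list(x = x, columns = schema$columns, labels = labels,
                 schema = schema),
            class = "feature_table")
}
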