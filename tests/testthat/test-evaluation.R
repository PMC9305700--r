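test_that("stratified folds balance classes and sizes", {
  labels <- rep(c("SZ", "HC"), each = 54)
  f <- stratified_kfold(labels, 10, seed = 4)
  sizes <- table(f)
  expect_true(all(sizes %in% c(10, 11)))
  per_class <- table(f, labels)
  expect_true(all(per_class >= 5 & per_class <= 6))
  expect_identical(sort(unique(f)), 1:10)
  expect_identical(f, stratified_kfold(labels, 10, seed = 4))
  # leave-one-out degenerates to singleton folds
  small <- rep(c("a", "b"), 3)
  loo <- stratified_kfold(small, 3, seed = 1)
  expect_true(all(table(loo) == 2))
  expect_error(stratified_kfold(c("a", "a", "b"), 2, seed = 1),
               "at least k")
})

test_that("kernel groupings cover the schema in each mode", {
  sch <- feature_schema()
  gp <- group_columns(sch, "paradigm")
  expect_identical(lengths(gp)[c("auditory_p300", "visual_p300", "mmn")],
                   c(auditory_p300 = 282L, visual_p300 = 282L, mmn = 162L))
  gc <- group_columns(sch, "channel")
  expect_true(all(lengths(gc) == 242L))
  gt <- group_columns(sch, "feature_type")
  expect_identical(sort(unname(unlist(gt))), sort(sch$columns$name))
  expect_identical(names(gt), c("LatencyAmplitude", "Morphological",
                                "Frequency"))
  # after selection to auditory/visual-only features, the MMN group drops
  sel <- sch$columns$name[c(1:6, 290)]
  expect_warning(g7 <- group_columns(sch, "paradigm", selected = sel),
                 "mmn")
  expect_identical(lengths(g7), c(auditory_p300 = 6L, visual_p300 = 1L))
})

test_that("metrics follow their confusion-matrix definitions", {
  y <- c(1, 1, 1, -1, -1, -1)
  perfect <- compute_metrics(y, c(2, 1, 3, -1, -2, -0.5))
  expect_equal(unlist(perfect[c("acc", "sen", "spe", "auc")]),
               c(acc = 1, sen = 1, spe = 1, auc = 1))
  allpos <- compute_metrics(y, rep(1, 6))
  expect_equal(allpos$sen, 1)
  expect_equal(allpos$spe, 0)
  expect_equal(allpos$auc, 0.5) # all tied: ranks give 1/2
  # label-independent scores give AUC ~ 0.5 over random draws
  set.seed(19)
  aucs <- replicate(300, compute_metrics(sample(y), rnorm(6))$auc)
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
  expect_warning(m1 <- compute_metrics(c(1, 1), c(0.3, -2)), "single-class")
  expect_true(is.na(m1$auc))
})

test_that("nested CV separates a planted signal, audits leakage and is
           reproducible", {
  ft <- make_mini_ft(seed = 44, n = 24, d = 2.5)
  cfg <- cv_config(outer_k = 4, inner_k = 2, C_grid = c(1),
                   kernels = "linear", feature_selection = FALSE,
                   grouping_mode = "channel", seed = 8)
  rep1 <- nested_cv(ft, cfg)
  expect_gt(rep1$mean$acc, 0.7)
  # per-fold audit: scaler fitted on the training rows only
  for (f in seq_along(rep1$audit)) {
    a <- rep1$audit[[f]]
    expect_length(intersect(a$train, a$test), 0)
    expect_identical(a$scaler_n, length(a$train))
  }
  expect_identical(sort(unlist(lapply(rep1$audit, `[[`, "test"))),
                   seq_len(nrow(ft$x)))
  # averaged metrics reproduce the fold table
  expect_equal(rep1$mean$acc, mean(rep1$folds$acc))
  expect_equal(rep1$mean$auc, mean(rep1$folds$auc))
  rep2 <- nested_cv(ft, cfg)
  expect_identical(rep1$folds, rep2$folds)
})

test_that("hyperparameter selection follows the documented tie-break
           order", {
  cfg <- cv_config(C_grid = c(1, 0.5), sigma_grid = c(1, 5),
                   degree_grid = c(3, 2),
                   kernels = c("gaussian", "linear", "polynomial"))
  grid <- erpmkl:::expand_grid_configs(cfg)
  labs <- vapply(grid, function(g)
    paste(g$C, erpmkl:::kernel_param_label(g$spec)), character(1))
  expect_identical(labs[1:4], c("0.5 linear", "0.5 polynomial(q=2)",
                                "0.5 polynomial(q=3)", "0.5 gaussian(s=5)"))
  expect_identical(labs[5], "0.5 gaussian(s=1)")
  expect_identical(labs[6], "1 linear")
})

test_that("feature selection inside CV falls back when nothing is
           accepted", {
  ft <- make_mini_ft(seed = 45, n = 24, d = 0) # no signal at all
  cfg <- cv_config(outer_k = 2, inner_k = 2, C_grid = 1,
                   kernels = "linear", feature_selection = TRUE,
                   grouping_mode = "channel", seed = 3)
  bcfg <- boruta_config(max_runs = 10, ntree = 50)
  w <- capture_warnings(repn <- nested_cv(ft, cfg, bcfg))
  expect_true(any(grepl("falling back", w)))
  expect_identical(unique(repn$folds$n_selected), ncol(ft$x))
})

test_that("CV reports export to text", {
  ft <- make_mini_ft(seed = 46)
  cfg <- cv_config(outer_k = 3, inner_k = 2, C_grid = 1,
                   kernels = "linear", feature_selection = FALSE,
                   grouping_mode = "channel", seed = 2)
  repn <- nested_cv(ft, cfg)
  prefix <- tempfile("cv")
  export_cv_report(repn, prefix)
  folds <- read.table(paste0(prefix, "_folds.tsv"), header = TRUE,
                      sep = "\t")
  expect_identical(nrow(folds), 3L)
  summ <- jsonlite::read_json(paste0(prefix, "_summary.json"),
                              simplifyVector = TRUE)
  expect_equal(summ$mean$acc, repn$mean$acc, tolerance = 1e-12)
  unlink(paste0(prefix, c("_folds.tsv", "_summary.json")))
})
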