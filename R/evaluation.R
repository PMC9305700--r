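#' Configure nested cross-validation
#'
#' @param outer_k outer folds for error estimation (default 10).
#' @param inner_k inner folds for hyperparameter tuning (default 5).
#' @param C_grid soft-margin costs searched.
#' @param sigma_grid Gaussian widths searched.
#' @param degree_grid polynomial degrees searched.
#' @param kernels kernel kinds searched.
#' @param grouping_mode how columns are split into kernel groups:
#'   `"paradigm"`, `"channel"` or `"feature_type"`.
#' @param feature_selection run Boruta on each outer-training set.
#' @param p_norm MKL weight-norm order.
#' @param scaling `"per_fold"` (standard leakage hygiene) or `"global"`
#'   (single scaler on all rows; ablation only).
#' @param seed master seed; folds and selection get derived sub-seeds.
#' @return `cv_config`.
#' @export
cv_config <- function(outer_k = 10, inner_k = 5,
                      C_grid = c(0.5, 1, 1.5, 5, 10),
                      sigma_grid = c(10, 5, 1, 0.25, 0.5, 0.75),
                      degree_grid = c(2, 3),
                      kernels = c("linear", "polynomial", "gaussian"),
                      grouping_mode = c("paradigm", "channel",
                                        "feature_type"),
                      feature_selection = TRUE, p_norm = 2,
                      scaling = c("per_fold", "global"), seed = 1) {
  abort_if(outer_k < 2 || inner_k < 2, "fold counts must be >= 2")
  abort_if(length(C_grid) == 0 || length(kernels) == 0,
           "grids must be non-empty")
  structure(list(outer_k = as.integer(outer_k),
                 inner_k = as.integer(inner_k),
                 C_grid = sort(C_grid), sigma_grid = sigma_grid,
                 degree_grid = sort(degree_grid), kernels = kernels,
                 grouping_mode = match.arg(grouping_mode),
                 feature_selection = isTRUE(feature_selection),
                 p_norm = p_norm, scaling = match.arg(scaling),
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Stratified k-fold assignment
#'
#' Shuffles each class (seeded) and deals members so that every fold's class
#' count is within one of `n_class / k`; the leftover members are spread to
#' the currently smallest folds, keeping total fold sizes within one of each
#' other across classes.
#'
#' @param labels class labels.
#' @param k number of folds (every class needs >= k members).
#' @param seed integer seed.
#' @return integer fold id (1..k) per row.
#' @export
stratified_kfold <- function(labels, k, seed = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  tab <- table(labels)
  abort_if(any(tab < k), "every class needs at least k members (k = ", k,
           ")")
  with_seed(seed, {
    fold <- integer(length(labels))
    load <- integer(k)
    for (cls in classes) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      base <- length(idx) %/% k
      extra <- length(idx) %% k
      counts <- rep(base, k)
      if (extra > 0) {
        take <- order(load, sample.int(k))[seq_len(extra)]
        counts[take] <- counts[take] + 1L
      }
      fold[idx] <- rep(seq_len(k), counts)
      load <- load + counts
    }
    fold
  })
}

FEATURE_TYPE_MAP <- c(
  Amplitude = "LatencyAmplitude", Latency = "LatencyAmplitude",
  absAmplitude = "LatencyAmplitude", Ratio = "LatencyAmplitude",
  absRatio = "LatencyAmplitude",
  avgAbsSlope = "Morphological", slopeSignChanges = "Morphological",
  ampDiff = "Morphological", latDiff = "Morphological",
  slope = "Morphological", PositiveArea = "Morphological",
  NegativeArea = "Morphological", TotalArea = "Morphological",
  absTotalArea = "Morphological", ZeroCrossing = "Morphological",
  ZeroCrossDensity = "Morphological", RMS = "Morphological",
  ModeFreq = "Frequency", MedianFreq = "Frequency", MeanFreq = "Frequency")

#' Split feature columns into kernel groups
#'
#' Three grouping modes: by paradigm, by channel, or by feature type
#' (latency & amplitude / morphological / frequency). Groups that end up
#' empty after feature selection are dropped with a warning, reducing the
#' number of kernels.
#'
#' @param columns the `columns` data.frame of a [feature_schema()] (or a
#'   `feature_table`).
#' @param mode grouping mode.
#' @param selected optional subset of column names to cover (default: all).
#' @return named list of column-name vectors (`kernel_grouping`).
#' @export
group_columns <- function(columns, mode = c("paradigm", "channel",
                                            "feature_type"),
                          selected = NULL) {
  mode <- match.arg(mode)
  if (inherits(columns, "feature_table")) columns <- columns$columns
  if (inherits(columns, "feature_schema")) columns <- columns$columns
  # the full grouping domain, before any selection, so dropped groups are
  # detected and warned about
  ord <- switch(mode,
                paradigm = unique(columns$paradigm),
                channel = unique(columns$channel),
                feature_type = c("LatencyAmplitude", "Morphological",
                                 "Frequency"))
  if (!is.null(selected)) {
    abort_if(!all(selected %in% columns$name),
             "`selected` contains unknown columns")
    columns <- columns[columns$name %in% selected, , drop = FALSE]
  }
  key <- switch(mode,
                paradigm = columns$paradigm,
                channel = columns$channel,
                feature_type = unname(FEATURE_TYPE_MAP[columns$feature]))
  groups <- split(columns$name, key)
  groups <- groups[intersect(ord, names(groups))]
  empty <- setdiff(ord, names(groups))
  if (length(empty))
    warning("empty kernel group(s) dropped: ",
            paste(empty, collapse = ", "), call. = FALSE)
  groups
}

#' Classification metrics from decision values
#'
#' SZ (+1) is the positive class. Sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), accuracy = (TP+TN)/n, and AUC is the Mann-Whitney rank
#' statistic of the decision values (ties counted half). A single-class
#' fold gets `AUC = NA` with a warning.
#'
#' @param labels true labels (+-1 or two-level).
#' @param decision numeric decision values (larger = more SZ-like).
#' @return named list: confusion counts and `acc`, `sen`, `spe`, `auc`.
#' @export
compute_metrics <- function(labels, decision) {
  y <- encode_labels(labels)
  pred <- ifelse(decision >= 0, 1, -1)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == -1)
  tn <- sum(pred == -1 & y == -1)
  fn <- sum(pred == -1 & y == 1)
  n1 <- sum(y == 1)
  n0 <- sum(y == -1)
  if (n1 == 0 || n0 == 0) {
    warning("single-class fold: AUC undefined", call. = FALSE)
    auc <- NA_real_
  } else {
    r <- rank(decision)
    auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       acc = (tp + tn) / length(y),
       sen = if (n1 > 0) tp / n1 else NA_real_,
       spe = if (n0 > 0) tn / n0 else NA_real_,
       auc = auc)
}

# hyperparameter grid in deterministic tie-break order:
# C ascending, then linear < polynomial < gaussian, then sigma descending /
# degree ascending. The first configuration attaining the best mean inner
# accuracy wins.
expand_grid_configs <- function(config) {
  specs <- list()
  for (kind in intersect(c("linear", "polynomial", "gaussian"),
                         config$kernels)) {
    if (kind == "linear") specs <- c(specs, list(kernel_spec("linear")))
    if (kind == "polynomial")
      for (q in config$degree_grid)
        specs <- c(specs, list(kernel_spec("polynomial", degree = q)))
    if (kind == "gaussian")
      for (s in sort(config$sigma_grid, decreasing = TRUE))
        specs <- c(specs, list(kernel_spec("gaussian", width = s)))
  }
  out <- list()
  for (C in config$C_grid)
    for (sp in specs)
      out <- c(out, list(list(C = C, spec = sp)))
  out
}

# Per-group linear Gram and squared distances over a row block; every grid
# configuration's kernel is an elementwise function of these.
group_gram_parts <- function(x, grouping) {
  lapply(grouping, function(cols) {
    xa <- x[, cols, drop = FALSE]
    G <- tcrossprod(xa)
    d <- outer(diag(G), diag(G), "+") - 2 * G
    d[d < 0] <- 0
    list(G = G, D = d)
  })
}

fit_eval_config <- function(parts, y, tr, te, cfg, p_norm) {
  Klist <- lapply(parts, function(p)
    kernel_from_parts(p$G[tr, tr, drop = FALSE], p$D[tr, tr, drop = FALSE],
                      cfg$spec))
  fit <- mkl_fit_grams(Klist, y[tr], cfg$C, p_norm)
  Kxlist <- lapply(parts, function(p)
    kernel_from_parts(p$G[te, tr, drop = FALSE], p$D[te, tr, drop = FALSE],
                      cfg$spec))
  list(fit = fit, decision = mkl_decision_grams(fit, Kxlist, y[tr]))
}

#' Nested cross-validated evaluation of the full pipeline
#'
#' Outer stratified k-fold for error estimation; per outer fold the scaler
#' is fitted on the outer-training rows, Boruta (optional) selects features
#' on the outer-training rows only, an inner stratified cross-validation
#' picks (C, kernel, parameter) by mean inner accuracy (inner folds refit
#' their own scalers), the winning configuration is retrained on the full
#' outer-training set and scored on the held-out fold. Fold metrics are
#' averaged; a pooled-decision AUC is reported alongside.
#'
#' @param ft a `feature_table`.
#' @param config a [cv_config()].
#' @param boruta a [boruta_config()] (used when `config$feature_selection`).
#' @return `cv_report`: per-fold data.frame `folds`, mean metrics, pooled
#'   AUC, selected features per fold, Boruta results, and leakage audit
#'   fields (per-fold train/test indices and scaler row counts).
#' @export
nested_cv <- function(ft, config = cv_config(), boruta = boruta_config()) {
  stopifnot(inherits(ft, "feature_table"), inherits(config, "cv_config"))
  x <- ft$x
  y <- encode_labels(ft$labels)
  folds <- stratified_kfold(ft$labels, config$outer_k,
                            seed = derive_seed(config$seed, 1))
  grid <- expand_grid_configs(config)
  global_scaler <- if (config$scaling == "global") fit_scaler(x) else NULL

  fold_rows <- list()
  selected_per_fold <- list()
  boruta_results <- list()
  audit <- list()
  pooled_dec <- numeric(length(y))

  for (f in seq_len(config$outer_k)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    scaler <- global_scaler %||% fit_scaler(x[tr, , drop = FALSE])
    xs_tr <- transform_features(x[tr, , drop = FALSE], scaler)
    xs_te <- transform_features(x[te, , drop = FALSE], scaler)

    sel <- colnames(x)
    bres <- NULL
    if (config$feature_selection) {
      bcfg <- boruta
      bcfg$seed <- derive_seed(config$seed, 1000 + f)
      bres <- run_boruta(xs_tr, ft$labels[tr], bcfg)
      sel <- boruta_selected(bres)
      if (length(sel) == 0) {
        warning("fold ", f, ": Boruta accepted no features; ",
                "falling back to all features", call. = FALSE)
        sel <- colnames(x)
      }
    }
    grouping <- group_columns(ft$columns, config$grouping_mode,
                              selected = sel)

    inner_folds <- stratified_kfold(ft$labels[tr], config$inner_k,
                                    seed = derive_seed(config$seed,
                                                       2000 + f))
    acc <- matrix(NA_real_, length(grid), config$inner_k)
    for (g in seq_len(config$inner_k)) {
      itr <- which(inner_folds != g)
      ite <- which(inner_folds == g)
      isc <- if (config$scaling == "global") global_scaler
             else fit_scaler(x[tr[itr], , drop = FALSE])
      xi <- transform_features(x[tr, , drop = FALSE], isc)
      parts <- group_gram_parts(xi, grouping)
      for (ci in seq_along(grid)) {
        res <- fit_eval_config(parts, y[tr], itr, ite, grid[[ci]],
                               config$p_norm)
        acc[ci, g] <- mean(ifelse(res$decision >= 0, 1, -1) == y[tr][ite])
      }
    }
    mean_acc <- rowMeans(acc)
    best <- which.max(mean_acc) # first max: grid is in tie-break order
    cfg <- grid[[best]]

    xall <- rbind(xs_tr, xs_te)
    parts <- group_gram_parts(xall[, , drop = FALSE], grouping)
    ntr <- length(tr)
    res <- fit_eval_config(parts, c(y[tr], y[te]), seq_len(ntr),
                           ntr + seq_along(te), cfg, config$p_norm)
    met <- compute_metrics(y[te], res$decision)
    pooled_dec[te] <- res$decision

    fold_rows[[f]] <- data.frame(
      fold = f, n_test = length(te), C = cfg$C,
      kernel = kernel_param_label(cfg$spec), n_selected = length(sel),
      inner_acc = mean_acc[best], TP = met$TP, FP = met$FP, TN = met$TN,
      FN = met$FN, acc = met$acc, sen = met$sen, spe = met$spe,
      auc = met$auc)
    selected_per_fold[[f]] <- sel
    if (!is.null(bres)) boruta_results[[f]] <- bres
    audit[[f]] <- list(train = tr, test = te, scaler_n = scaler$n)
  }

  folds_df <- do.call(rbind, fold_rows)
  structure(list(
    folds = folds_df,
    mean = list(acc = mean(folds_df$acc), sen = mean(folds_df$sen),
                spe = mean(folds_df$spe),
                auc = mean(folds_df$auc, na.rm = TRUE)),
    pooled_auc = compute_metrics(y, pooled_dec)$auc,
    selected = selected_per_fold, boruta = boruta_results,
    fold_assignment = folds, audit = audit, config = config),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("nested CV (", x$config$outer_k, "x", x$config$inner_k, "folds, ",
      x$config$grouping_mode, " grouping, feature selection ",
      ifelse(x$config$feature_selection, "on", "off"), ")\n", sep = "")
  cat(sprintf("mean Acc %.3f  Sen %.3f  Spe %.3f  AUC %.3f (pooled %.3f)\n",
              x$mean$acc, x$mean$sen, x$mean$spe, x$mean$auc, x$pooled_auc))
  invisible(x)
}

#' Export a CV report (per-fold TSV + JSON summary)
#'
#' @param report a `cv_report`.
#' @param prefix path prefix; writes `<prefix>_folds.tsv` and
#'   `<prefix>_summary.json`.
#' @return the prefix, invisibly.
#' @export
export_cv_report <- function(report, prefix) {
  write_numeric_tsv(report$folds, paste0(prefix, "_folds.tsv"))
  write_json_file(list(mean = report$mean, pooled_auc = report$pooled_auc,
                       config = unclass(report$config),
                       selected = report$selected),
                  paste0(prefix, "_summary.json"))
  invisible(prefix)
}
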