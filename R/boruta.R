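#' Configure the all-relevant feature-selection wrapper
#'
#' @param max_runs maximum number of forest runs (default 500).
#' @param alpha significance level of the two-sided binomial hit test
#'   (Bonferroni-corrected over currently undecided features).
#' @param ntree trees per forest run.
#' @param importance `"permutation"` or `"impurity"`.
#' @param tentative_policy what undecided features mean at the run cap:
#'   `"reject"` leaves them tentative and excludes them from the selected
#'   set; `"median-compare"` resolves each by comparing its median
#'   importance history against the median shadow maximum.
#' @param seed integer seed (`NULL` = use current RNG state).
#' @return `boruta_config`.
#' @export
boruta_config <- function(max_runs = 500, alpha = 0.01, ntree = 500,
                          importance = c("permutation", "impurity"),
                          tentative_policy = c("reject", "median-compare"),
                          seed = NULL) {
  abort_if(max_runs < 1, "`max_runs` must be >= 1")
  abort_if(alpha <= 0 || alpha >= 1, "`alpha` must be in (0, 1)")
  structure(list(max_runs = as.integer(max_runs), alpha = alpha,
                 ntree = as.integer(ntree),
                 importance = match.arg(importance),
                 tentative_policy = match.arg(tentative_policy),
                 seed = seed),
            class = "boruta_config")
}

#' Extend a table with shadow features
#'
#' Appends, for each column, an independently row-permuted copy named
#' `shadow_<col>`; shadows keep each feature's marginal distribution but
#' break any association with the outcome.
#'
#' @param x numeric matrix (>= 1 column).
#' @return matrix with twice the columns.
#' @export
add_shadows <- function(x) {
  abort_if(ncol(x) < 1, "need at least one feature")
  sh <- apply(x, 2, function(col) col[sample.int(length(col))])
  sh <- matrix(sh, nrow = nrow(x))
  colnames(sh) <- paste0("shadow_", colnames(x))
  cbind(x, sh)
}

#' All-relevant feature selection with shadow features (Boruta)
#'
#' Iterates: re-permute shadows of the undecided features, fit a forest on
#' accepted + undecided + shadows, score a "hit" for every undecided feature
#' whose importance exceeds the maximum shadow importance, then test the hit
#' count against Binomial(runs, 1/2) two-sidedly with Bonferroni correction
#' over the undecided set. Significantly many hits accepts a feature,
#' significantly few rejects it; rejected features (and all shadows) leave
#' the model. Stops when nothing is undecided or `max_runs` is reached.
#'
#' @param x numeric matrix (rows = instances, named columns).
#' @param y two-level labels.
#' @param config a [boruta_config()].
#' @return `boruta_result`: `accepted`, `rejected`, `tentative` name sets,
#'   `hits`, `runs`, per-run importance `history` and `shadow_max`.
#' @export
run_boruta <- function(x, y, config = boruta_config()) {
  stopifnot(inherits(config, "boruta_config"))
  abort_if(length(unique(as.character(y))) < 2,
           "labels must contain both classes")
  abort_if(nrow(x) < 10, "need at least 10 rows")
  abort_if(is.null(colnames(x)), "feature columns must be named")
  p <- ncol(x)
  feats <- colnames(x)
  status <- setNames(rep("undecided", p), feats)
  hits <- setNames(integer(p), feats)
  history <- matrix(NA_real_, p, config$max_runs,
                    dimnames = list(feats, NULL))
  shadow_max <- rep(NA_real_, config$max_runs)
  runs <- 0L

  with_seed(config$seed, {
    for (r in seq_len(config$max_runs)) {
      und <- feats[status == "undecided"]
      if (length(und) == 0) break
      runs <- r
      model_feats <- feats[status != "rejected"]
      ext <- add_shadows(x[, und, drop = FALSE])
      xx <- cbind(x[, setdiff(model_feats, und), drop = FALSE], ext)
      fit <- random_forest(xx, y, ntree = config$ntree)
      imp <- rf_importance(fit, config$importance)
      sh <- imp[startsWith(names(imp), "shadow_")]
      smax <- max(sh)
      shadow_max[r] <- smax
      history[und, r] <- imp[und]
      hits[und] <- hits[und] + (imp[und] > smax)

      m <- length(und)
      p_hi <- pbinom(hits[und] - 1, r, 0.5, lower.tail = FALSE)
      p_lo <- pbinom(hits[und], r, 0.5)
      status[und[p_hi * m < config$alpha]] <- "accepted"
      status[und[p_lo * m < config$alpha]] <- "rejected"
    }
  })

  history <- history[, seq_len(max(runs, 1)), drop = FALSE]
  shadow_max <- shadow_max[seq_len(max(runs, 1))]
  status[status == "undecided"] <- "tentative"
  if (config$tentative_policy == "median-compare" &&
      any(status == "tentative")) {
    med_sh <- median(shadow_max, na.rm = TRUE)
    for (f in feats[status == "tentative"]) {
      status[f] <- if (median(history[f, ], na.rm = TRUE) > med_sh)
        "accepted" else "rejected"
    }
  }
  structure(list(accepted = feats[status == "accepted"],
                 rejected = feats[status == "rejected"],
                 tentative = feats[status == "tentative"],
                 hits = hits, runs = runs, history = history,
                 shadow_max = shadow_max, config = config),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  cat("boruta_result:", length(x$accepted), "accepted,",
      length(x$rejected), "rejected,", length(x$tentative),
      "tentative after", x$runs, "runs\n")
  invisible(x)
}

#' Features selected by a Boruta run
#'
#' The accepted set (tentative features are excluded under the default
#' `"reject"` policy; `"median-compare"` resolves them before this point).
#'
#' @param result a `boruta_result`.
#' @return character vector of feature names.
#' @export
boruta_selected <- function(result) result$accepted

#' Per-feature selection frequency across repeated runs
#'
#' Counts, for every feature, in how many of the supplied results it was
#' accepted (the cross-validation selection-frequency report).
#'
#' @param results list of `boruta_result`.
#' @return named integer vector over all features seen in any result.
#' @export
selection_frequency <- function(results) {
  abort_if(length(results) == 0, "need at least one result")
  feats <- unique(unlist(lapply(results, function(r) names(r$hits))))
  counts <- setNames(integer(length(feats)), feats)
  for (r in results) counts[r$accepted] <- counts[r$accepted] + 1L
  counts
}

#' Export a Boruta result as delimited text
#'
#' One row per feature: status, hit count, median importance over the runs
#' in which the feature was still undecided.
#'
#' @param result a `boruta_result`.
#' @param path TSV path.
#' @return the path, invisibly.
#' @export
export_boruta <- function(result, path) {
  feats <- names(result$hits)
  status <- ifelse(feats %in% result$accepted, "accepted",
                   ifelse(feats %in% result$rejected, "rejected",
                          "tentative"))
  med <- apply(result$history, 1, median, na.rm = TRUE)
  df <- data.frame(feature = feats, status = status,
                   hits = as.integer(result$hits),
                   median_importance = med[feats])
  write_numeric_tsv(df, path)
  invisible(path)
}
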