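#' Random forest for binary classification
#'
#' Compact bootstrap/CART forest used by the shadow-variable selection
#' wrapper: Gini splits, majority-vote leaves, out-of-bag (OOB) permutation
#' importance. Seeded through R's RNG (`set.seed()`), so fits are
#' reproducible.
#'
#' @param x numeric matrix (rows = instances).
#' @param y two-level labels (factor, character, or +-1).
#' @param ntree number of trees.
#' @param mtry features tried per split (default `floor(sqrt(ncol(x)))`).
#' @param min_node minimum node size to attempt a split.
#' @param keep_forest keep the trees for prediction.
#' @return `erp_rf`: importance vectors (`imp_mean`, `imp_sd`, `gini`),
#'   `oob_error`, tree list and the level coding.
#' @export
random_forest <- function(x, y, ntree = 500, mtry = NULL, min_node = 1,
                          keep_forest = FALSE) {
  lev <- sort(unique(as.character(y)))
  abort_if(length(lev) != 2, "labels must have exactly 2 classes")
  yi <- as.integer(as.character(y) == lev[2])
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  fit <- .rf_fit(x, yi, as.integer(ntree), as.integer(mtry),
                 as.integer(min_node), TRUE, keep_forest)
  names(fit$imp_mean) <- names(fit$imp_sd) <- names(fit$gini) <- colnames(x)
  structure(c(fit, list(levels = lev, mtry = mtry)), class = "erp_rf")
}

#' Permutation-importance Z scores of a fitted forest
#'
#' Per-tree mean decrease in OOB accuracy, normalized by its standard error
#' over trees (features never used score 0).
#'
#' @param fit an `erp_rf`.
#' @param mode `"permutation"` (Z of the per-tree accuracy decrease) or
#'   `"impurity"` (total Gini decrease).
#' @return named numeric vector of importances.
#' @export
rf_importance <- function(fit, mode = c("permutation", "impurity")) {
  mode <- match.arg(mode)
  if (mode == "impurity") return(fit$gini)
  se <- fit$imp_sd / sqrt(fit$ntree)
  z <- ifelse(se > 0, fit$imp_mean / se, 0)
  names(z) <- names(fit$imp_mean)
  z
}

#' @param object an `erp_rf` with `keep_forest = TRUE`.
#' @param newdata numeric matrix with the training columns.
#' @param ... unused.
#' @rdname random_forest
#' @export
predict.erp_rf <- function(object, newdata, ...) {
  abort_if(length(object$forest) == 0,
           "forest was fitted with keep_forest = FALSE")
  votes <- .rf_predict_votes(object$forest, newdata)
  factor(object$levels[(votes > 0.5) + 1], levels = object$levels)
}
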