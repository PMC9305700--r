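#' Fit the feature scaler (columnwise mean and sd)
#'
#' Standardization statistics are computed on training rows only (sd with
#' denominator n-1). Constant columns get sd 0 and are mapped to 0.5 by
#' [transform_features()].
#'
#' @param x numeric matrix or `feature_table` (training rows).
#' @return `scaler_state`: per-column `mean`, `sd`, and `n` rows fitted on.
#' @export
fit_scaler <- function(x) {
  if (inherits(x, "feature_table")) x <- x$x
  abort_if(nrow(x) < 2, "scaler needs >= 2 rows")
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  structure(list(mean = mu, sd = s, n = nrow(x),
                 features = colnames(x)),
            class = "scaler_state")
}

#' Standardize then squash features into (0, 1)
#'
#' `s = 1 / (1 + exp(-(x - mean)/sd))`: the logistic function of the
#' z-score. Outputs are strictly inside (0, 1); constant training columns
#' (sd 0) map to 0.5. Strictly monotone per column, so rank order is
#' preserved.
#'
#' @param x matrix or `feature_table` to transform (any rows).
#' @param state a `scaler_state` fitted on training rows with the same
#'   columns.
#' @return matrix of the same shape as `x` (or a transformed
#'   `feature_table`).
#' @export
transform_features <- function(x, state) {
  stopifnot(inherits(state, "scaler_state"))
  ft <- NULL
  if (inherits(x, "feature_table")) { ft <- x; x <- x$x }
  abort_if(!identical(colnames(x), state$features),
           "feature columns do not match the fitted scaler")
  z <- sweep(x, 2, state$mean)
  pos <- state$sd > 0
  z[, pos] <- sweep(z[, pos, drop = FALSE], 2, state$sd[pos], "/")
  z[, !pos] <- 0
  out <- 1 / (1 + exp(-z))
  # keep the open interval even when exp() over/underflows
  out <- pmin(pmax(out, .Machine$double.xmin), 1 - .Machine$double.eps)
  if (!is.null(ft)) { ft$x <- out; return(ft) }
  out
}

#' Serialize / restore a scaler for audit
#'
#' @param state a `scaler_state`.
#' @param path JSON file path.
#' @return `write_scaler()` the path invisibly; `read_scaler()` the state.
#' @export
write_scaler <- function(state, path) {
  write_json_file(list(mean = as.list(state$mean), sd = as.list(state$sd),
                       n = state$n), path)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  j <- read_json_file(path)
  structure(list(mean = unlist(j$mean), sd = unlist(j$sd), n = j$n,
                 features = names(unlist(j$mean))),
            class = "scaler_state")
}
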