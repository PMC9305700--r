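# Internal fitter working on precomputed per-group Gram matrices.
# Alternates (1) the soft-margin SVM dual on the combined kernel with the
# weights fixed, and (2) the closed-form lp-norm weight update
#   beta_m = v_m^{1/(p+1)} / (sum_m' v_m'^{p/(p+1)})^{1/p},
# where v_m = ||w_m||^2 = beta_m^2 (alpha*y)' K_m (alpha*y) is the
# per-kernel margin norm of the variational formulation; this block update
# monotonically decreases the regularized objective and its fixed point
# satisfies the lp-norm MKL stationarity conditions. After the weights
# stabilize the dual is re-solved once so (alpha, b) match the final beta.
mkl_fit_grams <- function(Klist, y, C, p_norm = 2, tol = 1e-4,
                          max_iter = 100, svm_tol = 1e-8) {
  M <- length(Klist)
  n <- length(y)
  scales <- vapply(Klist, function(K) {
    tr <- sum(diag(K))
    if (tr > 0) n / tr else 1
  }, numeric(1))
  Ks <- lapply(seq_len(M), function(m) Klist[[m]] * scales[m])
  beta <- rep(M^(-1 / p_norm), M)
  solve_at <- function(beta) {
    Kc <- Reduce(`+`, lapply(seq_len(M), function(m) beta[m] * Ks[[m]]))
    .smo_solve(Kc, y, C, svm_tol, 200L * n * n + 10000L)
  }
  objective <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    sol <- solve_at(beta)
    objective <- c(objective, sol$objective)
    ay <- sol$alpha * y
    f <- vapply(Ks, function(K) drop(crossprod(ay, K %*% ay)), numeric(1))
    v <- beta^2 * f
    if (all(v <= 0)) { converged <- TRUE; break }
    beta_new <- v^(1 / (p_norm + 1)) /
      sum(v^(p_norm / (p_norm + 1)))^(1 / p_norm)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  sol <- solve_at(beta)
  objective <- c(objective, sol$objective)
  list(alpha = sol$alpha, b = sol$b, beta = beta, scales = scales,
       objective = objective, converged = converged, iterations = it)
}

mkl_decision_grams <- function(fit, Kxlist, y) {
  M <- length(Kxlist)
  ay <- fit$alpha * y
  f <- 0
  for (m in seq_len(M))
    f <- f + fit$beta[m] * ((Kxlist[[m]] * fit$scales[m]) %*% ay)
  drop(f) + fit$b
}

#' Train a multiple-kernel SVM
#'
#' Feature columns are split into M groups, each mapped through its own base
#' kernel; the classifier is a soft-margin SVM on the convex combination
#' `sum_m beta_m K_m` with `beta >= 0`, `||beta||_p = 1`. Training
#' alternates the SVM dual (with weights fixed) and a closed-form lp-norm
#' weight update until the weights stabilize. Base kernels are
#' trace-normalized before combination.
#'
#' @param x numeric matrix (named columns).
#' @param labels +-1 (or a two-level factor: the second sorted level maps
#'   to +1).
#' @param grouping named list of column-name (or index) vectors, one per
#'   kernel; `NULL` puts all columns in one group.
#' @param spec a [kernel_spec()] applied to every group, or a list with one
#'   spec per group.
#' @param C soft-margin cost (> 0).
#' @param p_norm weight-norm order p (1 = sparse, 2 = non-sparse; default 2).
#' @param tol convergence tolerance on `max |delta beta|`.
#' @param max_iter maximum alternating iterations (a model that hits the cap
#'   is returned with `converged = FALSE`).
#' @param svm_tol KKT tolerance of the inner dual solver.
#' @return `mkl_model` with support coefficients `alpha`, bias `b`, weights
#'   `beta`, kernel scales, specs, grouping and the training rows.
#' @export
train_mkl <- function(x, labels, grouping = NULL,
                      spec = kernel_spec("linear"), C = 1, p_norm = 2,
                      tol = 1e-4, max_iter = 100, svm_tol = 1e-8) {
  y <- encode_labels(labels)
  abort_if(length(y) < 4, "need at least 4 training rows")
  abort_if(length(unique(y)) < 2, "both classes must be present")
  abort_if(C <= 0, "`C` must be > 0")
  if (is.null(grouping)) grouping <- list(all = colnames(x) %||%
                                            seq_len(ncol(x)))
  specs <- if (inherits(spec, "kernel_spec"))
    rep(list(spec), length(grouping)) else spec
  abort_if(length(specs) != length(grouping),
           "need one kernel spec per group")
  xg <- lapply(grouping, function(cols) x[, cols, drop = FALSE])
  Klist <- lapply(seq_along(xg), function(m)
    compute_kernel(xg[[m]], spec = specs[[m]]))
  fit <- mkl_fit_grams(Klist, y, C, p_norm, tol, max_iter, svm_tol)
  structure(list(alpha = fit$alpha, y = y, b = fit$b, beta = fit$beta,
                 scales = fit$scales, specs = specs, grouping = grouping,
                 p_norm = p_norm, C = C, x_train = x,
                 objective = fit$objective, converged = fit$converged,
                 labels_map = attr(y, "labels_map")),
            class = "mkl_model")
}

encode_labels <- function(labels) {
  if (is.numeric(labels) && all(labels %in% c(-1, 1))) {
    y <- as.numeric(labels)
    attr(y, "labels_map") <- c(`-1` = -1, `1` = 1)
    return(y)
  }
  lev <- sort(unique(as.character(labels)))
  abort_if(length(lev) != 2, "labels must have exactly two levels")
  y <- ifelse(as.character(labels) == lev[2], 1, -1)
  attr(y, "labels_map") <- setNames(c(-1, 1), lev)
  y
}

#' Decision values and class predictions of an MKL model
#'
#' `f(x) = sum_i alpha_i y_i sum_m beta_m k_m(x_i^m, x^m) + b`; the
#' predicted class is `sign(f)` (0 maps to +1).
#'
#' @param model an `mkl_model`.
#' @param newx matrix with the training columns.
#' @return numeric decision values (`decision_function`) or +-1
#'   (`predict`).
#' @export
decision_function <- function(model, newx) {
  stopifnot(inherits(model, "mkl_model"))
  if (!is.matrix(newx)) newx <- rbind(newx)
  abort_if(!is.null(colnames(model$x_train)) &&
             !all(unlist(model$grouping) %in% colnames(newx)),
           "new rows are missing model feature columns")
  Kxlist <- lapply(seq_along(model$grouping), function(m) {
    cols <- model$grouping[[m]]
    compute_kernel(newx[, cols, drop = FALSE],
                   model$x_train[, cols, drop = FALSE], model$specs[[m]])
  })
  mkl_decision_grams(model, Kxlist, model$y)
}

#' @param object an `mkl_model`.
#' @param newdata matrix of rows to classify.
#' @param ... unused.
#' @rdname decision_function
#' @export
predict.mkl_model <- function(object, newdata, ...) {
  f <- decision_function(object, newdata)
  ifelse(f >= 0, 1, -1)
}

#' Serialize / restore an MKL model as structured text
#'
#' Stores coefficients, weights, kernel specs, grouping and the training
#' rows (values included so re-scoring is exact), plus an md5 of the
#' training block.
#'
#' @param model an `mkl_model`.
#' @param path JSON path.
#' @return `write_mkl_model()` the path invisibly; `read_mkl_model()` the
#'   model.
#' @export
write_mkl_model <- function(model, path) {
  obj <- list(alpha = model$alpha, y = as.numeric(model$y), b = model$b,
              beta = model$beta, scales = model$scales,
              p_norm = model$p_norm, C = model$C,
              specs = lapply(model$specs, unclass),
              grouping = model$grouping,
              labels_map = as.list(model$labels_map),
              x_train = apply(model$x_train, 1, as.numeric,
                              simplify = FALSE),
              colnames = colnames(model$x_train),
              train_hash = config_hash(list(
                x = as.numeric(model$x_train), y = as.numeric(model$y))))
  write_json_file(obj, path)
  invisible(path)
}

#' @rdname write_mkl_model
#' @export
read_mkl_model <- function(path) {
  j <- read_json_file(path)
  x <- if (is.matrix(j$x_train)) j$x_train else do.call(rbind, j$x_train)
  colnames(x) <- j$colnames
  y <- j$y
  attr(y, "labels_map") <- unlist(j$labels_map)
  structure(list(alpha = j$alpha, y = y, b = j$b, beta = j$beta,
                 scales = j$scales,
                 specs = if (is.data.frame(j$specs)) {
                   lapply(seq_len(nrow(j$specs)), function(i)
                     kernel_spec(j$specs$kind[i], j$specs$degree[i],
                                 j$specs$width[i]))
                 } else {
                   lapply(j$specs, function(s)
                     kernel_spec(s$kind, s$degree %||% 2, s$width %||% 1))
                 },
                 grouping = lapply(j$grouping, unlist),
                 p_norm = j$p_norm, C = j$C, x_train = x,
                 labels_map = unlist(j$labels_map)),
            class = "mkl_model")
}
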