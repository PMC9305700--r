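#' Base kernel specification
#'
#' Linear `<x, y>`, polynomial `(<x, y> + 1)^q`, or Gaussian
#' `exp(-||x - y||^2 / s^2)`.
#'
#' @param kind `"linear"`, `"polynomial"` or `"gaussian"`.
#' @param degree polynomial degree `q` (positive integer).
#' @param width Gaussian width `s` (> 0).
#' @return `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("linear", "polynomial", "gaussian"),
                        degree = 2, width = 1) {
  kind <- match.arg(kind)
  abort_if(kind == "polynomial" && (degree < 1 || degree != round(degree)),
           "polynomial degree must be a positive integer")
  abort_if(kind == "gaussian" && width <= 0, "gaussian width must be > 0")
  structure(list(kind = kind, degree = as.integer(degree), width = width),
            class = "kernel_spec")
}

kernel_param_label <- function(spec) {
  switch(spec$kind, linear = "linear",
         polynomial = sprintf("polynomial(q=%d)", spec$degree),
         gaussian = sprintf("gaussian(s=%g)", spec$width))
}

# squared Euclidean distances between row blocks
sq_dist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d[d < 0] <- 0
  d
}

#' Compute a kernel Gram matrix between two row blocks
#'
#' @param A,B numeric matrices with matching column counts (`B` defaults to
#'   `A`, giving a symmetric Gram matrix).
#' @param spec a [kernel_spec()].
#' @return `nrow(A) x nrow(B)` Gram matrix.
#' @export
compute_kernel <- function(A, B = A, spec = kernel_spec("linear")) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (!is.matrix(A)) A <- rbind(A)
  if (!is.matrix(B)) B <- rbind(B)
  abort_if(ncol(A) != ncol(B), "column counts must match")
  switch(spec$kind,
         linear = tcrossprod(A, B),
         polynomial = (tcrossprod(A, B) + 1)^spec$degree,
         gaussian = exp(-sq_dist(A, B) / spec$width^2))
}

# Kernels derived from a precomputed linear Gram G and squared distances D
# (cross-validation fast path: G and D are computed once per fold).
kernel_from_parts <- function(G, D, spec) {
  switch(spec$kind,
         linear = G,
         polynomial = (G + 1)^spec$degree,
         gaussian = exp(-D / spec$width^2))
}

#' Combine base kernels with non-negative weights
#'
#' Each base kernel is trace-normalized (`K * n / trace(K)`) so the weights
#' are comparable across kernel types, then summed with weights `beta`.
#'
#' @param kernels list of square Gram matrices of equal size.
#' @param beta non-negative weights (not all zero).
#' @param normalize trace-normalize before combining.
#' @return combined Gram matrix.
#' @export
combine_kernels <- function(kernels, beta, normalize = TRUE) {
  abort_if(length(kernels) != length(beta),
           "`kernels` and `beta` lengths differ")
  abort_if(any(beta < 0) || sum(beta) <= 0,
           "`beta` must be non-negative with at least one positive entry")
  n <- nrow(kernels[[1]])
  out <- matrix(0, n, n)
  for (m in seq_along(kernels)) {
    K <- kernels[[m]]
    abort_if(nrow(K) != n || ncol(K) != n, "kernels must be conformable")
    if (normalize) {
      tr <- sum(diag(K))
      if (tr > 0) K <- K * (n / tr)
    }
    out <- out + beta[m] * K
  }
  out
}
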