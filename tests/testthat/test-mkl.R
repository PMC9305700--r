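toy_groups <- function(seed = 3, n = 40) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n, 1.2), ncol = 2),
             matrix(rnorm(n, -1.2), ncol = 2))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = c(rep(1, n / 2), rep(-1, n / 2)))
}

test_that("base kernels evaluate their closed forms", {
  expect_equal(compute_kernel(c(1, 2), c(3, 4))[1, 1], 11)
  expect_equal(compute_kernel(c(1, 0), c(1, 0),
                              kernel_spec("polynomial", degree = 2))[1, 1],
               4)
  set.seed(17)
  x <- matrix(rnorm(12), 4, 3)
  Kg <- compute_kernel(x, spec = kernel_spec("gaussian", width = 2))
  expect_equal(diag(Kg), rep(1, 4))
  expect_equal(Kg, t(Kg))
  expect_equal(Kg[1, 2], exp(-sum((x[1, ] - x[2, ])^2) / 4))
  expect_error(kernel_spec("gaussian", width = 0), "width")
  expect_error(kernel_spec("polynomial", degree = 0.5), "degree")
})

test_that("kernel combination is trace-aware and validates weights", {
  set.seed(18)
  A <- crossprod(matrix(rnorm(25), 5, 5))
  expect_equal(combine_kernels(list(A), 1, normalize = FALSE), A)
  expect_error(combine_kernels(list(A, A), c(0, 0)), "beta")
  expect_error(combine_kernels(list(A), c(0.5, 0.5)), "lengths")
  # two copies at half weight reproduce the normalized kernel
  both <- combine_kernels(list(A, A), c(0.5, 0.5))
  one <- combine_kernels(list(A), 1)
  expect_equal(both, one)
})

test_that("with one linear kernel the MKL model matches an independent
           dual solver", {
  g <- toy_groups()
  m <- train_mkl(g$x, g$y, C = 1, spec = kernel_spec("linear"))
  K <- compute_kernel(g$x)
  K <- K * nrow(K) / sum(diag(K)) # same trace normalization
  o <- svm_dual_oracle(K, g$y, C = 1)
  f_pkg <- decision_function(m, g$x)
  f_orc <- drop(K %*% (o$alpha * g$y)) + o$b
  expect_lt(max(abs(f_pkg - f_orc)), 1e-3)
  expect_equal(m$beta, 1)
})

test_that("trained models satisfy the dual feasibility invariants", {
  g <- toy_groups(seed = 23)
  for (spec in list(kernel_spec("linear"),
                    kernel_spec("polynomial", degree = 2),
                    kernel_spec("gaussian", width = 1))) {
    for (C in c(0.5, 5)) {
      m <- train_mkl(g$x, g$y, grouping = list(a = "f1", b = "f2"),
                     spec = spec, C = C)
      expect_true(all(m$alpha >= -1e-10 & m$alpha <= C + 1e-10))
      expect_lt(abs(sum(m$alpha * m$y)), 1e-6)
      expect_true(all(m$beta >= 0))
      expect_equal(sqrt(sum(m$beta^2)), 1, tolerance = 1e-8)
      # margin support vectors sit on |f| = 1
      f <- decision_function(m, g$x)
      free <- m$alpha > 1e-6 * C & m$alpha < C * (1 - 1e-6)
      if (any(free))
        expect_equal(abs(f[free]), rep(1, sum(free)), tolerance = 1e-4)
      # objective is non-increasing along the alternating iterations
      expect_true(all(diff(m$objective) <= 1e-8))
    }
  }
})

test_that("combined Gram matrices stay positive semi-definite", {
  g <- toy_groups(seed = 29)
  m <- train_mkl(g$x, g$y, grouping = list(a = "f1", b = "f2"),
                 spec = kernel_spec("gaussian", width = 0.5), C = 1)
  Ks <- lapply(seq_along(m$grouping), function(i)
    compute_kernel(g$x[, m$grouping[[i]], drop = FALSE],
                   spec = m$specs[[i]]) * m$scales[i])
  Kc <- Reduce(`+`, Map(`*`, Ks, m$beta))
  ev <- eigen(Kc, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * sum(diag(Kc)))
})

test_that("duplicated kernels share the weight under p = 2 and a pure-noise
           group is down-weighted under p = 1", {
  g <- toy_groups(seed = 31)
  m <- train_mkl(g$x, g$y, grouping = list(a = c("f1", "f2"),
                                           b = c("f1", "f2")),
                 spec = kernel_spec("linear"), C = 1, p_norm = 2)
  expect_lt(abs(m$beta[1] - m$beta[2]), 1e-6)
  set.seed(32)
  x2 <- cbind(g$x, noise1 = rnorm(40), noise2 = rnorm(40))
  m2 <- train_mkl(x2, g$y,
                  grouping = list(sig = c("f1", "f2"),
                                  noi = c("noise1", "noise2")),
                  spec = kernel_spec("linear"), C = 1, p_norm = 1)
  expect_lt(m2$beta[2], m2$beta[1])
  expect_equal(sum(m2$beta), 1, tolerance = 1e-8)
})

test_that("a separable toy is classified perfectly and predictions are
           deterministic", {
  set.seed(33)
  x <- rbind(matrix(rnorm(20, 3), ncol = 2), matrix(rnorm(20, -3), ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- c(rep(1, 10), rep(-1, 10))
  m <- train_mkl(x, y, C = 10, spec = kernel_spec("linear"))
  expect_equal(predict(m, x), y)
  expect_identical(decision_function(m, x), decision_function(m, x))
})

test_that("decision values equal the explicit double-loop evaluation", {
  g <- toy_groups(seed = 37)
  grouping <- list(a = "f1", b = "f2")
  m <- train_mkl(g$x, g$y, grouping = grouping,
                 spec = kernel_spec("gaussian", width = 1), C = 1)
  new5 <- g$x[1:5, , drop = FALSE] + 0.1
  f <- decision_function(m, new5)
  for (r in 1:5) {
    acc <- 0
    for (i in seq_along(m$y)) {
      km <- 0
      for (mm in seq_along(grouping)) {
        xi <- g$x[i, grouping[[mm]], drop = FALSE]
        xn <- new5[r, grouping[[mm]], drop = FALSE]
        km <- km + m$beta[mm] * m$scales[mm] *
          exp(-sum((xi - xn)^2) / m$specs[[mm]]$width^2)
      }
      acc <- acc + m$alpha[i] * m$y[i] * km
    }
    expect_equal(f[r], acc + m$b, tolerance = 1e-10)
  }
})

test_that("models re-score exactly after a text round trip", {
  g <- toy_groups(seed = 41)
  m <- train_mkl(g$x, g$y, grouping = list(a = "f1", b = "f2"),
                 spec = kernel_spec("polynomial", degree = 2), C = 2)
  p <- tempfile(fileext = ".json")
  write_mkl_model(m, p)
  m2 <- read_mkl_model(p)
  expect_equal(decision_function(m2, g$x), decision_function(m, g$x),
               tolerance = 1e-10)
  unlink(p)
})
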