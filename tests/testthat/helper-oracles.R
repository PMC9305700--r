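# Independent oracles: deliberately different algorithms from the package
# implementations they check.

# SVM dual by projected gradient ascent (projection onto the box +
# equality constraint via bisection on the multiplier).
svm_dual_oracle <- function(K, y, C, iters = 4000) {
  n <- length(y)
  Q <- K * tcrossprod(y)
  L <- max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
  a <- rep(0, n)
  proj <- function(a0) {
    f <- function(lam) sum(pmin(pmax(a0 - lam * y, 0), C) * y)
    lo <- -max(abs(a0)) - C - 1
    hi <- -lo
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    pmin(pmax(a0 - ((lo + hi) / 2) * y, 0), C)
  }
  for (i in seq_len(iters)) a <- proj(a + drop(1 - Q %*% a) / L)
  free <- a > 1e-6 & a < C - 1e-6
  b <- mean(y[free] - (K %*% (a * y))[free])
  list(alpha = a, b = b)
}

# largest-remainder apportionment by exhaustive choice of which classes get
# the extra units (independent of the package's order()-based version)
largest_remainder_oracle <- function(prop, n) {
  raw <- prop * n
  base <- floor(raw)
  left <- round(n - sum(base))
  rem <- raw - base
  counts <- base
  for (i in seq_len(left)) {
    j <- which.max(rem)
    counts[j] <- counts[j] + 1
    rem[j] <- -1
  }
  counts
}

# direct DFT periodogram (quadratic-time) for spectral-feature checks
dft_power <- function(x) {
  n <- length(x)
  sapply(seq_len(floor(n / 2)), function(k) {
    w <- exp(-2i * pi * k * (0:(n - 1)) / n)
    Mod(sum(x * w))^2
  })
}

# planted-signal table for selection tests: p_inf informative columns at
# standardized effect size d, p_noise pure-noise columns
make_selection_table <- function(seed, n = 100, p_inf = 10, p_noise = 90,
                                 d = 1.5) {
  set.seed(seed)
  y <- rep(c("A", "B"), each = n / 2)
  x <- cbind(matrix(rnorm(n * p_inf, ifelse(y == "B", d / 2, -d / 2)),
                    n, p_inf),
             matrix(rnorm(n * p_noise), n, p_noise))
  colnames(x) <- c(paste0("inf", seq_len(p_inf)),
                   paste0("noise", seq_len(p_noise)))
  list(x = x, y = y)
}
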