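# Naive SSA reference: explicit trajectory matrix, full SVD, explicit
# anti-diagonal means. Kept deliberately direct and independent of the
# package's convolution-based reconstruction.
naive_ssa_components <- function(x, L) {
  N <- length(x); K <- N - L + 1
  X <- matrix(0, L, K)
  for (j in 1:K) X[, j] <- x[j:(j + L - 1)]
  sv <- svd(X)
  comps <- matrix(0, N, L)
  for (i in 1:L) {
    Xi <- sv$d[i] * outer(sv$u[, i], sv$v[, i])
    for (s in 1:N) {
      vals <- c()
      for (r in 1:L) {
        cidx <- s - r + 1
        if (cidx >= 1 && cidx <= K) vals <- c(vals, Xi[r, cidx])
      }
      comps[s, i] <- mean(vals)
    }
  }
  comps
}

test_that("elementary reconstructions match the naive SSA oracle", {
  set.seed(31)
  for (case in list(list(n = 24, L = 6), list(n = 50, L = 12),
                    list(n = 64, L = 32))) {
    x <- cumsum(rnorm(case$n)) + sin(seq_len(case$n))
    s <- uniform_series(x, 10)
    d <- ssa_decompose(s, case$L)
    ref <- naive_ssa_components(x, case$L)
    # singular vectors are sign/rotation ambiguous only within degenerate
    # singular values; compare the component-wise reconstructions summed
    # over groups of (numerically) equal singular values
    expect_equal(dim(d$components), dim(ref))
    grp <- cumsum(c(TRUE, abs(diff(sqrt(d$eigenvalues))) >
                      1e-9 * sqrt(d$eigenvalues[1])))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      expect_equal(rowSums(d$components[, idx, drop = FALSE]),
                   rowSums(ref[, idx, drop = FALSE]), tolerance = 1e-9)
    }
  }
})

test_that("sum of all elementary components reconstructs the input exactly", {
  set.seed(32)
  for (i in 1:5) {
    n <- sample(30:200, 1)
    x <- cumsum(rnorm(n))
    s <- uniform_series(x, 5)
    d <- ssa_decompose(s, sample(2:(n %/% 2), 1))
    expect_lt(max(abs(rowSums(d$components) - x)), 1e-9 * rms(x))
  }
})

test_that("eigenvalues are descending and sum to the trajectory energy", {
  set.seed(33)
  x <- rnorm(120)
  L <- 30
  d <- ssa_decompose(uniform_series(x, 10), L)
  expect_true(all(diff(d$eigenvalues) <= 1e-9 * d$eigenvalues[1]))
  expect_true(all(d$eigenvalues >= 0))
  K <- 120 - L + 1
  frob2 <- sum(vapply(1:L, function(i) sum(x[i:(i + K - 1)]^2), numeric(1)))
  expect_equal(sum(d$eigenvalues), frob2, tolerance = 1e-9)
})

test_that("a constant series is rank one; a sinusoid is rank two", {
  d <- ssa_decompose(uniform_series(rep(3, 60), 10), 15)
  expect_gt(d$eigenvalues[1] / sum(d$eigenvalues), 0.999)
  expect_equal(d$components[, 1], rep(3, 60), tolerance = 1e-6)
  s <- make_sine_series(1, 10, 20)
  d2 <- ssa_decompose(s, 50)
  expect_gt(sum(d2$eigenvalues[1:2]) / sum(d2$eigenvalues), 0.99)
  expect_error(ssa_decompose(s, 1), "window_len")
  expect_error(ssa_decompose(s, 150), "window_len")
})

test_that("grouping separates a ramp trend from a fast oscillation", {
  rate <- 10; n <- 400
  t <- (0:(n - 1)) / rate
  ramp <- 0.05 * t
  osc <- sin(2 * pi * 1.5 * t)
  s <- uniform_series(ramp + osc, rate)
  res <- group_components(ssa_decompose(s, 100), trend_cutoff = 0.1,
                          energy_floor = 0.05)
  expect_gt(cor(res$L$values, ramp), 0.99)
  expect_gt(cor(res$S$values, osc), 0.99)
  # additivity with every grouping
  expect_lt(max(abs(res$L$values + res$S$values + res$R$values -
                      s$values)), 1e-9 * rms(s$values))
})

test_that("white noise yields an empty oscillatory group at a high floor", {
  set.seed(35)
  s <- uniform_series(rnorm(300), 10)
  res <- group_components(ssa_decompose(s, 30), trend_cutoff = 0.1,
                          energy_floor = 0.2)
  expect_equal(sum(res$grouping == "S"), 0)
  expect_true(all(res$S$values == 0))
  expect_lt(max(abs(res$L$values + res$S$values + res$R$values - s$values)),
            1e-9)
})

test_that("zero trend cutoff gives an identically zero trend", {
  set.seed(36)
  s <- uniform_series(rnorm(100) + 5, 10)
  res <- group_components(ssa_decompose(s, 20), trend_cutoff = 0,
                          energy_floor = 0.05)
  expect_true(all(res$L$values == 0))
})

test_that("trend_of recovers constants and monotone ramps", {
  cs <- uniform_series(rep(2.2, 200), 10)
  expect_equal(trend_of(cs, window_len = 50)$values, rep(2.2, 200),
               tolerance = 1e-6)
  t <- (0:599) / 10
  ramp <- uniform_series(0.1 * t + 0.02 * sin(2 * pi * 2 * t), 10)
  tr <- trend_of(ramp, window_len = 100)
  core <- 101:499  # away from one window length of each edge
  expect_true(all(diff(tr$values[core]) > -1e-6))
})

test_that("trend plus complement reconstructs the input (additivity)", {
  set.seed(37)
  t <- (0:399) / 10
  s <- uniform_series(0.03 * t + sin(2 * pi * 1.2 * t) + rnorm(400, sd = 0.2),
                      10)
  d <- ssa_decompose(s, 80)
  res <- group_components(d)
  expect_equal(res$L$values + res$S$values + res$R$values, s$values,
               tolerance = 1e-9)
})
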