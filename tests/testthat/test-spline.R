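test_that("smoothing spline limits: p = 1 interpolates, p = 0 is the LS line", {
  set.seed(5)
  y <- rnorm(30)
  expect_equal(smoothingSpline(y, 1), y)
  f0 <- smoothingSpline(y, 0)
  x <- seq_along(y) - 1
  expect_equal(f0, as.numeric(fitted(lm(y ~ x))), tolerance = 1e-9)
  expect_error(smoothingSpline(y[1:3], 0.5), "at least 4")
  expect_error(smoothingSpline(y, 1.5), "\\[0, 1\\]")
})

test_that("smoothing spline solves the penalised least-squares problem", {
  # independent dense oracle: f = argmin p|y-f|^2 + (1-p) f' K f with the
  # natural-spline roughness matrix K = Q R^{-1} Q' assembled densely
  denseOracle <- function(y, p) {
    n <- length(y); h <- rep(1, n - 1)
    m <- n - 2
    Q <- matrix(0, n, m); R <- matrix(0, m, m)
    for (j in 1:m) {
      Q[j, j] <- 1 / h[j]
      Q[j + 1, j] <- -1 / h[j] - 1 / h[j + 1]
      Q[j + 2, j] <- 1 / h[j + 1]
      R[j, j] <- (h[j] + h[j + 1]) / 3
      if (j < m) { R[j, j + 1] <- h[j + 1] / 6; R[j + 1, j] <- h[j + 1] / 6 }
    }
    K <- Q %*% solve(R) %*% t(Q)
    as.numeric(solve(p * diag(n) + (1 - p) * K, p * y))
  }
  set.seed(6)
  y <- sin(seq(0, 2 * pi, length.out = 80)) + rnorm(80, sd = 0.2)
  for (p in c(0.99, 0.5, 0.001)) {
    expect_equal(smoothingSpline(y, p), denseOracle(y, p), tolerance = 1e-6)
  }
})

test_that("smoothing spline fit minimises the objective among perturbations", {
  # the objective, with the curvature integral computed numerically from an
  # independent natural-spline interpolant of the candidate values
  objective <- function(y, a, p) {
    x <- seq_along(y) - 1
    sf <- splinefun(x, a, method = "natural")
    grid <- seq(0, max(x), by = 0.02)
    d2 <- sf(grid, deriv = 2)
    p * sum((y - a)^2) + (1 - p) * sum(d2^2) * 0.02
  }
  set.seed(7)
  y <- cumsum(rnorm(60))
  p <- 0.9
  fit <- smoothingSpline(y, p)
  J0 <- objective(y, fit, p)
  for (i in 1:10) {
    pert <- fit + rnorm(60, sd = 0.05)
    expect_lt(J0, objective(y, pert, p))
  }
  expect_lt(J0, objective(y, y, p))
})

test_that("correctSevere flattens excursions and touches only severe samples", {
  n <- 600
  x <- numeric(n)
  idx <- 200:300
  tt <- (idx - 200) / 10
  x[idx] <- 8 * sin(2 * pi * 0.3 * tt) * exp(-0.5 * ((tt - 5) / 2)^2)
  ann <- ArtifactAnnotation(start = 200, end = 300, category = "severe",
                            source = "fnirs", nSamples = n)
  x1 <- correctSevere(x, ann)
  # post-correction RMS within the segment reduced by >= 80%
  expect_lt(sqrt(mean(x1[idx]^2)), 0.2 * sqrt(mean(x[idx]^2)))
  expect_identical(x1[-idx], x[-idx])
  # no severe segments: output is bit-identical
  empty <- ArtifactAnnotation(nSamples = n)
  expect_identical(correctSevere(x, empty), x)
})

test_that("removeBaselineShift re-anchors a step and leaves the rest alone", {
  n <- 400
  x <- numeric(n); x[201:n] <- 3
  ann <- ArtifactAnnotation(start = c(151, 151), end = c(250, 250),
                            category = c("slight", "baseline_shift"),
                            source = "fnirs", nSamples = n)
  x2 <- removeBaselineShift(x, ann, fs = 10)
  dm0 <- abs(mean(x[241:250]) - mean(x[151:160]))
  dm1 <- abs(mean(x2[241:250]) - mean(x2[151:160]))
  expect_lt(dm1, 0.1 * dm0)          # step mean-jump reduced >= 90%
  expect_identical(x2[151], x[151])  # anchored at the segment start
  expect_identical(x2[1:150], x[1:150])
  expect_identical(x2[251:n], x[251:n])
  # no baseline-shift segments: identity
  empty <- ArtifactAnnotation(nSamples = n)
  expect_identical(removeBaselineShift(x, empty, fs = 10), x)
})
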