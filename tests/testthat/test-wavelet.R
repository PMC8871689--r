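test_that("one DWT step matches an explicitly assembled orthonormal matrix", {
  # independent oracle: build the circulant analysis matrix row by row from
  # the filter definition and compare, and verify its orthonormality
  N <- 64L
  set.seed(10)
  x <- rnorm(N)
  for (wname in availableWavelets()) {
    f <- waveletFilter(wname)
    L <- length(f$lo)
    Mlo <- matrix(0, N / 2, N)
    Mhi <- matrix(0, N / 2, N)
    for (k in seq_len(N / 2)) {
      for (m in seq_len(L)) {
        col <- ((2 * (k - 1) + m - 1) %% N) + 1
        Mlo[k, col] <- Mlo[k, col] + f$lo[m]
        Mhi[k, col] <- Mhi[k, col] + f$hi[m]
      }
    }
    W <- rbind(Mlo, Mhi)
    expect_equal(W %*% t(W), diag(N), tolerance = 1e-9,
                 ignore_attr = TRUE)
    st <- fnirsart:::dwtStep(x, f$lo, f$hi)
    expect_equal(st$a, as.numeric(Mlo %*% x), tolerance = 1e-12)
    expect_equal(st$d, as.numeric(Mhi %*% x), tolerance = 1e-12)
    # synthesis is the transpose
    xr <- fnirsart:::idwtStep(st$a, st$d, f$lo, f$hi)
    expect_equal(xr, as.numeric(t(W) %*% c(st$a, st$d)), tolerance = 1e-12)
  }
})

test_that("multi-level decomposition round-trips for every wavelet and odd lengths", {
  set.seed(11)
  for (wname in availableWavelets()) {
    for (n in c(512L, 777L, 1000L)) {
      x <- rnorm(n)
      dec <- dwtDecompose(x, wname)
      err <- max(abs(dwtReconstruct(dec) - x)) / max(abs(x))
      expect_lt(err, 1e-8)
    }
  }
  expect_error(dwtDecompose(rnorm(8), "db4"), "too short")
  expect_error(waveletFilter("haar2"), "unknown wavelet")
})

test_that("decomposition conserves energy (orthonormal transform)", {
  set.seed(12)
  x <- rnorm(1024)
  dec <- dwtDecompose(x, "sym4")
  expect_equal(sum(unlist(dec@details)^2) + sum(dec@approx^2),
               sum(x^2), tolerance = 1e-9)
})

test_that("estimateSigma applies the 0.1587L order-statistic rule", {
  expect_equal(estimateSigma(c(-2, 2)), 2)  # index round(0.3174) -> 1
  expect_equal(estimateSigma(c(5)), 5)
  expect_error(estimateSigma(numeric(0)), "empty")
  # equivariance under positive scaling
  set.seed(13)
  co <- rnorm(1000)
  expect_equal(estimateSigma(2.5 * co), 2.5 * estimateSigma(co),
               tolerance = 1e-12)
  # Monte Carlo consistency: the 15.87th percentile of N(0, s^2) is -s
  set.seed(14)
  big <- rnorm(1e5, sd = 3.1)
  expect_lt(abs(estimateSigma(big) - 3.1) / 3.1, 0.02)
})

test_that("thresholdsFromAlpha gives the two-sided normal deviate and 1.3 ratio", {
  th <- thresholdsFromAlpha(0.05, 1)
  expect_equal(th@u, 1.959964, tolerance = 1e-6)
  expect_equal(th@w1 / th@w2, 1.3)
  # alpha -> 1 collapses both thresholds to zero
  th1 <- thresholdsFromAlpha(1 - 1e-12, 2)
  expect_lt(th1@w1, 1e-10)
  # monotone: smaller alpha, larger u
  expect_gt(thresholdsFromAlpha(0.005, 1)@u, thresholdsFromAlpha(0.1, 1)@u)
  expect_error(thresholdsFromAlpha(0, 1), "alpha")
  expect_error(thresholdsFromAlpha(1, 1), "alpha")
})

test_that("zeroOutliers expands across w2-neighbours and spares isolated mid-band", {
  w1 <- 3; w2 <- 1
  # run traced by hand: trigger at 1.2*w1 expands over the 0.8*w1 neighbours
  w <- c(0, 0.8 * w1, 1.2 * w1, 0.8 * w1, 0.3 * w2, 0.5)
  expect_equal(zeroOutliers(w, w1, w2), c(0, 0, 0, 0, 0.3 * w2, 0.5))
  # all below w2: untouched
  expect_equal(zeroOutliers(c(0.1, -0.5, 0.9), w1, w2), c(0.1, -0.5, 0.9))
  # isolated coefficient between the thresholds is kept
  iso <- c(0.1, 0.9 * w1, 0.2, 1.1 * w1, 0.2)
  out <- zeroOutliers(iso, w1, w2)
  expect_equal(out, c(0.1, 0.9 * w1, 0.2, 0, 0.2))
  # signs are irrelevant to the magnitude rule
  expect_equal(zeroOutliers(-w, w1, w2), -c(0, 0, 0, 0, 0.3 * w2, 0.5))
  expect_error(zeroOutliers(w, 1, 3), "w1 >= w2")
})

test_that("cycle-spun denoising is the identity when nothing crosses w1", {
  set.seed(15)
  x <- rnorm(2048)  # Gaussian coefficients: max |w| ~ 4 sigma << u(1e-12) sigma
  y <- dualThresholdDenoise(x, runConfig(alpha = 1e-12, K = 8))
  expect_lt(max(abs(y - x)) / max(abs(x)), 1e-8)
  # constant input stays constant
  yc <- dualThresholdDenoise(rep(2, 1024), runConfig(K = 4))
  expect_equal(yc, rep(2, 1024), tolerance = 1e-9)
})

test_that("cycle-spun denoising removes spikes while preserving the band signal", {
  cl <- sigValues(generateClean(600, 10, seed = 21,
                                cardiacAmp = 0, respAmp = 0))
  sp <- numeric(6000)
  for (s0 in c(1000, 3000, 5000)) {
    i <- s0:(s0 + 19); t2 <- (i - s0) / 10
    sp[i] <- 10 * sin(2 * pi * 2 * t2) * exp(-0.5 * ((t2 - 1) / 0.33)^2)
  }
  den <- dualThresholdDenoise(cl + sp, runConfig(), fs = 10)
  resid <- den - cl
  spikeIdx <- c(1000:1019, 3000:3019, 5000:5019)
  expect_lt(max(abs(resid[spikeIdx])), 0.1 * max(abs(sp)))
  expect_gt(cor(den, cl), 0.95)
})

test_that("denoising output length always matches the input", {
  for (n in c(300L, 1000L, 6000L)) {
    x <- rnorm(n)
    expect_length(dualThresholdDenoise(x, runConfig(K = 2)), n)
  }
})
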