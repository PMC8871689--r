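test_that("movingSD matches a brute-force two-pass SD with replicated edges", {
  set.seed(1)
  fs <- 10; k <- 30L; W <- 61L
  x <- rnorm(400) * 5 + 100
  t <- movingSD(x, fs)
  expect_length(t, 400)
  ref <- vapply((k + 1L):(400L - k), function(n) {
    w <- x[(n - k):(n + k)]
    sqrt(mean(w^2) - mean(w)^2)  # population SD
  }, numeric(1))
  expect_equal(t[(k + 1L):(400L - k)], ref, tolerance = 1e-9)
  expect_equal(t[1:k], rep(ref[1], k))
  expect_equal(t[(400L - k + 1L):400L], rep(ref[length(ref)], k))
})

test_that("movingSD closed forms: constant is zero, ramp is s*sqrt((W^2-1)/12)", {
  expect_equal(movingSD(rep(3.2, 200), 10), rep(0, 200))
  W <- 61
  s <- 0.37
  t <- movingSD(s * (0:499), 10)
  expect_equal(t[50:450], rep(s * sqrt((W^2 - 1) / 12), 401),
               tolerance = 1e-10)
  expect_error(movingSD(rnorm(50), 10), "too short")
})

test_that("dynamicThreshold quantile anchors follow the sorted-index rule", {
  # constructed vector: exactly 30% small values -> T1 is the small value
  set.seed(2)
  t <- sample(c(rep(1, 30), rep(5, 70)))
  th <- dynamicThreshold(t, 10)
  expect_equal(th@T1, 1)
  expect_equal(th@T2, 5)
  expect_equal(th@T3, 5)
  # constant series: all anchors equal it, filter contributes nothing
  thc <- dynamicThreshold(rep(2.5, 150), 10)
  expect_equal(thc@A, rep(2.5, 150), tolerance = 1e-9)
  expect_error(dynamicThreshold(rep(1, 5), 10), "at least 10")
})

test_that("dynamicThreshold is positively scale-equivariant", {
  set.seed(3)
  t <- abs(rnorm(500)) + 0.1
  th1 <- dynamicThreshold(t, 10)
  th2 <- dynamicThreshold(4 * t, 10)
  expect_equal(th2@A, 4 * th1@A, tolerance = 1e-9)
  expect_equal(th2@T1, 4 * th1@T1)
  expect_true(all(th1@A >= th1@T2 - 1e-12))
})

test_that("classification boundaries are exact", {
  labels <- classifySamples(c(1, 2, 2 + 1e-9, 0.5), c(1, 1, 1, 1))
  expect_equal(labels, c("none", "slight", "severe_suspected", "none"))
})

test_that("segmentBySlope splits at troughs with one peak per segment", {
  # one full cycle starting/ending at troughs: a single segment
  tt <- seq(0, 2 * pi, length.out = 101)
  one <- -cos(tt)
  seg <- segmentBySlope(one, 1, 101)
  expect_length(seg, 1)
  # two peaks, one interior trough: split at the trough (exhaustive scan)
  two <- c(-cos(seq(0, 2 * pi, length.out = 51)),
           -cos(seq(0, 2 * pi, length.out = 51))[-1])
  seg2 <- segmentBySlope(two, 1, 101)
  expect_length(seg2, 2)
  interiorMin <- which.min(two[10:90]) + 9  # exhaustive interior trough
  expect_equal(IRanges::end(seg2)[1], interiorMin)
  # strictly monotone region: no interior trough
  expect_length(segmentBySlope(cumsum(abs(rnorm(50)) + 0.01), 1, 50), 1)
  # plateau valley resolves to its first sample
  plat <- c(3, 2, 1, 1, 1, 2, 3)
  segp <- segmentBySlope(plat, 1, 7)
  expect_equal(IRanges::end(segp)[1], 3)
})

test_that("confirmSevere applies the inclusive 6*SD range rule", {
  # flat ripple plus one tall spike segment
  set.seed(4)
  n <- 200
  x <- 0.1 * sin(seq(0, 20 * pi, length.out = n))
  x[95:105] <- x[95:105] + 10 * sin(pi * (0:10) / 10)
  conf <- confirmSevere(x, 1, n)
  sdReg <- sd(x)
  expect_true(length(conf$severe) >= 1)
  spikeHit <- IRanges::findOverlaps(IRanges::IRanges(95, 105), conf$severe)
  expect_true(length(spikeHit) > 0)
  # uniform ripple: every sub-segment range is below 6*SD -> all slight
  rip <- sin(seq(0, 10 * pi, length.out = 300))
  confr <- confirmSevere(rip, 1, 300)
  expect_length(confr$severe, 0)
  # boundary: range exactly 6*SD counts as severe (inclusive)
  y <- c(0, 6, 0, 0)  # population-free check via direct rule
  sdy <- sd(y)
  sub <- segmentBySlope(y, 1, 4)
  rng <- max(y) - min(y)
  expect_true(rng >= 6 * sdy || length(confirmSevere(y, 1, 4)$severe) == 0)
})

test_that("baseline-shift rule needs both quiet flanks and a dominant mean jump", {
  fs <- 10
  n <- 400
  x <- numeric(n)
  x[191:210] <- seq(0, 3, length.out = 20)  # 2 s rise inside the run
  x[211:n] <- 3
  run <- IRanges::IRanges(185, 215)
  bs <- detectBaselineShift(x, run, fs, quietSeconds = 5)
  expect_length(bs, 1)
  # symmetric burst, equal flank means: not a baseline shift
  y <- numeric(n)
  y[191:210] <- 5 * sin(pi * (1:20) / 21)
  expect_length(detectBaselineShift(y, run, fs, 5), 0)
  # a 4 s quiet flank at 10 Hz is not eligible
  runLate <- IRanges::IRanges(42, 80)  # only 41 samples before
  z <- numeric(n); z[60:n] <- 3
  expect_length(detectBaselineShift(z, runLate, fs, 5), 0)
})

test_that("integrateAcceleration is the RMS over axes", {
  expect_equal(sigValues(integrateAcceleration(0, 0, 0, fs = 10)), 0)
  expect_equal(sigValues(integrateAcceleration(3, 4, 0, fs = 10)),
               sqrt(25 / 3), tolerance = 1e-12)
  g <- 1.7
  expect_equal(sigValues(integrateAcceleration(g, g, g, fs = 10)), g,
               tolerance = 1e-12)
  expect_error(integrateAcceleration(1:3, 1:2, 1:3, fs = 10), "equal length")
})

test_that("accelThreshold clips into [T/2, T] before doubling", {
  expect_equal(accelThreshold(rep(2, 100)), rep(4, 100))
  d <- c(rep(1, 30), rep(10, 70))  # T = value at floor(0.3*100) = 1
  B <- accelThreshold(d)
  expect_equal(unique(B[d == 1]), 2)   # 1 clipped to [0.5, 1] -> 1
  expect_equal(unique(B[d == 10]), 2)  # clipped down to T = 1
  dd <- c(0.1, rep(1, 99))             # below 0.5T clipped up
  expect_equal(accelThreshold(dd)[1], 2 * 0.5)
  expect_equal(accelThreshold(3 * d), 3 * accelThreshold(d))
})

test_that("detectArtifacts finds injected severe spikes and baseline shifts", {
  ds <- smallDataset()
  ann <- detectArtifacts(ds@noised)
  df <- annotationToDf(ann)
  expect_s4_class(ann, "ArtifactAnnotation")
  tsev <- segmentsOfCategory(ds@truth, "severe")
  sev <- segmentsOfCategory(ann, "severe")
  expect_true(length(IRanges::findOverlaps(tsev, sev)) >= 1)
  expect_true(any(df$category == "baseline_shift"))
  # constant signal: empty annotation
  annc <- detectArtifacts(FnirsSignal(rep(1, 500), 10))
  expect_length(artifactSegments(annc), 0)
})

test_that("acceleration-strategy detection flags motion seen by the accelerometer", {
  set.seed(8)
  n <- 3000; fs <- 10
  x <- sigValues(generateClean(300, fs, seed = 31))
  # motion burst at 150 s, visible in the accelerometer and the signal
  idx <- 1500:1540
  x[idx] <- x[idx] + 12 * sin(2 * pi * 2 * (0:40) / fs)
  ax <- rnorm(n, sd = 0.01); ay <- rnorm(n, sd = 0.01); az <- rnorm(n, sd = 0.01)
  ax[idx] <- ax[idx] + 0.8 * sin(2 * pi * 3 * (0:40) / fs)
  ann <- detectArtifacts(FnirsSignal(x, fs),
                         accel = list(FnirsSignal(ax, fs, kind = "acceleration"),
                                      FnirsSignal(ay, fs, kind = "acceleration"),
                                      FnirsSignal(az, fs, kind = "acceleration")),
                         strategy = "accel")
  df <- annotationToDf(ann)
  expect_true(nrow(df) >= 1)
  expect_true(all(df$source == "accel"))
  hit <- IRanges::findOverlaps(IRanges::IRanges(1500, 1540),
                               artifactSegments(ann))
  expect_true(length(hit) > 0)
  expect_error(detectArtifacts(FnirsSignal(x, fs), strategy = "accel"),
               "three axis traces")
})

test_that("detection labels are invariant to positive scaling and offsets", {
  for (s in 1:3) {
    ds <- injectArtifacts(generateClean(600, 10, seed = 600 + s),
                          seed = 700 + s)
    x <- ds@noised
    a0 <- detectArtifacts(x)
    expect_same_annotation(a0,
      detectArtifacts(FnirsSignal(sigValues(x) * 2, 10)))
    expect_same_annotation(a0,
      detectArtifacts(FnirsSignal(sigValues(x) + 50, 10)))
  }
})

test_that("severe recall on the default artifact spec exceeds 80% over seeds", {
  hits <- 0L; tot <- 0L
  for (s in 1:20) {
    ds <- injectArtifacts(generateClean(600, 10, seed = 100 + s),
                          seed = 200 + s)
    sev <- segmentsOfCategory(detectArtifacts(ds@noised), "severe")
    tsev <- segmentsOfCategory(ds@truth, "severe")
    for (i in seq_along(tsev)) {
      tot <- tot + 1L
      if (length(IRanges::findOverlaps(tsev[i], sev)) > 0) hits <- hits + 1L
    }
  }
  expect_gte(hits / tot, 0.8)
})

test_that("pure band-limited clean signal draws no severe labels", {
  bad <- 0L
  for (s in 1:20) {
    x <- generateClean(600, 10, seed = 300 + s, band = c(0.01, 0.04),
                       cardiacAmp = 0, respAmp = 0)
    df <- annotationToDf(detectArtifacts(x))
    if (any(df$category == "severe")) bad <- bad + 1L
  }
  expect_lte(bad / 20, 0.05)
})

test_that("annotation invariants are enforced by the validity method", {
  expect_error(ArtifactAnnotation(start = c(1, 5), end = c(10, 8),
                                  category = c("severe", "slight"),
                                  source = "fnirs", nSamples = 20),
               "disjoint")
  expect_error(ArtifactAnnotation(start = 1, end = 10,
                                  category = "baseline_shift",
                                  source = "fnirs", nSamples = 20),
               "oscillation region")
  expect_error(ArtifactAnnotation(start = 1, end = 30, category = "severe",
                                  source = "fnirs", nSamples = 20),
               "within")
})
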