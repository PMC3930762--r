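test_that("local maxima detection handles empty and constructed cases", {
  p <- defaultParameters(intensity_threshold = 5)
  expect_length(localMaxima(makeMeasurement(matrix(0, 20, 20)), p), 0L)

  ## one discrete blob with a supra-threshold footprint of >= 9 cells
  S <- bellMatrix(40, 50, 20, 30, 100, 2.5, 2.5)
  cand <- peaks(localMaxima(makeMeasurement(S), p))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$retention_time_index, 20L)
  expect_equal(cand$inverse_reduced_mobility_index, 30L)
  expect_equal(cand$signal, 100)

  ## an 8-cell supra-threshold component fails the area test at A = 9
  S <- matrix(0, 15, 15)
  S[7:8, 7:10] <- c(6, 5, 9, 5, 7, 5, 6, 5)   # 8 cells >= 5, apex 9
  expect_length(localMaxima(makeMeasurement(S), p), 0L)
})

test_that("local maxima equal the exhaustive scan oracle on random matrices", {
  p <- defaultParameters(intensity_threshold = 8)
  set.seed(31)
  for (rep in 1:4) {
    S <- matrix(sample(0:12, 50 * 50, replace = TRUE), 50, 50)
    S <- round(localAverage(S, 1) * 3)      # induce plateaus and blobs
    got <- peaks(localMaxima(makeMeasurement(S), p))
    want <- bruteLocalMaxima(S, I = 8, Amin = 9)
    gotCells <- if (nrow(got)) paste(got$retention_time_index,
                                     got$inverse_reduced_mobility_index)
                else character(0)
    wantCells <- if (!is.null(want)) paste(want[, 1], want[, 2])
                 else character(0)
    expect_setequal(gotCells, wantCells)
  }
})

test_that("every reported candidate meets the intensity threshold", {
  p <- defaultParameters(intensity_threshold = 10)
  set.seed(32)
  S <- round(bellMatrix(60, 60, 30, 30, 50, 6, 6) +
               matrix(runif(3600, 0, 4), 60, 60))
  m <- makeMeasurement(S)
  expect_true(all(peaks(localMaxima(m, p))$signal >= 10))
  expect_true(all(peaks(crossFind(m, p))$signal > 10))
})

test_that("active-position alignment reproduces the printed scoring", {
  al <- alignActivePositions(10, 10)
  expect_equal(nrow(al$pairs), 1L)
  expect_equal(al$score, 1.0)               # (1 + 0)^-1
  ## distance > 9 index units is never aligned
  al <- alignActivePositions(10, 25)
  expect_equal(nrow(al$pairs), 0L)
  expect_equal(al$score, 0.2)               # two gap scores
  al <- alignActivePositions(c(5, 40), c(7, 38, 90))
  expect_equal(al$pairs[, "a"], c(1L, 2L), ignore_attr = TRUE)
  expect_equal(al$pairs[, "b"], c(1L, 2L), ignore_attr = TRUE)
  expect_equal(al$score, 2 / 3 + 0.1)
})

test_that("alignment is optimal versus exhaustive monotone-pairing search", {
  set.seed(33)
  for (rep in 1:25) {
    a <- sort(sample(0:40, sample(0:6, 1)))
    b <- sort(sample(0:40, sample(0:6, 1)))
    al <- alignActivePositions(a, b)
    expect_equal(al$score, bruteAlignScore(a, b), tolerance = 1e-12)
    if (nrow(al$pairs)) {
      expect_true(all(diff(al$pairs[, "a"]) > 0))   # order-preserving
      expect_true(all(diff(al$pairs[, "b"]) > 0))
      expect_true(all(abs(a[al$pairs[, "a"]] - b[al$pairs[, "b"]]) <= 9))
      recomputed <- sum(1 / (1 + abs(a[al$pairs[, "a"]] -
                                       b[al$pairs[, "b"]]))) +
        0.1 * (length(a) + length(b) - 2 * nrow(al$pairs))
      expect_equal(al$score, recomputed, tolerance = 1e-12)
    }
  }
})

test_that("cross finding marks apexes and ignores monotone ramps", {
  p <- defaultParameters(intensity_threshold = 5)
  ramp <- outer(1:30, 1:30, `+`)
  expect_length(crossFind(makeMeasurement(ramp), p), 0L)

  S <- bellMatrix(50, 60, 25, 35, 80, 4, 5)
  cand <- peaks(crossFind(makeMeasurement(S), p))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$retention_time_index, 25L)
  expect_equal(cand$inverse_reduced_mobility_index, 35L)

  S2 <- bellMatrix(120, 120, 30, 30, 80, 4, 4) +
    bellMatrix(120, 120, 80, 80, 60, 4, 4)
  cand2 <- peaks(crossFind(makeMeasurement(S2), p))
  expect_equal(nrow(cand2), 2L)
  expect_setequal(paste(cand2$retention_time_index,
                        cand2$inverse_reduced_mobility_index),
                  c("30 30", "80 80"))
})

test_that("both detectors localize well-separated planted peaks within tolerance", {
  sim <- simulateIMSC(simulationConfig(
    m = 200, n = 300, rMax = 200, tMax = 1.45, ripIntensity = 0,
    baselineLevel = 0, baselineVariation = 0, noiseSd = 1,
    peaks = data.frame(r = c(50, 150), t = c(0.6, 1.1),
                       amplitude = c(300, 400), r_sd = c(4, 5),
                       t_sd = c(0.02, 0.02), skew = 0.3),
    seed = 34))
  p <- defaultParameters(intensity_threshold = 30)
  truth <- peaks(sim$truth)
  for (det in list(localMaxima, crossFind)) {
    cand <- peaks(det(sim$measurement, p))
    for (i in 1:2) {
      d <- abs(cand$retention_time - truth$retention_time[i]) <=
        deltaR(truth$retention_time[i]) &
        abs(cand$inverse_reduced_mobility -
              truth$inverse_reduced_mobility[i]) <= 0.003
      expect_true(any(d))
    }
  }
})
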