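test_that("IMSC CSV round-trip is lossless", {
  set.seed(11)
  S <- matrix(sample(0:4095, 30 * 12, replace = TRUE), 30, 12)
  m <- IMSMeasurement("probe-1", seq(0, 29, by = 1) * 0.5,
                      seq(0.3, by = 0.0012, length.out = 12), S,
                      metadata = list(date = "2026-01-01", sample = "air"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeIMSC(m, path)
  m2 <- readIMSC(path)
  expect_equal(measurementName(m2), "probe-1")
  expect_equal(retentionTimes(m2), retentionTimes(m))
  expect_equal(inverseMobilities(m2), inverseMobilities(m))
  expect_identical(intensities(m2), intensities(m) * 1.0)
  expect_equal(measurementMetadata(m2)$sample, "air")
})

test_that("a literal 2x2 IMSC file reads back verbatim and name falls back to the stem", {
  path <- file.path(withr::local_tempdir(), "tiny.csv")
  writeLines(c("0.4,0.5", "0,0,1", "100,2,3"), path)
  m <- readIMSC(path)
  expect_equal(measurementName(m), "tiny")
  expect_equal(retentionTimes(m), c(0, 100))
  expect_equal(inverseMobilities(m), c(0.4, 0.5))
  expect_equal(intensities(m), matrix(c(0, 2, 1, 3), 2, 2))
})

test_that("malformed IMSC files raise parse errors naming the line", {
  dir <- withr::local_tempdir()
  ragged <- file.path(dir, "ragged.csv")
  writeLines(c("# name=x", "0.4,0.5,0.6", "0,1,2,3,4"), ragged)
  expect_error(readIMSC(ragged), "line 3.*expected 4 fields")
  bad <- file.path(dir, "bad.csv")
  writeLines(c("0.4,0.5", "0,1,oops"), bad)
  expect_error(readIMSC(bad), "non-numeric")
})

test_that("raw-mode negative intensities warn but are written as-is", {
  S <- matrix(c(-3L, 1L, 2L, 4L), 2, 2)
  m <- makeMeasurement(S)
  path <- withr::local_tempfile(fileext = ".csv")
  expect_warning(writeIMSC(m, path), "negative")
  expect_equal(intensities(readIMSC(path))[1, 1], -3)
})

test_that("peak list CSV has the documented column order and round-trips", {
  pl <- peakListFromCoords(c(12, 80), c(0.55, 0.72), c(100, 40),
                           ri = c(3L, 9L), ti = c(150L, 320L))
  path <- withr::local_tempfile(fileext = ".csv")
  writePeakList(pl, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_identical(header,
    c("measurement_name", "peak_name", "retention_time",
      "inverse_reduced_mobility", "signal", "volume",
      "retention_time_index", "inverse_reduced_mobility_index"))
  expect_length(strsplit(readLines(path)[2], ",")[[1]], 8L)
  pl2 <- readPeakList(path)
  expect_equal(peaks(pl2), peaks(pl))

  ## extra model parameters extend the line, keys from parameterNames
  df <- peaks(pl)
  extras <- sprintf("par%d", 1:7)
  for (p in extras) df[[p]] <- seq_len(nrow(df)) * 0.1
  plx <- IMSPeakList(df, parameterNames = extras)
  writePeakList(plx, path)
  expect_length(strsplit(readLines(path)[2], ",")[[1]], 15L)
  expect_equal(parameterNames(readPeakList(path)), extras)
})

test_that("empty peak lists write a header-only file", {
  path <- withr::local_tempfile(fileext = ".csv")
  writePeakList(IMSPeakList(), path)
  expect_length(readLines(path), 1L)
  expect_equal(length(readPeakList(path)), 0L)
})

test_that("annotation files without indices snap to the grid or use the -1 sentinel", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "measurement_name,peak_name,retention_time,inverse_reduced_mobility,signal",
    "fix,a,10.4,0.4025,50",
    "fix,b,2.0,0.409,20"), path)
  bare <- readPeakList(path)
  expect_equal(peaks(bare)$retention_time_index, c(-1L, -1L))
  expect_equal(peaks(bare)$volume, peaks(bare)$signal)
  m <- makeMeasurement(matrix(0, 21, 10))   # r = 0..20, t = 0.4, 0.401, ...
  snapped <- readPeakList(path, measurement = m)
  expect_equal(peaks(snapped)$retention_time_index, c(11L, 3L))
  expect_equal(peaks(snapped)$inverse_reduced_mobility_index, c(3L, 10L))
})

test_that("duplicate peak names are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "measurement_name,peak_name,retention_time,inverse_reduced_mobility,signal",
    "fix,a,10,0.5,50", "fix,a,20,0.6,20"), path)
  expect_error(readPeakList(path), "duplicate")
})

test_that("mobility tolerance converts to index units as printed", {
  expect_identical(rimToleranceIndices(0.003, 2500, 1.45), 5L)
  expect_identical(rimToleranceIndices(0, 2500, 1.45), 0L)
  expect_identical(rimToleranceIndices(0.003, 1000, 1.45), 2L)
  expect_error(rimToleranceIndices(0.003, 2500, 0), "tMax")
  ## monotone in tolerance and grid size
  grid <- seq(0, 0.01, by = 0.001)
  vals <- vapply(grid, rimToleranceIndices, integer(1),
                 nPoints = 2500, tMax = 1.45)
  expect_true(all(diff(vals) >= 0))
  ns <- seq(500, 5000, by = 250)
  vals <- vapply(ns, function(n) rimToleranceIndices(0.003, n, 1.45),
                 integer(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("measurement and peak list validity catches broken objects", {
  expect_error(IMSMeasurement("x", c(1, 1), c(0.4, 0.5),
                              matrix(0, 2, 2)), "strictly increasing")
  expect_error(IMSMeasurement("x", c(0, 1), c(0.4, 0.5),
                              matrix(0, 3, 2)), "dimensions")
  df <- peaks(peakListFromCoords(c(1, 2), c(0.5, 0.6), c(1, 1)))
  df$peak_name <- c("a", "a")
  expect_error(IMSPeakList(df), "unique")
})
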