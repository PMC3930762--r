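test_that("the retention-time tolerance is affine-linear in r", {
  expect_equal(deltaR(0), 3)
  expect_equal(deltaR(100), 13)
  r <- sort(runif(20, 0, 600))
  expect_true(all(diff(deltaR(r)) > 0))
})

test_that("the normalized squared distance matches the printed formula", {
  tol <- toleranceParams()
  expect_equal(candidateDistanceSq(10, 0.5, 10, 0.5, tol), 0)
  ## both differences at tolerance: d2 = 1
  r <- 100; dr <- deltaR(r, tol)          # deltaR at the pair mean
  r1 <- r - dr / 2; r2 <- r + dr / 2
  expect_equal(candidateDistanceSq(r1, 0.5, r2, 0.5 + tol$tol_rim, tol), 1)
  expect_equal(candidateDistanceSq(10, 0.5, 10, 0.5 + tol$tol_rim, tol), 0.5)
  ## symmetry
  expect_equal(candidateDistanceSq(10, 0.5, 40, 0.52, tol),
               candidateDistanceSq(40, 0.52, 10, 0.5, tol))
})

test_that("similarity weights follow the piecewise definition", {
  expect_equal(similarityWeight(0, 26), 2^26 - 1)
  expect_equal(similarityWeight(0, 26), 67108863)
  expect_equal(similarityWeight(1, 26), 0)
  expect_equal(similarityWeight(2, 26), -1)
  expect_equal(similarityWeight(0.5, 3), 2^3 * 0.5 - 1)
})

test_that("merging by intensity keeps the strongest peak per box", {
  p <- defaultParameters()
  one <- peakListFromCoords(10, 0.5, 100)
  expect_equal(peaks(mergeByIntensity(one, p)), peaks(one))

  two <- peakListFromCoords(c(10, 11), c(0.500, 0.501), c(100, 90))
  out <- peaks(mergeByIntensity(two, p))
  expect_equal(nrow(out), 1L)
  expect_equal(out$signal, 100)

  far <- peakListFromCoords(c(10, 60), c(0.5, 0.5), c(100, 90))
  out <- peaks(mergeByIntensity(far, p))
  expect_equal(nrow(out), 2L)
  expect_equal(out$signal, c(100, 90))      # descending signal
})

test_that("the cluster-editing solver is exact on forced and enumerable cases", {
  expect_equal(solveClusterEditing(matrix(0, 1, 1))$membership, 1L)
  Wpos <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_equal(length(unique(solveClusterEditing(Wpos)$membership)), 1L)
  Wneg <- matrix(c(0, -5, -5, 0), 2, 2)
  expect_equal(length(unique(solveClusterEditing(Wneg)$membership)), 2L)

  set.seed(41)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- round(runif(n * (n - 1) / 2, -10, 10), 1)
    W <- W + t(W)
    sol <- solveClusterEditing(W)
    expect_equal(sol$status, "exact")
    expect_equal(sol$cost, bruteClusterEditingCost(W), tolerance = 1e-9)
  }
})

test_that("cluster-editing picking merges coincident and keeps distant candidates", {
  p <- defaultParameters()
  co <- peakListFromCoords(c(10, 10), c(0.5, 0.5), c(100, 80))
  out <- peaks(clusterEditPick(co, p))
  expect_equal(nrow(out), 1L)
  expect_equal(out$signal, 100)

  tol <- toleranceParams(p)
  apart <- peakListFromCoords(c(10, 10), c(0.5, 0.5 + 2 * tol$tol_rim),
                              c(100, 80))   # d2 = 2, w = -1
  expect_equal(nrow(peaks(clusterEditPick(apart, p))), 2L)

  ## three collinear candidates: result matches the partition oracle cost
  tri <- peakListFromCoords(c(10, 10, 10),
                            c(0.5, 0.5 + tol$tol_rim, 0.5 + 2 * tol$tol_rim),
                            c(100, 90, 80))
  df <- peaks(tri)
  D2 <- outer(seq_len(3), seq_len(3), function(i, j)
    candidateDistanceSq(df$retention_time[i], df$inverse_reduced_mobility[i],
                        df$retention_time[j], df$inverse_reduced_mobility[j],
                        tol))
  W <- similarityWeight(D2, p$ce_weight_exponent); diag(W) <- 0
  sol <- solveClusterEditing(W)
  expect_equal(sol$cost, bruteClusterEditingCost(W), tolerance = 1e-9)
})

test_that("EM clustering merges close candidates and keeps distant ones", {
  p <- defaultParameters()
  tol <- toleranceParams(p)
  one <- peakListFromCoords(10, 0.5, 100)
  expect_equal(peaks(emClusterPick(one, p)), peaks(one))

  close <- peakListFromCoords(
    c(10, 10 + 0.1 * deltaR(10, tol)), c(0.5, 0.5 + 0.1 * tol$tol_rim),
    c(100, 80))
  out <- peaks(emClusterPick(close, p))
  expect_equal(nrow(out), 1L)
  expect_equal(out$signal, 100)

  far <- peakListFromCoords(
    c(10, 10 + 10 * deltaR(10, tol)), c(0.5, 0.5 + 10 * tol$tol_rim),
    c(100, 80))
  expect_equal(nrow(peaks(emClusterPick(far, p))), 2L)
})

test_that("all pickers agree when candidates are far apart", {
  p <- defaultParameters()
  cands <- peakListFromCoords(
    r = c(10, 120, 300), t = c(0.5, 0.8, 1.2), signal = c(50, 80, 40),
    ri = c(10L, 120L, 300L), ti = c(100L, 400L, 800L))
  keyOf <- function(pl) paste(peaks(pl)$retention_time,
                              peaks(pl)$inverse_reduced_mobility)
  ms <- keyOf(mergeByIntensity(cands, p))
  ce <- keyOf(clusterEditPick(cands, p))
  emc <- keyOf(emClusterPick(cands, p))
  expect_setequal(ms, keyOf(cands))
  expect_setequal(ce, keyOf(cands))
  expect_setequal(emc, keyOf(cands))
})

test_that("picker outputs are subsets of their inputs", {
  set.seed(42)
  n <- 15
  cands <- peakListFromCoords(
    r = runif(n, 0, 100), t = runif(n, 0.5, 1.2),
    signal = round(runif(n, 10, 200)),
    ri = sample.int(500, n), ti = sample.int(2000, n))
  keys <- paste(peaks(cands)$retention_time, peaks(cands)$signal)
  for (pick in list(mergeByIntensity, clusterEditPick, emClusterPick)) {
    out <- peaks(pick(cands, defaultParameters()))
    expect_lte(nrow(out), n)
    expect_true(all(paste(out$retention_time, out$signal) %in% keys))
    expect_true(all(diff(out$signal) <= 0))
  }
})
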