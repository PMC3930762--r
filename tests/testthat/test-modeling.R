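test_that("the shifted Inverse Gaussian density, mode and moments are consistent", {
  expect_equal(shiftedInvGaussPdf(c(2.5, 3), mu = 2, lambda = 5, offset = 3),
               c(0, 0))
  ## integral over the support is 1
  expect_equal(stats::integrate(shiftedInvGaussPdf, 3, Inf, mu = 2,
                                lambda = 5, offset = 3,
                                rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
  ## closed-form mode equals the numeric argmax of the density
  mom <- shiftedInvGaussMoments(mu = 2, lambda = 5, offset = 3)
  grid <- seq(3.0001, 8, by = 1e-4)
  expect_equal(mom[["mode"]],
               grid[which.max(shiftedInvGaussPdf(grid, 2, 5, 3))],
               tolerance = 1e-3)
  expect_equal(mom[["mean"]], 5)
  expect_equal(mom[["sd"]], sqrt(8 / 5))
})

test_that("moment inversion round-trips through the parameterization", {
  for (case in list(c(50, 50.3, 4), c(10, 10.001, 1), c(100, 103, 10))) {
    p <- shiftedInvGaussFromMoments(case[1], case[2], case[3])
    mom <- shiftedInvGaussMoments(p$mu, p$lambda, p$offset)
    expect_equal(mom[["mode"]], case[1], tolerance = 1e-6)
    expect_equal(mom[["mean"]], case[2], tolerance = 1e-6)
    expect_equal(mom[["sd"]], case[3], tolerance = 1e-6)
  }
})

test_that("box expansion walks to the zero rim, widens, clips and merges", {
  S <- matrix(0, 40, 40)
  S[17:23, 17:23] <- 5                      # zeros at distance 4 from (20, 20)
  m <- makeMeasurement(S)
  pl <- peakListFromCoords(19, 0.419, 5, ri = 20L, ti = 20L)
  boxes <- expandBoxes(m, pl, expansionSize = 10)
  expect_length(boxes, 1L)
  expect_equal(boxes[[1]][c("rLo", "rHi", "tLo", "tHi")],
               list(rLo = 7L, rHi = 33L, tLo = 7L, tHi = 33L))
  ## clipping at the matrix border
  pl2 <- peakListFromCoords(1, 0.402, 5, ri = 2L, ti = 3L)
  S2 <- matrix(1, 10, 10)
  b2 <- expandBoxes(makeMeasurement(S2), pl2, expansionSize = 4)
  expect_equal(b2[[1]][c("rLo", "rHi", "tLo", "tHi")],
               list(rLo = 1L, rHi = 10L, tLo = 1L, tHi = 10L))
  ## overlapping boxes merge into one bounding rectangle with both members
  plb <- peakListFromCoords(c(19, 21), c(0.419, 0.421), c(5, 5),
                            ri = c(20L, 22L), ti = c(20L, 22L))
  bb <- expandBoxes(m, plb, expansionSize = 10)
  expect_length(bb, 1L)
  expect_setequal(bb[[1]]$members, c(1L, 2L))
  expect_length(expandBoxes(m, IMSPeakList(), 10), 0L)
})

test_that("the empty modeling module is the identity", {
  pl <- peakListFromCoords(c(10, 20), c(0.5, 0.6), c(9, 5))
  expect_identical(emptyModel(pl), pl)
  expect_identical(emptyModel(IMSPeakList()), IMSPeakList())
})

test_that("peak model estimation recovers an isolated synthetic peak", {
  ## intensity-weighted sample from a known separable shifted-IG product
  modeR <- 60; sdR <- 5; modeT <- 55; sdT <- 8
  pr <- shiftedInvGaussFromMoments(modeR, modeR + 0.3 * sdR, sdR)
  pt <- shiftedInvGaussFromMoments(modeT, modeT + 0.3 * sdT, sdT)
  profR <- shiftedInvGaussPdf(1:120, pr$mu, pr$lambda, pr$offset)
  profT <- shiftedInvGaussPdf(1:120, pt$mu, pt$lambda, pt$offset)
  S <- round(500 * outer(profR / max(profR), profT / max(profT)))
  m <- makeMeasurement(S)
  pl <- peakListFromCoords(retentionTimes(m)[modeR],
                           inverseMobilities(m)[modeT],
                           S[modeR, modeT], ri = modeR, ti = as.integer(modeT))
  out <- fitPeakModels(m, pl, defaultParameters())
  expect_equal(length(out), 1L)
  df <- peaks(out)
  expect_lt(abs(df$r_mode - modeR), 1)
  expect_lt(abs(df$t_mode - modeT), 1)
  expect_lt(abs(df$r_sd - sdR) / sdR, 0.2)
  expect_lt(abs(df$t_sd - sdT) / sdT, 0.2)
  expect_true(df$model_omega > 0 && df$model_omega <= 1)
  ## volume = omega * box intensity, coordinates moved to the modeled mode
  expect_gt(df$volume, 0)
  expect_equal(df$retention_time, retentionTimes(m)[round(df$r_mode)],
               tolerance = 0.02)
})

test_that("two overlapping peaks in one merged box are both recovered", {
  mk <- function(mode, sd) shiftedInvGaussFromMoments(mode, mode + 0.3 * sd, sd)
  p1r <- mk(40, 4); p1t <- mk(50, 6); p2r <- mk(58, 4); p2t <- mk(62, 6)
  prof <- function(p, n) shiftedInvGaussPdf(1:n, p$mu, p$lambda, p$offset)
  S <- 600 * outer(prof(p1r, 100) / max(prof(p1r, 100)),
                   prof(p1t, 110) / max(prof(p1t, 110))) +
       500 * outer(prof(p2r, 100) / max(prof(p2r, 100)),
                   prof(p2t, 110) / max(prof(p2t, 110)))
  S <- round(S)
  m <- makeMeasurement(S)
  pl <- peakListFromCoords(retentionTimes(m)[c(40, 58)],
                           inverseMobilities(m)[c(50, 62)],
                           c(600, 500), ri = c(40L, 58L), ti = c(50L, 62L))
  out <- peaks(fitPeakModels(m, pl, defaultParameters()))
  expect_equal(nrow(out), 2L)
  expect_lt(abs(out$r_mode[1] - 40), 2)
  expect_lt(abs(out$t_mode[1] - 50), 2)
  expect_lt(abs(out$r_mode[2] - 58), 2)
  expect_lt(abs(out$t_mode[2] - 62), 2)
})

test_that("modeling preserves list size and annotates the model schema", {
  out <- fitPeakModels(makeMeasurement(matrix(0, 10, 10)), IMSPeakList(),
                       defaultParameters())
  expect_equal(length(out), 0L)
  expect_true(all(c("model_omega", "r_mu", "t_sd") %in% parameterNames(out)))
})
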