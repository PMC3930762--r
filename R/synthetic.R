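## Seeded generator of synthetic IMSC measurements with planted ground
## truth: a per-mobility baseline, a reactant ion peak (RIP) chromatogram
## near t = 0.48 Vs/cm2, additive Gaussian noise, and 2D analyte peaks shaped
## as separable products of shifted Inverse Gaussian profiles, quantized to
## unsigned 12-bit intensities (0..4095). This is the test bed standing in
## for real clinical measurements, which are not distributable.

#' Simulation configuration
#'
#' @param m,n grid sizes: number of spectra (retention times) and drift
#'   points (inverse mobilities).
#' @param rMax largest retention time (s); the grid is equidistant from 0.
#' @param tMax largest reduced inverse mobility (Vs/cm2).
#' @param ripT RIP position (Vs/cm2), just below the standard 0.48
#'   evaluation cutoff as in real measurements.
#' @param ripIntensity RIP apex intensity (signal units).
#' @param ripTsd RIP width along the mobility axis (Vs/cm2).
#' @param ripJitterSd standard deviation of the slow drift of the RIP
#'   position over the course of the run (Vs/cm2); the drift is smooth in
#'   retention time (instrument temperature/pressure drift), not independent
#'   per spectrum.
#' @param baselineLevel mean per-mobility baseline intensity.
#' @param baselineVariation amplitude of the slow per-mobility baseline
#'   modulation.
#' @param noiseMean,noiseSd additive Gaussian noise parameters.
#' @param peaks data.frame with one planted peak per row: columns \code{r}
#'   (apex retention time, s), \code{t} (apex mobility, Vs/cm2),
#'   \code{amplitude} (apex intensity), \code{r_sd} (s), \code{t_sd}
#'   (Vs/cm2) and \code{skew} (mean-mode gap in units of sd, in (0, 0.6]).
#' @param seed integer RNG seed; identical configs give identical output.
#' @return validated configuration list.
#' @export
simulationConfig <- function(m = 600L, n = 2500L, rMax = 600, tMax = 1.45,
                             ripT = 0.473, ripIntensity = 3000,
                             ripTsd = 0.002, ripJitterSd = 1e-4,
                             baselineLevel = 3, baselineVariation = 40,
                             noiseMean = 0, noiseSd = 3,
                             peaks = defaultSyntheticPeaks(), seed = 1L) {
  cfg <- list(m = as.integer(m), n = as.integer(n), rMax = rMax, tMax = tMax,
              ripT = ripT, ripIntensity = ripIntensity, ripTsd = ripTsd,
              ripJitterSd = ripJitterSd, baselineLevel = baselineLevel,
              baselineVariation = baselineVariation, noiseMean = noiseMean,
              noiseSd = noiseSd, peaks = peaks, seed = as.integer(seed))
  stopifnot(cfg$m > 1L, cfg$n > 1L, cfg$rMax > 0, cfg$tMax > 0)
  if (nrow(peaks)) {
    if (any(peaks$amplitude < 0))
      stop("peak amplitudes must be non-negative")
    if (any(peaks$r < 0 | peaks$r > rMax | peaks$t <= 0 | peaks$t > tMax))
      stop("planted peak outside the measurement grid")
    if (any(peaks$r_sd <= 0 | peaks$t_sd <= 0 | peaks$skew <= 0))
      stop("peak widths and skew must be positive")
  }
  cfg
}

#' Default planted peaks
#'
#' Five analyte peaks inside the standard evaluation region (r > 5 s,
#' t > 0.48 Vs/cm2), pairwise well separated relative to the picking
#' tolerances, with apex amplitudes far above the default noise level and
#' widths growing with retention time as in real MCC/IMS data.
#'
#' @return data.frame of peak specs (see \code{\link{simulationConfig}}).
#' @export
defaultSyntheticPeaks <- function() {
  data.frame(
    r = c(60, 150, 250, 350, 480),
    t = c(0.60, 0.75, 0.90, 0.62, 1.05),
    amplitude = c(600, 800, 500, 700, 400),
    r_sd = c(3, 5, 7, 9, 12),
    t_sd = c(0.008, 0.008, 0.010, 0.010, 0.012),
    skew = 0.3)
}

#' Simulate a synthetic IMSC with planted ground truth
#'
#' Builds \code{clip[0,4095](round(baseline(t) + RIP + sum of planted peaks
#' + noise))} on an equidistant grid and returns both the measurement and
#' the ground-truth peak list (apex coordinates, grid indices and
#' amplitudes).
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @return list with elements \code{measurement}
#'   (\linkS4class{IMSMeasurement}) and \code{truth}
#'   (\linkS4class{IMSPeakList}).
#' @export
simulateIMSC <- function(cfg = simulationConfig()) {
  set.seed(cfg$seed)
  m <- cfg$m; n <- cfg$n
  rGrid <- seq(0, cfg$rMax, length.out = m)
  tGrid <- seq(cfg$tMax / n, cfg$tMax, length.out = n)
  S <- matrix(0, m, n)

  ## per-mobility baseline: flat detector offset, elevated toward the
  ## low-mobility edge (pre-RIP region)
  baseline <- cfg$baselineLevel +
    cfg$baselineVariation * exp(-tGrid / (0.15 * cfg$tMax))
  S <- S + matrix(baseline, m, n, byrow = TRUE)

  ## RIP: a full-length high-intensity chromatogram whose position drifts
  ## slowly and smoothly over the run
  if (cfg$ripIntensity > 0) {
    knotR <- seq(1, m, length.out = 11)
    drift <- stats::spline(knotR, stats::rnorm(11, 0, cfg$ripJitterSd),
                           xout = seq_len(m))$y
    for (i in seq_len(m))
      S[i, ] <- S[i, ] + cfg$ripIntensity *
        exp(-0.5 * ((tGrid - cfg$ripT - drift[i]) / cfg$ripTsd)^2)
  }

  ## planted peaks: separable shifted-IG profiles, apex-normalized
  pk <- cfg$peaks
  truthRows <- list()
  for (i in seq_len(nrow(pk))) {
    ri <- which.min(abs(rGrid - pk$r[i]))
    ti <- which.min(abs(tGrid - pk$t[i]))
    rStep <- cfg$rMax / (m - 1)
    tStep <- cfg$tMax / n
    profR <- .igProfile(seq_len(m), ri, pk$r_sd[i] / rStep, pk$skew[i])
    profT <- .igProfile(seq_len(n), ti, pk$t_sd[i] / tStep, pk$skew[i])
    S <- S + pk$amplitude[i] * outer(profR, profT)
    truthRows[[i]] <- data.frame(
      measurement_name = "synthetic", peak_name = sprintf("T%d", i),
      retention_time = rGrid[ri], inverse_reduced_mobility = tGrid[ti],
      signal = pk$amplitude[i], volume = pk$amplitude[i],
      retention_time_index = ri, inverse_reduced_mobility_index = ti,
      stringsAsFactors = FALSE)
  }

  S <- S + stats::rnorm(m * n, cfg$noiseMean, cfg$noiseSd)
  S <- pmin(pmax(round(S), 0), 4095)

  meas <- IMSMeasurement(
    "synthetic", rGrid, tGrid, S,
    metadata = list(generator = "imspeaks synthetic",
                    seed = as.character(cfg$seed)))
  truth <- if (length(truthRows))
    IMSPeakList(do.call(rbind, truthRows)) else IMSPeakList()
  list(measurement = meas, truth = truth)
}

## apex-normalized shifted-IG profile along one axis (index units)
.igProfile <- function(idx, modeIdx, sdIdx, skew) {
  p <- shiftedInvGaussFromMoments(modeIdx, modeIdx + skew * sdIdx, sdIdx)
  prof <- .digauss(idx, p$mu, p$lambda, p$offset)
  prof / max(prof)
}
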