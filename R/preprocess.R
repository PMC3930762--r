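## Preprocessing modules: baseline correction (bc), de-noising (dn) and
## smoothing (s). Each maps an IMSMeasurement to an IMSMeasurement of the
## same shape; they may be composed in any order and none is optional in a
## full pipeline.

#' Estimate the per-chromatogram baseline
#'
#' For each reduced inverse mobility t, the chromatogram's integer-binned
#' intensity histogram is described by a two-component mixture: a Gaussian
#' for the most prominent histogram peak (the noise level in a typical
#' chromatogram, the RIP level in a RIP chromatogram) plus a uniform over the
#' observed intensity range. EM starts from mean = histogram argmax and
#' variance 1. The baseline is \code{B_t = mu(t) + 2 sigma(t)}.
#'
#' @param m an \linkS4class{IMSMeasurement}.
#' @return list with numeric vectors \code{mu}, \code{sigma} and
#'   \code{baseline} (one entry per column).
#' @export
estimateBaseline <- function(m) {
  S <- intensities(m)
  n <- ncol(S)
  mu <- sigma <- numeric(n)
  for (j in seq_len(n)) {
    hs <- histogramSample(S[, j])
    init <- MixtureModel(list(
      mixtureComponent("gaussian",
                       mean = hs$values[which.max(hs$counts)], var = 1),
      mixtureComponent("uniform", lo = min(hs$values),
                       hi = max(hs$values) + 1)))
    fit <- emFit(hs, init)
    g <- fit$model@components[[1]]$params
    mu[j] <- g$mean
    sigma[j] <- sqrt(g$var)
  }
  list(mu = mu, sigma = sigma, baseline = mu + 2 * sigma)
}

#' Baseline correction (bc)
#'
#' Removes the per-chromatogram baseline \code{B_t = mu(t) + 2 sigma(t)}
#' estimated by \code{\link{estimateBaseline}}, clamping at zero:
#' \code{S'[r,t] = max(S[r,t] - B_t, 0)}. This erases both the general
#' baseline and the reactant ion peak (RIP), whose level dominates the
#' histogram of its chromatograms.
#'
#' @param m an \linkS4class{IMSMeasurement}.
#' @param params parameter list (unused by bc; accepted for a uniform stage
#'   interface).
#' @return the corrected \linkS4class{IMSMeasurement}.
#' @export
baselineCorrection <- function(m, params = defaultParameters()) {
  est <- estimateBaseline(m)
  S <- intensities(m)
  Sp <- pmax(sweep(S, 2L, est$baseline, `-`), 0)
  intensities(m) <- Sp
  m
}

#' Local average of an intensity matrix
#'
#' Mean over the (2 rho + 1) x (2 rho + 1) window around each cell. With
#' \code{boundary = "zero"} cells outside the matrix count as zeros (a corner
#' cell of a constant-v matrix averages to 4v/9 at rho = 1); with
#' \code{boundary = "renormalize"} the window sum is divided by the number of
#' in-bounds cells instead, which keeps the estimate unbiased at the borders.
#'
#' @param m an \linkS4class{IMSMeasurement} or numeric matrix.
#' @param rho window half-width in index units (>= 0).
#' @param boundary boundary handling, see above.
#' @return numeric matrix of local averages, same shape as the input.
#' @export
localAverage <- function(m, rho, boundary = c("zero", "renormalize")) {
  S <- if (is(m, "IMSMeasurement")) intensities(m) else m
  boundary <- match.arg(boundary)
  stopifnot(rho >= 0)
  rho <- as.integer(rho)
  if (rho == 0L) return(S)
  k <- 2L * rho + 1L
  win <- .windowSums(S, rho)
  if (boundary == "zero")
    win / k^2
  else
    win / .windowSums(matrix(1, nrow(S), ncol(S)), rho)
}

## zero-padded window sums via a summed-area table
.windowSums <- function(S, rho) {
  nr <- nrow(S); nc <- ncol(S)
  P <- matrix(0, nr + 2L * rho, nc + 2L * rho)
  P[(rho + 1L):(rho + nr), (rho + 1L):(rho + nc)] <- S
  sat <- apply(P, 2L, cumsum)
  sat <- t(apply(sat, 1L, cumsum))
  sat <- cbind(0, rbind(0, sat))
  k <- 2L * rho + 1L
  ri <- seq_len(nr); ci <- seq_len(nc)
  sat[ri + k, ci + k, drop = FALSE] -
    sat[ri, ci + k, drop = FALSE] -
    sat[ri + k, ci, drop = FALSE] +
    sat[ri, ci, drop = FALSE]
}

#' De-noising (dn)
#'
#' Fits a three-component heterogeneous mixture (Gaussian noise + Inverse
#' Gaussian signal + uniform background) to the integer-binned histogram of
#' the locally averaged matrix A (window half-width \code{rho}), then damps
#' every cell by its posterior noise membership:
#' \code{S'[r,t] = S[r,t] * (1 - W[r,t])}, so only the non-noise fraction
#' remains. EM initialization: Gaussian at the histogram argmax with variance
#' 1; Inverse Gaussian mean at the 90th intensity percentile with shape equal
#' to that mean; weights (0.8, 0.1, 0.1).
#'
#' @param m an \linkS4class{IMSMeasurement}.
#' @param params parameter list; uses \code{smoothing_radius}.
#' @return the de-noised \linkS4class{IMSMeasurement}. On EM degeneracy the
#'   input is passed through with a warning and
#'   \code{measurementMetadata(x)$denoise_status == "degenerate"}.
#' @export
denoise <- function(m, params = defaultParameters()) {
  rho <- params$smoothing_radius
  S <- intensities(m)
  A <- localAverage(S, rho, boundary = "renormalize")
  hs <- histogramSample(A)
  if (length(hs$values) == 1L) {
    warning("de-noising skipped: degenerate intensity distribution")
    m@metadata$denoise_status <- "degenerate"
    return(m)
  }
  muIG <- max(stats::quantile(A, 0.9), 1e-3)
  init <- MixtureModel(
    list(
      mixtureComponent("gaussian",
                       mean = hs$values[which.max(hs$counts)], var = 1),
      mixtureComponent("inverse_gaussian", mu = muIG, lambda = muIG),
      mixtureComponent("uniform", lo = min(hs$values),
                       hi = max(hs$values) + 1)),
    weights = c(0.8, 0.1, 0.1))
  ## background component spans all measured intensities, not just the
  ## narrower range of the local averages
  fit <- emFit(hs, init, uniformRange = c(min(min(S), min(hs$values)),
                                          max(max(S), max(hs$values)) + 1))
  if (fit$model@status != "ok") {
    warning("de-noising skipped: EM degenerate")
    m@metadata$denoise_status <- "degenerate"
    return(m)
  }
  W <- posteriorMembership(fit$model, as.vector(A))[, 1L]
  Sp <- S * (1 - matrix(W, nrow(S), ncol(S)))
  intensities(m) <- Sp
  m
}

#' Isotropic FFT lowpass filter
#'
#' Zeroes all 2D-FFT coefficients whose radial index
#' \code{sqrt(kr^2 + kt^2)} on the centered frequency grid exceeds
#' \code{cutoff}, then back-transforms. A cutoff beyond the grid's Nyquist
#' radius is the identity.
#'
#' @param S numeric matrix.
#' @param cutoff radial frequency index threshold (> 0).
#' @return filtered real matrix, same shape.
#' @export
fftLowpass <- function(S, cutoff) {
  stopifnot(cutoff > 0)
  nr <- nrow(S); nc <- ncol(S)
  fr <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  ft <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  rad <- sqrt(outer(fr^2, ft^2, `+`))
  if (all(rad <= cutoff)) return(S)
  Fm <- stats::fft(S)
  Fm[rad > cutoff] <- 0
  Re(stats::fft(Fm, inverse = TRUE)) / (nr * nc)
}

## SG convolution weights: least-squares fit of a degree-2 bivariate
## polynomial on the window, evaluated at the center
.sgKernel <- function(rho) {
  off <- -rho:rho
  g <- expand.grid(dr = off, dt = off)
  X <- cbind(1, g$dr, g$dt, g$dr^2, g$dr * g$dt, g$dt^2)
  h <- (solve(crossprod(X)) %*% t(X))[1L, ]
  matrix(h, 2L * rho + 1L, 2L * rho + 1L)
}

#' Two-dimensional Savitzky-Golay filter
#'
#' Degree-2 local polynomial smoothing over (2 rho + 1) x (2 rho + 1)
#' windows, realized as a convolution with the standard SG weights; the
#' matrix boundary is handled by a zero margin of width \code{rho}. Degree-2
#' polynomials on interior cells are reproduced exactly.
#'
#' @param S numeric matrix.
#' @param rho window half-width in index units (>= 1).
#' @return smoothed matrix, same shape.
#' @export
savitzkyGolay2D <- function(S, rho) {
  stopifnot(rho >= 1)
  rho <- as.integer(rho)
  K <- .sgKernel(rho)
  nr <- nrow(S); nc <- ncol(S)
  P <- matrix(0, nr + 2L * rho, nc + 2L * rho)
  P[(rho + 1L):(rho + nr), (rho + 1L):(rho + nc)] <- S
  out <- matrix(0, nr, nc)
  for (dr in -rho:rho)
    for (dt in -rho:rho) {
      kk <- K[dr + rho + 1L, dt + rho + 1L]
      out <- out + kk * P[(rho + 1L + dr):(rho + nr + dr),
                          (rho + 1L + dt):(rho + nc + dt), drop = FALSE]
    }
  out
}

#' Smoothing (s)
#'
#' Two consecutive filters: an isotropic FFT lowpass (parameter
#' \code{fftcutoff}) followed by a two-dimensional Savitzky-Golay filter on
#' (2 rho + 1) x (2 rho + 1) windows (parameter \code{smoothing_radius}).
#' Negative values possibly produced by either filter are kept; downstream
#' intensity thresholds make them irrelevant.
#'
#' @param m an \linkS4class{IMSMeasurement}.
#' @param params parameter list; uses \code{fftcutoff} and
#'   \code{smoothing_radius}.
#' @return the smoothed \linkS4class{IMSMeasurement}.
#' @export
smoothIMSC <- function(m, params = defaultParameters()) {
  S <- intensities(m)
  S <- fftLowpass(S, params$fftcutoff)
  S <- savitzkyGolay2D(S, params$smoothing_radius)
  intensities(m) <- S
  m
}
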