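## Heterogeneous mixture-model EM engine shared by baseline correction,
## de-noising and peak model estimation. Data enter as a weighted sample
## (histogram): values x_i with non-negative multiplicities, which for
## integer-valued intensities with bin size 1 is exactly equivalent to
## per-point EM on the expanded multiset.

#' Weighted sample (histogram) constructor
#'
#' @param values numeric sample values.
#' @param counts non-negative multiplicities, same length (default all 1).
#' @return list with elements \code{values}, \code{counts}.
#' @export
weightedSample <- function(values, counts = rep(1, length(values))) {
  stopifnot(length(values) == length(counts), all(counts >= 0),
            sum(counts) > 0)
  list(values = as.numeric(values), counts = as.numeric(counts))
}

#' Integer-binned histogram of intensities
#'
#' Bins values with bin size 1 (bin = floor(x)); for raw integer intensities
#' this is the exact frequency table.
#'
#' @param x numeric intensities.
#' @return a \code{\link{weightedSample}} over occupied bins.
#' @export
histogramSample <- function(x) {
  b <- floor(x)
  lo <- min(b)
  counts <- tabulate(b - lo + 1L)
  keep <- counts > 0
  weightedSample(values = (lo:(lo + length(counts) - 1L))[keep],
                 counts = counts[keep])
}

#' Component probability density
#'
#' Density of a single mixture component, vectorized over \code{x}. Densities
#' are 0 outside the support (x <= offset for (shifted) Inverse Gaussians,
#' outside [lo, hi] for the uniform).
#'
#' @param comp a \code{\link{mixtureComponent}}.
#' @param x numeric evaluation points.
#' @return numeric densities, same length as \code{x}.
#' @export
componentPdf <- function(comp, x) {
  p <- comp$params
  .checkComponentParams(comp$kind, p)
  switch(comp$kind,
    gaussian = stats::dnorm(x, p$mean, sqrt(p$var)),
    inverse_gaussian = .digauss(x, p$mu, p$lambda, 0),
    shifted_inverse_gaussian = .digauss(x, p$mu, p$lambda, p$offset),
    uniform = ifelse(x >= p$lo & x <= p$hi, 1 / (p$hi - p$lo), 0))
}

## shifted Inverse Gaussian density:
## f(x) = sqrt(lambda / (2 pi (x-o)^3)) *
##        exp(-lambda (x - o - mu)^2 / (2 mu^2 (x - o))),  x > o
.digauss <- function(x, mu, lambda, offset) {
  y <- x - offset
  d <- numeric(length(x))
  pos <- y > 0
  yp <- y[pos]
  d[pos] <- sqrt(lambda / (2 * pi * yp^3)) *
    exp(-lambda * (yp - mu)^2 / (2 * mu^2 * yp))
  d
}

#' Posterior component membership
#'
#' Per-component posterior probabilities proportional to
#' \code{weight * density}, normalized to sum to 1 per point. Points at which
#' every density vanishes are assigned to the uniform component when one is
#' present (error otherwise).
#'
#' @param model a \linkS4class{MixtureModel}.
#' @param x numeric evaluation points.
#' @return matrix, length(x) rows by one column per component.
#' @export
posteriorMembership <- function(model, x) {
  stopifnot(is(model, "MixtureModel"))
  D <- vapply(seq_along(model@components),
              function(c) componentPdf(model@components[[c]], x) *
                model@weights[c],
              numeric(length(x)))
  D <- matrix(D, nrow = length(x))
  tot <- rowSums(D)
  zero <- tot <= 0
  if (any(zero)) {
    uni <- which(vapply(model@components,
                        function(cp) cp$kind == "uniform", logical(1)))
    if (!length(uni))
      stop("all component densities vanish at some points and no uniform ",
           "component is present")
    D[zero, ] <- 0
    D[zero, uni[1]] <- 1
    tot[zero] <- 1
  }
  D / tot
}

#' Fit a heterogeneous mixture by expectation maximization
#'
#' Histogram-weighted EM: the E-step computes expected memberships of each
#' sample value in each component; the M-step re-estimates weights and
#' component parameters by weighted maximum likelihood. Uniform components
#' are clamped to the observed data range and never re-estimated; components
#' flagged \code{fixed} keep their parameters. The weighted log-likelihood is
#' non-decreasing across iterations.
#'
#' @param data a \code{\link{weightedSample}}.
#' @param init a \linkS4class{MixtureModel} with starting parameters.
#' @param maxIter maximum number of EM iterations.
#' @param tol relative log-likelihood change below which iteration stops.
#' @param uniformRange optional numeric(2) support for uniform components;
#'   defaults to the observed range of the fitted data. Callers fitting
#'   summaries (e.g. local averages) can pass the raw measurement's intensity
#'   range so the background component stays spread over all measured
#'   intensities.
#' @return list with elements \code{model} (fitted \linkS4class{MixtureModel};
#'   its \code{status} is "degenerate" when the data admit no fit),
#'   \code{membership} (points x components posterior matrix),
#'   \code{logLik} (trace of the weighted log-likelihood, one entry per
#'   iteration) and \code{iterations}.
#' @export
emFit <- function(data, init, maxIter = 500L, tol = 1e-6,
                  uniformRange = NULL) {
  stopifnot(is(init, "MixtureModel"))
  x <- data$values
  w <- data$counts
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  comps <- init@components
  omega <- init@weights / sum(init@weights)

  ## clamp uniform components to the observed data range (or the caller's)
  rng <- if (is.null(uniformRange)) range(x) else range(uniformRange)
  if (rng[1] > min(x) || rng[2] < max(x))
    stop("uniformRange must cover the fitted data")
  for (c in seq_along(comps)) {
    if (comps[[c]]$kind == "uniform") {
      comps[[c]]$params$lo <- rng[1]
      comps[[c]]$params$hi <- if (rng[2] > rng[1]) rng[2] else rng[1] + 1
    }
  }

  ## degenerate data: a single distinct value supports no mixture fit
  if (length(unique(x)) == 1L) {
    for (c in seq_along(comps)) {
      if (comps[[c]]$kind == "gaussian") {
        comps[[c]]$params$mean <- x[1]
        comps[[c]]$params$var <- .SIGMA2_FLOOR
      }
    }
    model <- MixtureModel(comps, omega, status = "degenerate")
    W <- posteriorMembership(model, x)
    return(list(model = model, membership = W, logLik = numeric(0),
                iterations = 0L))
  }

  ll <- -Inf
  trace <- numeric(0)
  W <- NULL
  for (it in seq_len(maxIter)) {
    ## E-step
    D <- vapply(comps, function(cp) componentPdf(cp, x), numeric(length(x)))
    D <- matrix(D, nrow = length(x))
    num <- sweep(D, 2L, omega, `*`)
    tot <- rowSums(num)
    bad <- tot <= 0
    if (any(bad)) {
      uni <- which(vapply(comps, function(cp) cp$kind == "uniform",
                          logical(1)))
      if (length(uni)) {
        num[bad, ] <- 0
        num[bad, uni[1]] <- 1
        tot[bad] <- 1
      } else {
        tot[bad] <- .Machine$double.xmin
      }
    }
    W <- num / tot
    llNew <- sum(w * log(pmax(tot, .Machine$double.xmin)))
    trace <- c(trace, llNew)

    ## M-step
    wc <- colSums(w * W)
    omega <- pmax(wc / sum(wc), .OMEGA_FLOOR)
    omega <- omega / sum(omega)
    for (c in seq_along(comps)) {
      if (comps[[c]]$fixed) next
      cw <- w * W[, c]
      comps[[c]] <- .mstepComponent(comps[[c]], x, cw)
    }

    if (is.finite(ll) && abs(llNew - ll) <= tol * abs(ll) + 1e-12) {
      ll <- llNew
      break
    }
    ll <- llNew
  }
  model <- MixtureModel(comps, omega, status = "ok")
  list(model = model, membership = W, logLik = trace, iterations = it)
}

.SIGMA2_FLOOR <- 1e-12
.OMEGA_FLOOR <- 1e-12

## weighted ML update of one component; offsets of shifted IGs stay fixed
.mstepComponent <- function(comp, x, cw) {
  tot <- sum(cw)
  if (tot <= 0) return(comp)
  if (comp$kind == "gaussian") {
    mu <- sum(cw * x) / tot
    v <- sum(cw * (x - mu)^2) / tot
    comp$params$mean <- mu
    comp$params$var <- max(v, .SIGMA2_FLOOR)
  } else if (comp$kind %in% c("inverse_gaussian",
                              "shifted_inverse_gaussian")) {
    o <- if (comp$kind == "inverse_gaussian") 0 else comp$params$offset
    pos <- x > o
    cwp <- cw[pos]; y <- x[pos] - o
    if (sum(cwp) <= 0) return(comp)
    mu <- sum(cwp * y) / sum(cwp)
    invl <- sum(cwp * (1 / y - 1 / mu)) / sum(cwp)
    comp$params$mu <- max(mu, 1e-12)
    comp$params$lambda <- max(1 / max(invl, 1e-12), 1e-12)
  }
  comp
}

#' Weighted log-likelihood of a mixture model
#'
#' @param model a \linkS4class{MixtureModel}.
#' @param data a \code{\link{weightedSample}}.
#' @return scalar log-likelihood.
#' @export
mixtureLogLik <- function(model, data) {
  D <- vapply(seq_along(model@components),
              function(c) componentPdf(model@components[[c]], data$values) *
                model@weights[c],
              numeric(length(data$values)))
  D <- matrix(D, nrow = length(data$values))
  sum(data$counts * log(pmax(rowSums(D), .Machine$double.xmin)))
}
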