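## Peak model estimation (pme): describe each picked peak by a separable
## product of two shifted Inverse Gaussian densities (one per axis, three
## parameters each) plus one mixture coefficient - seven parameters per peak
## - fitted by intensity-weighted EM inside an expanded box around the peak,
## against a uniform background component per box. All fitting happens in
## grid index units; results are translated back into mode, mean and
## standard deviation per axis.

.modelParameterNames <- c("model_omega", "r_mu", "r_lambda", "r_offset",
                          "t_mu", "t_lambda", "t_offset",
                          "r_mode", "r_mean", "r_sd",
                          "t_mode", "t_mean", "t_sd")

#' Shifted Inverse Gaussian density
#'
#' \code{f(x) = sqrt(lambda / (2 pi (x-o)^3)) *
#'   exp(-lambda (x-o-mu)^2 / (2 mu^2 (x-o)))} for \code{x > o}, 0 otherwise.
#'
#' @param x evaluation points.
#' @param mu Inverse Gaussian mean parameter (> 0).
#' @param lambda shape parameter (> 0).
#' @param offset shift o.
#' @return densities.
#' @export
shiftedInvGaussPdf <- function(x, mu, lambda, offset = 0) {
  stopifnot(mu > 0, lambda > 0)
  .digauss(x, mu, lambda, offset)
}

#' Mode, mean and standard deviation of a shifted Inverse Gaussian
#'
#' @param mu,lambda,offset distribution parameters.
#' @return named numeric vector with \code{mode}, \code{mean}, \code{sd}.
#' @export
shiftedInvGaussMoments <- function(mu, lambda, offset = 0) {
  ratio <- 3 * mu / (2 * lambda)
  c(mode = offset + mu * (sqrt(1 + ratio^2) - ratio),
    mean = offset + mu,
    sd = sqrt(mu^3 / lambda))
}

#' Shifted Inverse Gaussian parameters from descriptors
#'
#' Solves the (mode, mean, sd) relations numerically for
#' (mu, lambda, offset); requires \code{mean > mode}.
#'
#' @param mode,mean,sd target descriptors.
#' @return list with \code{mu}, \code{lambda}, \code{offset}.
#' @export
shiftedInvGaussFromMoments <- function(mode, mean, sd) {
  stopifnot(mean > mode, sd > 0)
  gap <- mean - mode
  ## with lambda = mu^3 / sd^2 the mean-mode gap is
  ##   u(mu) = mu (1 + c - sqrt(1 + c^2)),  c = 3 sd^2 / (2 mu^2),
  ## which is unimodal in mu with two roots of u(mu) = gap; the larger root
  ## (the mildly skewed, near-Gaussian shape) is the intended solution
  u <- function(mu) {
    cc <- 3 * sd^2 / (2 * mu^2)
    mu * (1 + cc - sqrt(1 + cc^2))
  }
  peak <- stats::optimize(u, sd * c(1e-3, 1e3), maximum = TRUE)
  if (u(peak$maximum) <= gap)
    stop("mean - mode gap too large for the given sd")
  hi <- peak$maximum
  while (u(hi) > gap) hi <- hi * 2
  mu <- stats::uniroot(function(m) u(m) - gap, c(peak$maximum, hi),
                       tol = 1e-12)$root
  list(mu = mu, lambda = mu^3 / sd^2, offset = mean - mu)
}

#' Expand boxes around picked peaks
#'
#' For each peak, walks from the peak cell in all four axis directions until
#' the signal drops to zero (or the border), then widens the box by
#' \code{expansion_size} index units and clips it to the matrix. Intersecting
#' boxes are merged into their bounding rectangle until a fixpoint is
#' reached.
#'
#' @param m an \linkS4class{IMSMeasurement}.
#' @param pl picked peaks (\linkS4class{IMSPeakList}) with valid indices.
#' @param expansionSize additional margin in index units.
#' @return list of boxes, each a list with \code{rLo}, \code{rHi},
#'   \code{tLo}, \code{tHi} (inclusive 1-based index bounds) and
#'   \code{members} (row numbers into \code{peaks(pl)}).
#' @export
expandBoxes <- function(m, pl, expansionSize = 10) {
  df <- peaks(pl)
  if (!nrow(df)) return(list())
  S <- intensities(m)
  nr <- nrow(S); nc <- ncol(S)
  boxes <- lapply(seq_len(nrow(df)), function(i) {
    ri <- df$retention_time_index[i]
    ti <- df$inverse_reduced_mobility_index[i]
    rLo <- ri; while (rLo > 1L && S[rLo - 1L, ti] > 0) rLo <- rLo - 1L
    rHi <- ri; while (rHi < nr && S[rHi + 1L, ti] > 0) rHi <- rHi + 1L
    tLo <- ti; while (tLo > 1L && S[ri, tLo - 1L] > 0) tLo <- tLo - 1L
    tHi <- ti; while (tHi < nc && S[ri, tHi + 1L] > 0) tHi <- tHi + 1L
    list(rLo = max(1L, as.integer(rLo - expansionSize)),
         rHi = min(nr, as.integer(rHi + expansionSize)),
         tLo = max(1L, as.integer(tLo - expansionSize)),
         tHi = min(nc, as.integer(tHi + expansionSize)),
         members = i)
  })
  ## merge intersecting boxes into bounding rectangles until fixpoint
  repeat {
    merged <- FALSE
    k <- length(boxes)
    if (k <= 1L) break
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        a <- boxes[[i]]; b <- boxes[[j]]
        if (a$rLo <= b$rHi && b$rLo <= a$rHi &&
            a$tLo <= b$tHi && b$tLo <= a$tHi) {
          boxes[[i]] <- list(
            rLo = min(a$rLo, b$rLo), rHi = max(a$rHi, b$rHi),
            tLo = min(a$tLo, b$tLo), tHi = max(a$tHi, b$tHi),
            members = c(a$members, b$members))
          boxes[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  boxes
}

#' The empty modeling module (e)
#'
#' Passes the peak list through unchanged.
#'
#' @param pl an \linkS4class{IMSPeakList}.
#' @param ... ignored.
#' @return \code{pl}, unmodified.
#' @export
emptyModel <- function(pl, ...) pl

## profile-likelihood M-step for one shifted IG dimension: closed-form
## (mu, lambda) given the offset, offset itself re-estimated by 1D weighted
## likelihood optimization below the smallest observation
.msShiftedIGDim <- function(x, w, cur) {
  tot <- sum(w)
  if (tot <= 0) return(cur)
  closedForm <- function(o) {
    y <- x - o
    mu <- sum(w * y) / tot
    invl <- sum(w * (1 / y - 1 / mu)) / tot
    list(mu = max(mu, 1e-9), lambda = 1 / max(invl, 1e-12))
  }
  ll <- function(o) {
    p <- closedForm(o)
    sum(w * log(pmax(.digauss(x, p$mu, p$lambda, o),
                     .Machine$double.xmin)))
  }
  xmin <- min(x[w > 0])
  span <- max(diff(range(x)), 1)
  opt <- stats::optimize(ll, c(xmin - 3 * span, xmin - 1e-9), maximum = TRUE)
  o <- opt$maximum
  p <- closedForm(o)
  list(mu = p$mu, lambda = p$lambda, offset = o)
}

#' Peak model estimation (pme)
#'
#' Interprets the measurement inside each expanded box (see
#' \code{\link{expandBoxes}}) as an intensity-weighted sample from a mixture
#' of per-peak separable shifted-Inverse-Gaussian products plus a uniform
#' background, and fits it by EM. Components start at the picked locations:
#' mode = picked index, mean = mode + 1e-3 index units, sd = 1 index unit.
#' Each peak gains the seven model parameters plus the derived mode, mean and
#' sd per axis; its coordinates move to the modeled mode, and its volume
#' becomes its mixture weight times the box's total intensity. The output has
#' exactly as many peaks as the input.
#'
#' @param m the preprocessed \linkS4class{IMSMeasurement}.
#' @param pl picked peaks (\linkS4class{IMSPeakList}).
#' @param params parameter list; uses \code{expansion_size}.
#' @param maxIter,tol EM iteration control per box.
#' @return An \linkS4class{IMSPeakList} with model parameters in the extra
#'   columns. If EM fails in a box its peaks keep their input coordinates and
#'   get NA model parameters.
#' @export
fitPeakModels <- function(m, pl, params = defaultParameters(),
                          maxIter = 60L, tol = 1e-6) {
  df <- peaks(pl)
  for (p in .modelParameterNames) df[[p]] <- rep(NA_real_, nrow(df))
  if (!nrow(df))
    return(IMSPeakList(df, parameterNames = .modelParameterNames))
  S <- pmax(intensities(m), 0)
  rGrid <- retentionTimes(m)
  tGrid <- inverseMobilities(m)
  boxes <- expandBoxes(m, pl, params$expansion_size)
  for (box in boxes) {
    fit <- tryCatch(
      .fitBox(S, box, df, maxIter, tol),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("peak model estimation failed in a box; peaks kept unmodeled")
      next
    }
    for (k in seq_along(box$members)) {
      i <- box$members[k]
      pr <- fit$components[[k]]
      momR <- shiftedInvGaussMoments(pr$r$mu, pr$r$lambda, pr$r$offset)
      momT <- shiftedInvGaussMoments(pr$t$mu, pr$t$lambda, pr$t$offset)
      df[i, .modelParameterNames] <- c(
        fit$omega[k], pr$r$mu, pr$r$lambda, pr$r$offset,
        pr$t$mu, pr$t$lambda, pr$t$offset,
        momR["mode"], momR["mean"], momR["sd"],
        momT["mode"], momT["mean"], momT["sd"])
      df$volume[i] <- fit$omega[k] * fit$totalIntensity
      ## move the reported coordinate to the modeled mode
      df$retention_time[i] <- .gridInterp(rGrid, momR["mode"])
      df$inverse_reduced_mobility[i] <- .gridInterp(tGrid, momT["mode"])
      df$retention_time_index[i] <-
        min(max(1L, as.integer(round(momR["mode"]))), length(rGrid))
      df$inverse_reduced_mobility_index[i] <-
        min(max(1L, as.integer(round(momT["mode"]))), length(tGrid))
    }
  }
  IMSPeakList(df, parameterNames = .modelParameterNames)
}

## continuous index -> axis units by linear interpolation (clipped)
.gridInterp <- function(grid, idx) {
  idx <- min(max(idx, 1), length(grid))
  lo <- floor(idx)
  hi <- ceiling(idx)
  if (lo == hi) return(grid[lo])
  grid[lo] + (idx - lo) * (grid[hi] - grid[lo])
}

.fitBox <- function(S, box, df, maxIter, tol) {
  ri <- box$rLo:box$rHi
  ti <- box$tLo:box$tHi
  sub <- S[ri, ti, drop = FALSE]
  w <- as.vector(sub)
  if (sum(w) <= 0) stop("empty box")
  xr <- rep(ri, times = length(ti))
  xt <- rep(ti, each = length(ri))
  keep <- w > 0
  xr <- xr[keep]; xt <- xt[keep]; w <- w[keep]
  P <- length(box$members)
  comps <- lapply(box$members, function(i) {
    list(r = shiftedInvGaussFromMoments(df$retention_time_index[i],
                                        df$retention_time_index[i] + 1e-3, 1),
         t = shiftedInvGaussFromMoments(df$inverse_reduced_mobility_index[i],
                                        df$inverse_reduced_mobility_index[i] + 1e-3,
                                        1))
  })
  area <- length(ri) * length(ti)
  omega <- rep(1 / (P + 1), P + 1)   # last = uniform background
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    D <- vapply(seq_len(P), function(c)
      .digauss(xr, comps[[c]]$r$mu, comps[[c]]$r$lambda,
               comps[[c]]$r$offset) *
        .digauss(xt, comps[[c]]$t$mu, comps[[c]]$t$lambda,
                 comps[[c]]$t$offset),
      numeric(length(w)))
    D <- cbind(matrix(D, nrow = length(w)), 1 / area)
    num <- sweep(D, 2L, omega, `*`)
    totd <- rowSums(num)
    totd[totd <= 0] <- .Machine$double.xmin
    W <- num / totd
    llNew <- sum(w * log(totd))
    wc <- colSums(w * W)
    omega <- pmax(wc / sum(wc), 1e-12)
    omega <- omega / sum(omega)
    for (c in seq_len(P)) {
      cw <- w * W[, c]
      comps[[c]]$r <- .msShiftedIGDim(xr, cw, comps[[c]]$r)
      comps[[c]]$t <- .msShiftedIGDim(xt, cw, comps[[c]]$t)
    }
    if (is.finite(ll) && abs(llNew - ll) <= tol * abs(ll)) break
    ll <- llNew
  }
  if (!is.finite(llNew)) stop("EM diverged")
  list(components = comps, omega = omega[seq_len(P)],
       totalIntensity = sum(w))
}
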