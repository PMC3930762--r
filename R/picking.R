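## Peak picking: reduce the candidate list to distinct peaks. All three
## pickers (ms, ce, emc) return a subset of the input candidates, sorted by
## descending signal, one representative per group of candidates closer than
## the tolerance geometry allows for distinct compounds.

#' Squared normalized distance between two peaks
#'
#' \code{d2(u,v) = 1/2 * [ ((t_u - t_v)/deltaT)^2 + ((r_u - r_v)/deltaR)^2 ]}
#' where \code{deltaT} is the constant mobility tolerance and \code{deltaR}
#' the affine-linear retention-time tolerance evaluated at the mean retention
#' time of the pair. \code{d2 = 1} when both coordinate differences equal
#' their tolerances.
#'
#' @param rU,tU,rV,tV coordinates (retention time s, inverse mobility
#'   Vs/cm2); vectorized.
#' @param tol tolerance parameters (see \code{\link{toleranceParams}}).
#' @return squared normalized distance(s).
#' @export
candidateDistanceSq <- function(rU, tU, rV, tV, tol = toleranceParams()) {
  dR <- deltaR((rU + rV) / 2, tol)
  0.5 * (((tU - tV) / tol$tol_rim)^2 + ((rU - rV) / dR)^2)
}

#' Similarity weight for cluster editing
#'
#' \code{w = 2^b * (1 - d2) - 1} for \code{d2 < 1}, else \code{1 - d2}; the
#' range is (-Inf, 2^b - 1], with weight 0 at \code{d2 = 1} and the maximum
#' \code{2^b - 1} for coincident candidates.
#'
#' @param d2 squared normalized distance(s).
#' @param b weight exponent (ce_weight_exponent, >= 1).
#' @return similarity weight(s).
#' @export
similarityWeight <- function(d2, b) {
  stopifnot(b >= 1)
  ifelse(d2 < 1, 2^b * (1 - d2) - 1, 1 - d2)
}

.subsetPeaks <- function(pl, idx) {
  df <- peaks(pl)[idx, , drop = FALSE]
  rownames(df) <- NULL
  IMSPeakList(df, parameterNames = parameterNames(pl))
}

## deterministic candidate order: descending signal, then ascending indices
.signalOrder <- function(df) {
  order(-df$signal, df$retention_time_index,
        df$inverse_reduced_mobility_index)
}

#' Merging by signal intensity (ms)
#'
#' Greedy picker: iterate candidates by descending signal; each reported
#' candidate claims (marks as merged) every still-unmerged candidate inside
#' its box \code{(r_i +/- deltaR(r_i)) x (t_i +/- deltaT)}.
#'
#' @param cands an \linkS4class{IMSPeakList} of candidates.
#' @param params parameter list (tolerances).
#' @return the picked \linkS4class{IMSPeakList}, descending signal.
#' @export
mergeByIntensity <- function(cands, params = defaultParameters()) {
  df <- peaks(cands)
  if (nrow(df) <= 1L) return(cands)
  tol <- toleranceParams(params)
  ord <- .signalOrder(df)
  df <- df[ord, ]
  merged <- rep(FALSE, nrow(df))
  report <- integer(0)
  for (i in seq_len(nrow(df))) {
    if (merged[i]) next
    report <- c(report, ord[i])
    dr <- deltaR(df$retention_time[i], tol)
    inBox <- abs(df$retention_time - df$retention_time[i]) <= dr &
      abs(df$inverse_reduced_mobility -
            df$inverse_reduced_mobility[i]) <= tol$tol_rim
    merged <- merged | inBox
  }
  .subsetPeaks(cands, report)
}

#' Cluster-editing picker (ce)
#'
#' Builds the complete similarity graph over candidates with
#' \code{\link{similarityWeight}} (exponent \code{ce_weight_exponent}),
#' solves the weighted cluster editing problem with
#' \code{\link{solveClusterEditing}}, and reports the highest-signal
#' candidate of each resulting cluster.
#'
#' @param cands an \linkS4class{IMSPeakList} of candidates.
#' @param params parameter list (tolerances and \code{ce_weight_exponent}).
#' @return the picked \linkS4class{IMSPeakList}, descending signal.
#' @export
clusterEditPick <- function(cands, params = defaultParameters()) {
  df <- peaks(cands)
  n <- nrow(df)
  if (n <= 1L) return(cands)
  tol <- toleranceParams(params)
  D2 <- outer(seq_len(n), seq_len(n), function(i, j)
    candidateDistanceSq(df$retention_time[i], df$inverse_reduced_mobility[i],
                        df$retention_time[j], df$inverse_reduced_mobility[j],
                        tol))
  W <- similarityWeight(D2, params$ce_weight_exponent)
  diag(W) <- 0
  sol <- solveClusterEditing(W)
  reps <- integer(0)
  for (cl in unique(sol$membership)) {
    members <- which(sol$membership == cl)
    best <- members[order(-df$signal[members],
                          df$retention_time_index[members],
                          df$inverse_reduced_mobility_index[members])][1L]
    reps <- c(reps, best)
  }
  .subsetPeaks(cands, reps[order(-df$signal[reps],
                                 df$retention_time_index[reps],
                                 df$inverse_reduced_mobility_index[reps])])
}

#' EM-clustering picker (emc)
#'
#' Gaussian mixture over candidate coordinates, one diagonal-covariance 2D
#' component per candidate, initialized at the candidate position with axis
#' standard deviations \code{deltaR(r)/3} and \code{deltaT/3}. E- and M-steps
#' alternate; when the normalized distance between two component means drops
#' below \code{mergeThreshold} the component anchored to the lower-signal
#' candidate is removed and its weight added to the survivor. Estimated
#' standard deviations are floored at \code{tau} (Vs/cm2) on the mobility
#' axis and at \code{tau} scaled by \code{deltaR/deltaT} on the retention
#' time axis.
#'
#' @param cands an \linkS4class{IMSPeakList} of candidates.
#' @param params parameter list (tolerances).
#' @param mergeThreshold normalized mean distance below which components
#'   merge (default 1/3, consistent with the sigma = tolerance/3 init).
#' @param tau standard deviation floor in Vs/cm2 (default 1e-5).
#' @param maxIter maximum EM iterations.
#' @return the picked \linkS4class{IMSPeakList}, descending signal.
#' @export
emClusterPick <- function(cands, params = defaultParameters(),
                          mergeThreshold = 1 / 3, tau = 1e-5,
                          maxIter = 200L) {
  df <- peaks(cands)
  n <- nrow(df)
  if (n <= 1L) return(cands)
  tol <- toleranceParams(params)
  r <- df$retention_time; t <- df$inverse_reduced_mobility
  comp <- data.frame(
    muR = r, muT = t,
    sdR = deltaR(r, tol) / 3, sdT = tol$tol_rim / 3,
    w = rep(1 / n, n), anchor = seq_len(n))
  conv <- 1e-6
  for (it in seq_len(maxIter)) {
    ## E-step over the n candidate points
    dens <- sapply(seq_len(nrow(comp)), function(c)
      comp$w[c] * stats::dnorm(r, comp$muR[c], comp$sdR[c]) *
        stats::dnorm(t, comp$muT[c], comp$sdT[c]))
    dens <- matrix(dens, nrow = n)
    tot <- rowSums(dens)
    tot[tot <= 0] <- .Machine$double.xmin
    W <- dens / tot
    ## M-step
    wc <- colSums(W)
    oldMuR <- comp$muR; oldMuT <- comp$muT
    comp$w <- wc / sum(wc)
    nzw <- pmax(wc, 1e-300)
    comp$muR <- colSums(W * r) / nzw
    comp$muT <- colSums(W * t) / nzw
    sdFloorR <- tau * deltaR(comp$muR, tol) / tol$tol_rim
    comp$sdR <- pmax(sqrt(colSums(W * outer(r, comp$muR, `-`)^2) / nzw),
                     sdFloorR)
    comp$sdT <- pmax(sqrt(colSums(W * outer(t, comp$muT, `-`)^2) / nzw),
                     tau)
    move <- max(sqrt(candidateDistanceSq(comp$muR, comp$muT,
                                         oldMuR, oldMuT, tol)))
    ## merge components whose means collapsed
    mergedAny <- FALSE
    repeat {
      k <- nrow(comp)
      if (k <= 1L) break
      D <- sqrt(outer(seq_len(k), seq_len(k), function(i, j)
        candidateDistanceSq(comp$muR[i], comp$muT[i],
                            comp$muR[j], comp$muT[j], tol)))
      diag(D) <- Inf
      hit <- which(D < mergeThreshold, arr.ind = TRUE)
      if (!nrow(hit)) break
      i <- hit[1L, 1L]; j <- hit[1L, 2L]
      lo <- if (df$signal[comp$anchor[i]] < df$signal[comp$anchor[j]]) i else j
      hi <- i + j - lo
      comp$w[hi] <- comp$w[hi] + comp$w[lo]
      comp <- comp[-lo, , drop = FALSE]
      mergedAny <- TRUE
    }
    if (move < conv && !mergedAny) break
  }
  anchors <- comp$anchor
  .subsetPeaks(cands, anchors[order(-df$signal[anchors],
                                    df$retention_time_index[anchors],
                                    df$inverse_reduced_mobility_index[anchors])])
}
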