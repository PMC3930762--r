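## Evaluation of an automatic peak list against an annotated one: region
## filter, tolerance-box matching (TP/FP/FN), sensitivity, positive
## predictive value, Fowlkes-Mallows index G, Jaccard distance d, Pareto
## fronts over pipelines.

#' Filter peaks to the evaluation region
#'
#' Keeps peaks with retention time strictly above \code{rMin} seconds and
#' reduced inverse mobility strictly above \code{tMin} Vs/cm2 (standard
#' practice: r > 5 s and t > 0.48 Vs/cm2, excluding the RIP region).
#'
#' @param pl an \linkS4class{IMSPeakList}.
#' @param rMin retention time cutoff (s).
#' @param tMin inverse mobility cutoff (Vs/cm2).
#' @return filtered \linkS4class{IMSPeakList}, order preserved.
#' @export
filterRegion <- function(pl, rMin = 5, tMin = 0.48) {
  df <- peaks(pl)
  keep <- df$retention_time > rMin & df$inverse_reduced_mobility > tMin
  .subsetPeaks(pl, which(keep))
}

#' Match automatic against annotated peaks
#'
#' A tolerance box of widths \code{2 deltaR(r)} by \code{2 deltaT} is imagined
#' around every annotated peak; boxes are visited in ascending (r, t) order,
#' each box containing at least one not-yet-consumed automatic peak counts as
#' a true positive and consumes the closest such peak (smallest normalized
#' distance, ties to smaller r then t). Annotated peaks with empty boxes are
#' false negatives; automatic peaks never consumed are false positives.
#'
#' @param auto automatic \linkS4class{IMSPeakList} (region-filtered).
#' @param manual annotated \linkS4class{IMSPeakList} (region-filtered).
#' @param params parameter list (tolerances).
#' @return named integer vector with \code{TP}, \code{FP}, \code{FN}.
#' @export
matchPeaks <- function(auto, manual, params = defaultParameters()) {
  tol <- toleranceParams(params)
  am <- peaks(auto)
  mm <- peaks(manual)
  used <- rep(FALSE, nrow(am))
  tp <- 0L
  for (i in order(mm$retention_time, mm$inverse_reduced_mobility)) {
    r0 <- mm$retention_time[i]
    t0 <- mm$inverse_reduced_mobility[i]
    dr <- deltaR(r0, tol)
    inBox <- !used &
      abs(am$retention_time - r0) <= dr &
      abs(am$inverse_reduced_mobility - t0) <= tol$tol_rim
    if (!any(inBox)) next
    cand <- which(inBox)
    d2 <- candidateDistanceSq(am$retention_time[cand],
                              am$inverse_reduced_mobility[cand],
                              r0, t0, tol)
    best <- cand[order(d2, am$retention_time[cand],
                       am$inverse_reduced_mobility[cand])][1L]
    used[best] <- TRUE
    tp <- tp + 1L
  }
  c(TP = tp, FP = nrow(am) - tp, FN = nrow(mm) - tp)
}

#' Derived comparison metrics
#'
#' \code{SENS = TP/(TP+FN)}, \code{PPV = TP/(TP+FP)},
#' \code{G = sqrt(SENS * PPV)} (Fowlkes-Mallows index),
#' \code{J = TP/(FN+TP+FP)} (Jaccard index) and the distance
#' \code{d = 1/J - 1}. Empty-versus-empty comparisons count as perfect
#' agreement (SENS = PPV = J = 1, d = 0); \code{d} is \code{Inf} when
#' \code{J = 0}.
#'
#' @param TP,FP,FN non-negative counts.
#' @return named numeric vector with TP, FP, FN, SENS, PPV, G, J, d.
#' @export
computeMetrics <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  sens <- if (TP + FN == 0) 1 else TP / (TP + FN)
  ppv <- if (TP + FP == 0) 1 else TP / (TP + FP)
  j <- if (TP + FP + FN == 0) 1 else TP / (TP + FP + FN)
  d <- if (j == 0) Inf else 1 / j - 1
  c(TP = TP, FP = FP, FN = FN, SENS = sens, PPV = ppv,
    G = sqrt(sens * ppv), J = j, d = d)
}

#' Evaluate an automatic peak list against an annotation
#'
#' Convenience wrapper: region-filters both lists, matches them and computes
#' the metrics.
#'
#' @param auto,manual \linkS4class{IMSPeakList}s.
#' @param params parameter list (tolerances).
#' @param rMin,tMin evaluation region cutoffs.
#' @return named numeric vector as from \code{\link{computeMetrics}}.
#' @export
evaluatePeakList <- function(auto, manual, params = defaultParameters(),
                             rMin = 5, tMin = 0.48) {
  counts <- matchPeaks(filterRegion(auto, rMin, tMin),
                       filterRegion(manual, rMin, tMin), params)
  computeMetrics(counts[["TP"]], counts[["FP"]], counts[["FN"]])
}

#' Pareto front of (SENS, PPV) points
#'
#' Returns the points not strictly dominated by any other (another point at
#' least as good in both coordinates and strictly better in one). Duplicated
#' non-dominated points are all retained; input order is preserved.
#'
#' @param sens,ppv numeric vectors of equal length.
#' @return logical vector marking Pareto-optimal entries.
#' @export
paretoFront <- function(sens, ppv) {
  stopifnot(length(sens) == length(ppv))
  n <- length(sens)
  vapply(seq_len(n), function(i) {
    !any(sens >= sens[i] & ppv >= ppv[i] &
           (sens > sens[i] | ppv > ppv[i]))
  }, logical(1))
}
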