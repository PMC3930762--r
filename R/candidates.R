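## Peak candidate detection: local maxima (lm) and cross finding (cf).
## Both emit an IMSPeakList sorted by descending signal (ties by row then
## column index); every candidate meets the intensity threshold I.

#' Local maxima candidate detection (lm)
#'
#' Reports a candidate at (r, t) iff (1) \code{S[r,t] >= I} and every
#' existing direct neighbour (8-neighbourhood) has intensity between
#' \code{I} and \code{S[r,t]}, and (2) the 8-connected component of cells
#' with intensity \code{>= I} containing (r, t) has at least
#' \code{area_size} cells, discarding maxima whose surrounding
#' high-intensity area is too small.
#'
#' @param m an \linkS4class{IMSMeasurement} (normally preprocessed).
#' @param params parameter list; uses \code{intensity_threshold} and
#'   \code{area_size}.
#' @return An \linkS4class{IMSPeakList} of candidates.
#' @export
localMaxima <- function(m, params = defaultParameters()) {
  I <- params$intensity_threshold
  Amin <- params$area_size
  stopifnot(Amin >= 9)
  S <- intensities(m)
  nr <- nrow(S); nc <- ncol(S)
  mask <- S >= I

  ## neighbour conditions with an NA border: missing neighbours pass
  P <- matrix(NA_real_, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- S
  ok <- mask
  for (dr in -1:1) for (dt in -1:1) {
    if (dr == 0L && dt == 0L) next
    nb <- P[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dt, drop = FALSE]
    cond <- (nb <= S) & (nb >= I)
    cond[is.na(cond)] <- TRUE
    ok <- ok & cond
  }
  cand <- which(ok)
  if (!length(cand)) return(IMSPeakList())

  sizes <- .componentSizes(mask)
  keep <- sizes[cand] >= Amin
  cand <- cand[keep]
  if (!length(cand)) return(IMSPeakList())
  ri <- ((cand - 1L) %% nr) + 1L
  ti <- ((cand - 1L) %/% nr) + 1L
  .candidateList(m, ri, ti)
}

## size of the 8-connected supra-threshold component containing each cell;
## returns a full matrix-sized vector (0 for cells outside the mask)
.componentSizes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  sizes <- numeric(nr * nc)
  if (!length(idx)) return(sizes)
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  edges <- list()
  ri <- ((idx - 1L) %% nr) + 1L
  ti <- ((idx - 1L) %/% nr) + 1L
  k <- 0L
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    r2 <- ri + sh[1]; t2 <- ti + sh[2]
    inb <- r2 >= 1L & r2 <= nr & t2 >= 1L & t2 <= nc
    j2 <- (t2[inb] - 1L) * nr + r2[inb]
    sel <- mask[j2]
    if (any(sel)) {
      k <- k + 1L
      edges[[k]] <- cbind(vid[idx[inb][sel]], vid[j2[sel]])
    }
  }
  g <- igraph::graph_from_edgelist(
    if (k) do.call(rbind, edges) else matrix(0L, 0L, 2L),
    directed = FALSE)
  g <- igraph::add_vertices(
    g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  sizes[idx] <- comp$csize[comp$membership[seq_along(idx)]]
  sizes
}

.candidateList <- function(m, ri, ti) {
  S <- intensities(m)
  sig <- S[cbind(ri, ti)]
  ord <- order(-sig, ri, ti)
  ri <- ri[ord]; ti <- ti[ord]; sig <- sig[ord]
  df <- data.frame(
    measurement_name = measurementName(m),
    peak_name = sprintf("C%d", seq_along(ri)),
    retention_time = retentionTimes(m)[ri],
    inverse_reduced_mobility = inverseMobilities(m)[ti],
    signal = sig,
    volume = sig,
    retention_time_index = ri,
    inverse_reduced_mobility_index = ti,
    stringsAsFactors = FALSE)
  IMSPeakList(df)
}

#' Align active positions of two consecutive spectra
#'
#' Order-preserving (non-crossing) pairing of two sorted integer position
#' lists maximizing the total score, where matching positions at distance d
#' scores \code{1 / (1 + d)} and each unmatched position scores the gap
#' score \code{gamma}. Positions farther apart than \code{maxDist} index
#' units are never aligned. Ties are broken toward the pairing with the
#' smaller total matched distance, then lexicographically.
#'
#' @param a,b sorted integer vectors of active positions.
#' @param gamma gap score (default 0.1).
#' @param maxDist maximum matchable distance in index units (default 9).
#' @return list with \code{pairs} (2-column matrix of indices into
#'   \code{a} and \code{b}) and \code{score}.
#' @export
alignActivePositions <- function(a, b, gamma = 0.1, maxDist = 9) {
  na <- length(a); nb <- length(b)
  stopifnot(!is.unsorted(a), !is.unsorted(b))
  ## dp over prefixes; tie-break on smaller matched-distance total
  SC <- matrix(-Inf, na + 1L, nb + 1L)
  DS <- matrix(Inf, na + 1L, nb + 1L)     # total matched |d|
  MV <- matrix(0L, na + 1L, nb + 1L)      # 1 = match, 2 = gap in a, 3 = gap in b
  SC[1L, ] <- gamma * (0:nb)
  SC[, 1L] <- gamma * (0:na)
  DS[1L, ] <- 0; DS[, 1L] <- 0
  MV[1L, -1L] <- 3L; MV[-1L, 1L] <- 2L
  eps <- 1e-12
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      d <- abs(a[i] - b[j])
      sc <- c(if (d <= maxDist) SC[i, j] + 1 / (1 + d) else -Inf,
              SC[i, j + 1L] + gamma,
              SC[i + 1L, j] + gamma)
      ds <- c(if (d <= maxDist) DS[i, j] + d else Inf,
              DS[i, j + 1L],
              DS[i + 1L, j])
      best <- which(sc >= max(sc) - eps)
      if (length(best) > 1L) best <- best[which.min(ds[best])]
      SC[i + 1L, j + 1L] <- sc[best]
      DS[i + 1L, j + 1L] <- ds[best]
      MV[i + 1L, j + 1L] <- best
    }
  }
  ## traceback
  i <- na; j <- nb
  pi <- integer(0); pj <- integer(0)
  while (i > 0L || j > 0L) {
    mv <- MV[i + 1L, j + 1L]
    if (mv == 1L) {
      pi <- c(i, pi); pj <- c(j, pj)
      i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(pairs = cbind(a = pi, b = pj), score = SC[na + 1L, nb + 1L])
}

## chase downward zero crossings of the discrete derivative along rows of S
## (zero-padded), chaining them across consecutive rows into finalized
## position lists ("bands"); returns a list of 2-column (row, col) matrices
## in original matrix coordinates
.zeroCrossingBands <- function(S, gamma = 0.1, maxDist = 9) {
  nr <- nrow(S); nc <- ncol(S)
  P <- matrix(0, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- S
  finalized <- list(); nf <- 0L
  active <- list()                       # each: list(rows=, cols=)
  lastPos <- integer(0)
  for (rp in 2:(nr + 1L)) {
    row <- P[rp, ]
    D <- diff(row)                       # D[t] = P[rp, t+1] - P[rp, t]
    cross <- which(D[-1L] < 0 & D[-length(D)] >= 0) + 1L  # padded col index
    ## a drop that exists only because of the zero pad at the far border
    ## (position nc+1) is no evidence of an apex: a still-rising signal at
    ## the matrix edge must not become a candidate
    cross <- cross[cross <= nc]
    pos <- cross - 1L                    # original column index, 1..nc-1
    ## align last positions of active lists with the new positions
    ord <- order(lastPos)
    active <- active[ord]; lastPos <- lastPos[ord]
    al <- alignActivePositions(lastPos, pos, gamma, maxDist)
    matchedA <- al$pairs[, 1L]; matchedB <- al$pairs[, 2L]
    newActive <- list(); newLast <- integer(0)
    ## (2) extend matched lists
    for (k in seq_along(matchedA)) {
      lst <- active[[matchedA[k]]]
      lst$rows <- c(lst$rows, rp - 1L)
      lst$cols <- c(lst$cols, pos[matchedB[k]])
      newActive[[length(newActive) + 1L]] <- lst
      newLast <- c(newLast, pos[matchedB[k]])
    }
    ## (3) finalize unmatched active lists
    for (k in setdiff(seq_along(active), matchedA)) {
      nf <- nf + 1L
      finalized[[nf]] <- active[[k]]
    }
    ## (1) open new lists for unmatched new positions
    for (k in setdiff(seq_along(pos), matchedB)) {
      newActive[[length(newActive) + 1L]] <- list(rows = rp - 1L,
                                                  cols = pos[k])
      newLast <- c(newLast, pos[k])
    }
    active <- newActive; lastPos <- newLast
  }
  for (k in seq_along(active)) {
    nf <- nf + 1L
    finalized[[nf]] <- active[[k]]
  }
  lapply(finalized, function(l) cbind(row = l$rows, col = l$cols))
}

#' Cross finding candidate detection (cf)
#'
#' Marks downward zero crossings of the discrete derivatives along both axes
#' of the zero-padded matrix (indices where the derivative turns from >= 0 to
#' < 0), chains them across consecutive spectra (and, transposed, across
#' consecutive chromatograms) by order-preserving alignment into vertical and
#' horizontal bands, and intersects the two band sets. For every pair of
#' bands sharing cells, the shared cell with the highest signal is reported
#' (ties to the smaller row, then column index); candidates must exceed the
#' intensity threshold \code{I}.
#'
#' @param m an \linkS4class{IMSMeasurement} (normally preprocessed).
#' @param params parameter list; uses \code{intensity_threshold}.
#' @return An \linkS4class{IMSPeakList} of candidates.
#' @export
crossFind <- function(m, params = defaultParameters()) {
  I <- params$intensity_threshold
  S <- intensities(m)
  nr <- nrow(S)
  vert <- .zeroCrossingBands(S)             # crossings along t, per spectrum
  horiz <- .zeroCrossingBands(t(S))         # crossings along r, per chromatogram
  if (!length(vert) || !length(horiz)) return(IMSPeakList())

  ## cell -> vertical band id
  vid <- integer(length(S))
  for (k in seq_along(vert)) {
    cells <- (vert[[k]][, "col"] - 1L) * nr + vert[[k]][, "row"]
    vid[cells] <- k
  }
  ri <- integer(0); ti <- integer(0)
  for (h in seq_along(horiz)) {
    rows <- horiz[[h]][, "col"]            # transposed back
    cols <- horiz[[h]][, "row"]
    cells <- (cols - 1L) * nr + rows
    v <- vid[cells]
    hit <- v > 0L
    if (!any(hit)) next
    for (vk in unique(v[hit])) {
      sel <- which(hit & v == vk)
      sig <- S[cells[sel]]
      best <- sel[order(-sig, rows[sel], cols[sel])][1L]
      ri <- c(ri, rows[best]); ti <- c(ti, cols[best])
    }
  }
  if (!length(ri)) return(IMSPeakList())
  keep <- !duplicated(cbind(ri, ti))
  ri <- ri[keep]; ti <- ti[keep]
  keep <- S[cbind(ri, ti)] > I
  if (!any(keep)) return(IMSPeakList())
  .candidateList(m, ri[keep], ti[keep])
}
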