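## Weighted cluster editing: partition the vertex set of a weighted graph
## into cliques with minimum total modification cost |w(u,v)| over toggled
## pairs (insert pairs with w < 0 that end up inside a cluster, delete pairs
## with w >= 0 that end up across clusters). Solved exactly per connected
## component by subset dynamic programming up to a size threshold, by a
## greedy pivot heuristic with single-vertex local moves above it.

#' Cost of a clustering under the cluster-editing objective
#'
#' @param W symmetric numeric weight matrix (diagonal ignored).
#' @param membership integer cluster labels, one per vertex.
#' @return total edit cost.
#' @export
clusterEditingCost <- function(W, membership) {
  n <- nrow(W)
  cost <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same <- membership[i] == membership[j]
      w <- W[i, j]
      cost <- cost + if (same) max(-w, 0) else max(w, 0)
    }
  }
  cost
}

#' Solve weighted cluster editing
#'
#' Decomposes the graph into connected components of the edge set
#' \code{w >= 0} (optimal clusters never span components) and solves each
#' component: exactly by subset dynamic programming for components of at
#' most \code{exactThreshold} vertices, by a deterministic greedy pivot
#' heuristic refined with single-vertex moves above that. Weights of
#' \code{-Inf} mark pairs that are never joined.
#'
#' @param W symmetric numeric weight matrix; \code{W[u,v] >= 0} means an
#'   edge.
#' @param exactThreshold largest component size solved exactly (default 12).
#' @return list with \code{membership} (integer labels 1..k),
#'   \code{cost} (total edit cost) and \code{status} ("exact" if every
#'   component was solved exactly, else "heuristic").
#' @export
solveClusterEditing <- function(W, exactThreshold = 12L) {
  n <- nrow(W)
  stopifnot(n == ncol(W))
  if (n == 0L)
    return(list(membership = integer(0), cost = 0, status = "exact"))
  if (n == 1L)
    return(list(membership = 1L, cost = 0, status = "exact"))
  Wf <- W
  Wf[is.infinite(Wf) & Wf < 0] <- -1e15
  adj <- Wf >= 0
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  membership <- integer(n)
  nextLabel <- 0L
  status <- "exact"
  for (cc in seq_len(comp$no)) {
    verts <- which(comp$membership == cc)
    k <- length(verts)
    if (k == 1L) {
      part <- 1L
    } else if (k <= exactThreshold) {
      part <- .cePartitionExact(Wf[verts, verts, drop = FALSE])
    } else {
      part <- .cePartitionGreedy(Wf[verts, verts, drop = FALSE])
      status <- "heuristic"
    }
    membership[verts] <- part + nextLabel
    nextLabel <- nextLabel + max(part)
  }
  list(membership = membership, cost = clusterEditingCost(W, membership),
       status = status)
}

## exact: maximize the sum over clusters of the net intra-cluster weight
## (equivalent to minimizing the edit cost) by DP over vertex subsets
.cePartitionExact <- function(W) {
  k <- nrow(W)
  full <- bitwShiftL(1L, k) - 1L
  bits <- bitwShiftL(1L, 0:(k - 1L))
  ## net[mask] = sum of pairwise weights inside mask
  net <- numeric(full + 1L)
  for (mask in seq_len(full)) {
    v <- .lowestBit(mask)
    rest <- mask - bits[v]
    s <- net[rest + 1L]
    if (rest > 0L) {
      us <- which(bitwAnd(rest, bits) > 0L)
      s <- s + sum(W[us, v])
    }
    net[mask + 1L] <- s
  }
  dp <- numeric(full + 1L)
  choice <- integer(full + 1L)
  for (mask in seq_len(full)) {
    v <- .lowestBit(mask)
    best <- -Inf; bestSub <- 0L
    sub <- mask
    while (sub > 0L) {
      if (bitwAnd(sub, bits[v]) > 0L) {
        val <- net[sub + 1L] + dp[bitwAnd(mask, bitwNot(sub)) + 1L]
        if (val > best + 1e-12) {
          best <- val; bestSub <- sub
        }
      }
      sub <- bitwAnd(sub - 1L, mask)
    }
    dp[mask + 1L] <- best
    choice[mask + 1L] <- bestSub
  }
  part <- integer(k)
  mask <- full
  label <- 0L
  while (mask > 0L) {
    label <- label + 1L
    sub <- choice[mask + 1L]
    part[which(bitwAnd(sub, bits) > 0L)] <- label
    mask <- bitwAnd(mask, bitwNot(sub))
  }
  part
}

.lowestBit <- function(mask) {
  b <- 1L
  while (bitwAnd(mask, bitwShiftL(1L, b - 1L)) == 0L) b <- b + 1L
  b
}

## heuristic: greedy pivot clustering followed by single-vertex local moves
.cePartitionGreedy <- function(W) {
  k <- nrow(W)
  part <- integer(k)
  label <- 0L
  for (v in seq_len(k)) {
    if (part[v] > 0L) next
    label <- label + 1L
    part[v] <- label
    free <- which(part == 0L)
    join <- free[W[v, free] > 0]
    part[join] <- label
  }
  ## local moves: relocate single vertices while the cost drops
  repeat {
    improved <- FALSE
    for (v in seq_len(k)) {
      labels <- unique(part)
      gains <- vapply(c(labels, max(labels) + 1L), function(lab) {
        inLab <- part == lab
        inLab[v] <- FALSE
        own <- part == part[v]
        own[v] <- FALSE
        ## move v to lab: pairs to lab become intra, pairs to own become inter
        sum(pmax(-W[v, inLab], 0)) - sum(pmax(W[v, inLab], 0)) -
          sum(pmax(-W[v, own], 0)) + sum(pmax(W[v, own], 0))
      }, numeric(1))
      best <- which.min(gains)
      if (gains[best] < -1e-9) {
        part[v] <- c(labels, max(labels) + 1L)[best]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  match(part, unique(part))
}
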