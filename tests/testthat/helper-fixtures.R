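# shared fixtures and independent brute-force oracles

# measurement wrapper around a plain matrix with unit-ish grids
makeMeasurement <- function(S, name = "fix",
                            r = seq(0, by = 1, length.out = nrow(S)),
                            t = seq(0.4, by = 0.001, length.out = ncol(S))) {
  IMSMeasurement(name, r, t, S)
}

# smooth separable 2D bell (discrete gaussian product), apex 'amp' at (r0, t0)
bellMatrix <- function(nr, nc, r0, t0, amp, sdR = 3, sdT = 3) {
  pr <- exp(-0.5 * ((seq_len(nr) - r0) / sdR)^2)
  pt <- exp(-0.5 * ((seq_len(nc) - t0) / sdT)^2)
  amp * outer(pr, pt)
}

peakListFromCoords <- function(r, t, signal,
                               ri = rep(-1L, length(r)),
                               ti = rep(-1L, length(r)),
                               name = "fix") {
  IMSPeakList(data.frame(
    measurement_name = name,
    peak_name = sprintf("Q%d", seq_along(r)),
    retention_time = r, inverse_reduced_mobility = t,
    signal = signal, volume = signal,
    retention_time_index = ri, inverse_reduced_mobility_index = ti,
    stringsAsFactors = FALSE))
}

# Inverse Gaussian sampler (Michael-Schucany-Haas transformation)
statmodInvGauss <- function(n, mu, lambda) {
  nu <- rnorm(n)^2
  x <- mu + mu^2 * nu / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * nu + mu^2 * nu^2)
  u <- runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

# oracle: exhaustive local-maxima scan with BFS flood fill (8-connectivity)
bruteLocalMaxima <- function(S, I, Amin) {
  nr <- nrow(S); nc <- ncol(S)
  out <- NULL
  compSize <- function(r0, t0) {
    seen <- matrix(FALSE, nr, nc)
    queue <- list(c(r0, t0)); seen[r0, t0] <- TRUE; size <- 0L
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]; size <- size + 1L
      for (dr in -1:1) for (dt in -1:1) {
        rr <- cell[1] + dr; tt <- cell[2] + dt
        if (rr >= 1 && rr <= nr && tt >= 1 && tt <= nc &&
            !seen[rr, tt] && S[rr, tt] >= I) {
          seen[rr, tt] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, tt)
        }
      }
    }
    size
  }
  for (r0 in seq_len(nr)) for (t0 in seq_len(nc)) {
    if (S[r0, t0] < I) next
    isMax <- TRUE
    for (dr in -1:1) for (dt in -1:1) {
      if (dr == 0 && dt == 0) next
      rr <- r0 + dr; tt <- t0 + dt
      if (rr < 1 || rr > nr || tt < 1 || tt > nc) next
      if (S[rr, tt] > S[r0, t0] || S[rr, tt] < I) isMax <- FALSE
    }
    if (isMax && compSize(r0, t0) >= Amin)
      out <- rbind(out, c(r0, t0))
  }
  out
}

# oracle: exhaustive search over all monotone pairings of two sorted lists
bruteAlignScore <- function(a, b, gamma = 0.1, maxDist = 9) {
  rec <- function(i, j) {
    if (i > length(a)) return(gamma * (length(b) - j + 1))
    if (j > length(b)) return(gamma * (length(a) - i + 1))
    best <- max(rec(i + 1, j) + gamma, rec(i, j + 1) + gamma)
    d <- abs(a[i] - b[j])
    if (d <= maxDist)
      best <- max(best, rec(i + 1, j + 1) + 1 / (1 + d))
    best
  }
  rec(1, 1)
}

# oracle: minimum cluster-editing cost by enumerating all set partitions
# (restricted growth strings), n <= 8
bruteClusterEditingCost <- function(W) {
  n <- nrow(W)
  best <- Inf
  labels <- integer(n)
  rec <- function(i, maxLab) {
    if (i > n) {
      best <<- min(best, clusterEditingCost(W, labels))
      return(invisible())
    }
    for (lab in seq_len(maxLab + 1L)) {
      labels[i] <<- lab
      rec(i + 1L, max(maxLab, lab))
    }
  }
  rec(1L, 0L)
  best
}
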