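#' Default module parameters
#'
#' The parameter map shared by all pipeline stages, with the standard
#' evaluation defaults: \code{fftcutoff} (lowpass radial frequency index,
#' 500), \code{smoothing_radius} (rho, window half-width in index units, 4),
#' \code{area_size} (minimum supra-threshold area for local maxima, 9),
#' \code{intensity_threshold} (I, signal units, 10), \code{ce_weight_exponent}
#' (b, 26), \code{tol_rt} (c, seconds, 3), \code{tol_rt_percent} (p, 0.1),
#' \code{tol_rim} (delta-t, Vs/cm2, 0.003) and \code{expansion_size}
#' (box margin for peak modeling, index units, 10).
#'
#' @param ... overrides as \code{key = value} pairs.
#' @return named list of parameters.
#' @examples
#' defaultParameters(intensity_threshold = 5)
#' @export
defaultParameters <- function(...) {
  p <- list(
    fftcutoff = 500,
    smoothing_radius = 4,
    area_size = 9,
    intensity_threshold = 10,
    ce_weight_exponent = 26,
    tol_rt = 3,
    tol_rt_percent = 0.1,
    tol_rim = 0.003,
    expansion_size = 10)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  for (k in names(over)) p[[k]] <- over[[k]]
  .validateParameters(p)
  p
}

.validateParameters <- function(p) {
  num <- unlist(p[vapply(p, is.numeric, logical(1))])
  if (any(!is.finite(num)))
    stop("all parameter values must be finite")
  for (k in c("tol_rt", "tol_rt_percent", "tol_rim"))
    if (!is.null(p[[k]]) && p[[k]] <= 0)
      stop(sprintf("tolerance '%s' must be > 0", k))
  if (!is.null(p$area_size) && p$area_size < 9)
    stop("area_size must be >= 9")
  if (!is.null(p$smoothing_radius) && p$smoothing_radius < 0)
    stop("smoothing_radius must be >= 0")
  invisible(TRUE)
}

#' Tolerance parameters for peak picking and matching
#'
#' The minimum distances below which two peaks are considered the same
#' compound: a constant \code{deltaT} on the reduced inverse mobility axis
#' and an affine-linear \code{deltaR(r) = p * r + c} on the retention time
#' axis (peak widths grow with retention time).
#'
#' @param params parameter list (see \code{\link{defaultParameters}}).
#' @return list with fields \code{tol_rim}, \code{tol_rt}, \code{tol_rt_percent}.
#' @export
toleranceParams <- function(params = defaultParameters()) {
  list(tol_rim = params$tol_rim, tol_rt = params$tol_rt,
       tol_rt_percent = params$tol_rt_percent)
}

#' Retention-time tolerance at a given retention time
#'
#' \code{deltaR(r) = tol_rt_percent * r + tol_rt} seconds.
#'
#' @param r retention time in seconds (vectorized).
#' @param tol tolerance parameters (see \code{\link{toleranceParams}}).
#' @return tolerance in seconds.
#' @examples
#' deltaR(0)    # 3
#' deltaR(100)  # 13
#' @export
deltaR <- function(r, tol = toleranceParams()) {
  stopifnot(all(r >= 0))
  tol$tol_rt_percent * r + tol$tol_rt
}

#' Read a flat key=value configuration file
#'
#' One \code{key = value} pair per line; blank lines and lines starting with
#' \code{#} are ignored. Values that parse as numbers become numeric.
#'
#' @param path file path.
#' @return named list.
#' @export
readConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
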