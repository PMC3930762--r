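#' @import methods
NULL

#' IMSMeasurement: an ion mobility spectrum-chromatogram (IMSC)
#'
#' Container for a single MCC/IMS measurement: an \eqn{m \times n} intensity
#' matrix whose rows are IM spectra (fixed retention time) and whose columns
#' are IM chromatograms (fixed reduced inverse mobility). Raw instrument data
#' are unsigned 12-bit integer counts (0..4095); preprocessing promotes the
#' matrix to non-negative reals.
#'
#' @slot name character(1), measurement identifier.
#' @slot retentionTimes numeric(m), strictly increasing retention time grid
#'   in seconds (one value per matrix row).
#' @slot inverseMobilities numeric(n), strictly increasing reduced inverse
#'   mobility grid in Vs/cm2 (one value per matrix column).
#' @slot intensities numeric m x n matrix of signal intensities.
#' @slot metadata named list of character metadata (date, sample info, ...).
#'
#' @examples
#' m <- IMSMeasurement("demo", c(0, 1), c(0.4, 0.5),
#'                     matrix(0:3, 2, 2, byrow = TRUE))
#' dim(m)
#' @export
setClass("IMSMeasurement",
  slots = c(
    name = "character",
    retentionTimes = "numeric",
    inverseMobilities = "numeric",
    intensities = "matrix",
    metadata = "list"
  )
)

setValidity("IMSMeasurement", function(object) {
  msg <- character()
  r <- object@retentionTimes
  t <- object@inverseMobilities
  S <- object@intensities
  if (length(object@name) != 1L || is.na(object@name))
    msg <- c(msg, "'name' must be a single non-NA string")
  if (length(r) < 1L || any(!is.finite(r)))
    msg <- c(msg, "retention times must be finite and non-empty")
  else if (length(r) > 1L && any(diff(r) <= 0))
    msg <- c(msg, "retention times must be strictly increasing")
  if (length(t) < 1L || any(!is.finite(t)))
    msg <- c(msg, "inverse mobilities must be finite and non-empty")
  else if (length(t) > 1L && any(diff(t) <= 0))
    msg <- c(msg, "inverse mobilities must be strictly increasing")
  if (!is.numeric(S))
    msg <- c(msg, "intensity matrix must be numeric")
  if (nrow(S) != length(r) || ncol(S) != length(t))
    msg <- c(msg, sprintf(
      "matrix dimensions (%d x %d) must match grids (%d x %d)",
      nrow(S), ncol(S), length(r), length(t)))
  if (length(object@metadata) && is.null(names(object@metadata)))
    msg <- c(msg, "metadata must be a named list")
  if (length(msg)) msg else TRUE
})

#' Construct an IMSMeasurement
#'
#' @param name measurement identifier.
#' @param retentionTimes strictly increasing retention time grid (s).
#' @param inverseMobilities strictly increasing reduced inverse mobility grid
#'   (Vs/cm2).
#' @param intensities m x n numeric matrix, rows indexed by retention time.
#' @param metadata named list of character metadata.
#' @return An \linkS4class{IMSMeasurement}.
#' @export
IMSMeasurement <- function(name, retentionTimes, inverseMobilities,
                           intensities, metadata = list()) {
  new("IMSMeasurement",
    name = as.character(name),
    retentionTimes = as.numeric(retentionTimes),
    inverseMobilities = as.numeric(inverseMobilities),
    intensities = intensities,
    metadata = metadata)
}

#' @describeIn IMSMeasurement dimensions of the intensity matrix
#' @param x an IMSMeasurement.
#' @export
setMethod("dim", "IMSMeasurement", function(x) dim(x@intensities))

setMethod("show", "IMSMeasurement", function(object) {
  d <- dim(object@intensities)
  cat("IMSMeasurement '", object@name, "'\n", sep = "")
  cat(sprintf("  %d spectra (retention time %.6g..%.6g s)\n",
              d[1], min(object@retentionTimes), max(object@retentionTimes)))
  cat(sprintf("  %d drift points (inverse mobility %.6g..%.6g Vs/cm2)\n",
              d[2], min(object@inverseMobilities),
              max(object@inverseMobilities)))
  cat(sprintf("  intensity range [%.6g, %.6g]\n",
              min(object@intensities), max(object@intensities)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
  invisible(object)
})

## mandatory peak-list columns, in output order
.peakColumns <- c("measurement_name", "peak_name", "retention_time",
                  "inverse_reduced_mobility", "signal", "volume",
                  "retention_time_index", "inverse_reduced_mobility_index")

#' IMSPeakList: a list of extracted peaks
#'
#' Stores one row per peak with the mandatory descriptor columns
#' (measurement name, peak name, retention time, reduced inverse mobility,
#' signal, volume, retention time index, reduced inverse mobility index)
#' plus optional extra model parameters whose keys are recorded in
#' \code{parameterNames}. Indices are 1-based; an index of \code{-1} is the
#' sentinel for "not attached to a measurement grid".
#'
#' @slot peaks data.frame with the mandatory columns followed by one column
#'   per entry of \code{parameterNames}.
#' @slot parameterNames character vector of extra parameter keys shared by
#'   all peaks.
#' @export
setClass("IMSPeakList",
  slots = c(peaks = "data.frame", parameterNames = "character")
)

setValidity("IMSPeakList", function(object) {
  msg <- character()
  df <- object@peaks
  missing <- setdiff(.peakColumns, names(df))
  if (length(missing))
    msg <- c(msg, paste("missing mandatory peak columns:",
                        paste(missing, collapse = ", ")))
  extras <- object@parameterNames
  if (length(extras) && length(setdiff(extras, names(df))))
    msg <- c(msg, "all parameterNames must be present as columns")
  if (nrow(df) && anyDuplicated(df$peak_name))
    msg <- c(msg, "peak names must be unique within a list")
  if (nrow(df) && (any(df$signal < 0) || any(df$volume < 0)))
    msg <- c(msg, "signal and volume must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct an IMSPeakList
#'
#' @param peaks data.frame of peaks; missing mandatory columns are filled
#'   with defaults (volume = signal, indices = -1 sentinel).
#' @param parameterNames character vector of extra parameter column names.
#' @return An \linkS4class{IMSPeakList}.
#' @export
IMSPeakList <- function(peaks = NULL, parameterNames = character()) {
  if (is.null(peaks) || nrow(peaks) == 0L) {
    peaks <- data.frame(
      measurement_name = character(), peak_name = character(),
      retention_time = numeric(), inverse_reduced_mobility = numeric(),
      signal = numeric(), volume = numeric(),
      retention_time_index = integer(),
      inverse_reduced_mobility_index = integer(),
      stringsAsFactors = FALSE)
    for (p in parameterNames) peaks[[p]] <- numeric()
  } else {
    if (is.null(peaks$volume)) peaks$volume <- peaks$signal
    if (is.null(peaks$retention_time_index))
      peaks$retention_time_index <- -1L
    if (is.null(peaks$inverse_reduced_mobility_index))
      peaks$inverse_reduced_mobility_index <- -1L
    if (is.null(peaks$peak_name))
      peaks$peak_name <- sprintf("P%d", seq_len(nrow(peaks)))
    peaks <- peaks[, c(.peakColumns,
                       setdiff(parameterNames, .peakColumns)), drop = FALSE]
  }
  rownames(peaks) <- NULL
  new("IMSPeakList", peaks = peaks, parameterNames = parameterNames)
}

#' @describeIn IMSPeakList number of peaks
#' @param x an IMSPeakList.
#' @export
setMethod("length", "IMSPeakList", function(x) nrow(x@peaks))

setMethod("show", "IMSPeakList", function(object) {
  cat(sprintf("IMSPeakList with %d peak(s)", nrow(object@peaks)))
  if (length(object@parameterNames))
    cat(" and extra parameters:",
        paste(object@parameterNames, collapse = ", "))
  cat("\n")
  if (nrow(object@peaks))
    print(utils::head(object@peaks, 6L))
  invisible(object)
})

#' MixtureModel: heterogeneous finite mixture
#'
#' A finite mixture \eqn{f(x) = \sum_c \omega_c f_c(x)} whose components may
#' be of different parametric families: \code{gaussian} (mean, variance),
#' \code{inverse_gaussian} (mean mu, shape lambda), \code{
#' shifted_inverse_gaussian} (mu, lambda, offset) and \code{uniform}
#' (lo, hi; never re-estimated). Used by baseline correction, de-noising and
#' peak model estimation.
#'
#' @slot components list of components as returned by
#'   \code{\link{mixtureComponent}}.
#' @slot weights numeric mixture coefficients, non-negative, summing to 1.
#' @slot status character(1) fit status ("ok", "degenerate", ...).
#' @export
setClass("MixtureModel",
  slots = c(components = "list", weights = "numeric", status = "character")
)

setValidity("MixtureModel", function(object) {
  msg <- character()
  if (length(object@components) != length(object@weights))
    msg <- c(msg, "one weight per component required")
  if (any(object@weights < 0))
    msg <- c(msg, "weights must be non-negative")
  if (length(object@weights) &&
      abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, "weights must sum to 1")
  kinds <- vapply(object@components, function(cp) cp$kind, character(1))
  bad <- setdiff(kinds, c("gaussian", "inverse_gaussian",
                          "shifted_inverse_gaussian", "uniform"))
  if (length(bad))
    msg <- c(msg, paste("unknown component kind:", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a mixture component
#'
#' @param kind one of "gaussian", "inverse_gaussian",
#'   "shifted_inverse_gaussian", "uniform".
#' @param ... kind-specific parameters: gaussian(mean, var);
#'   inverse_gaussian(mu, lambda); shifted_inverse_gaussian(mu, lambda,
#'   offset); uniform(lo, hi).
#' @param fixed logical; if TRUE the M-step leaves the parameters untouched
#'   (always the case for uniform components).
#' @return list with elements kind, params, fixed.
#' @export
mixtureComponent <- function(kind, ..., fixed = FALSE) {
  kind <- match.arg(kind, c("gaussian", "inverse_gaussian",
                            "shifted_inverse_gaussian", "uniform"))
  params <- list(...)
  required <- switch(kind,
    gaussian = c("mean", "var"),
    inverse_gaussian = c("mu", "lambda"),
    shifted_inverse_gaussian = c("mu", "lambda", "offset"),
    uniform = c("lo", "hi"))
  missing <- setdiff(required, names(params))
  if (length(missing))
    stop(sprintf("component '%s' needs parameters: %s", kind,
                 paste(missing, collapse = ", ")))
  .checkComponentParams(kind, params)
  if (kind == "uniform") fixed <- TRUE
  list(kind = kind, params = params[required], fixed = fixed)
}

.checkComponentParams <- function(kind, p) {
  ok <- switch(kind,
    gaussian = is.finite(p$mean) && is.finite(p$var) && p$var > 0,
    inverse_gaussian = p$mu > 0 && p$lambda > 0,
    shifted_inverse_gaussian = p$mu > 0 && p$lambda > 0 &&
      is.finite(p$offset),
    uniform = p$lo < p$hi)
  if (!isTRUE(ok))
    stop(sprintf("invalid parameters for %s component", kind))
  invisible(TRUE)
}

#' Construct a MixtureModel
#'
#' @param components list of \code{\link{mixtureComponent}} results.
#' @param weights mixture coefficients; defaults to equal weights.
#' @param status fit status string.
#' @return A \linkS4class{MixtureModel}.
#' @export
MixtureModel <- function(components, weights = NULL, status = "ok") {
  if (is.null(weights))
    weights <- rep(1 / length(components), length(components))
  new("MixtureModel", components = components,
      weights = as.numeric(weights), status = status)
}

setMethod("show", "MixtureModel", function(object) {
  cat(sprintf("MixtureModel with %d component(s) [%s]\n",
              length(object@components), object@status))
  for (i in seq_along(object@components)) {
    cp <- object@components[[i]]
    cat(sprintf("  %d: %-25s w=%.4f  %s\n", i, cp$kind, object@weights[i],
                paste(sprintf("%s=%.6g", names(cp$params),
                              unlist(cp$params)), collapse = ", ")))
  }
  invisible(object)
})
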