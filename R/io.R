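## IMSC CSV dialect
##   line 1:  # name=<id>
##   0+ lines:# key=value        (opaque metadata)
##   line:    t_1,...,t_n        (inverse mobility grid, Vs/cm2)
##   m lines: r,S_r1,...,S_rn    (retention time + one spectrum per line)

#' Read an IMSC CSV file
#'
#' Parses the plain-text measurement dialect written by
#' \code{\link{writeIMSC}}: optional \code{# key=value} header lines (with
#' \code{name} giving the measurement identifier), one line with the
#' inverse-mobility grid, then one line per spectrum whose first field is the
#' retention time.
#'
#' @param path file path.
#' @return An \linkS4class{IMSMeasurement}. When the header lacks a name the
#'   file stem is used.
#' @export
readIMSC <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty IMSC file: ", path)
  meta <- list()
  name <- NULL
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    kv <- sub("^#\\s*", "", lines[i])
    eq <- regexpr("=", kv)
    if (eq > 0) {
      key <- trimws(substr(kv, 1L, eq - 1L))
      val <- trimws(substr(kv, eq + 1L, nchar(kv)))
      if (key == "name") name <- val else meta[[key]] <- val
    }
    i <- i + 1L
  }
  if (i > length(lines))
    stop("IMSC file has no grid line (line ", i, ")")
  t <- .parseNumericLine(lines[i], i, path)
  n <- length(t)
  dataLines <- lines[seq.int(i + 1L, length.out = length(lines) - i)]
  dataLines <- dataLines[nzchar(trimws(dataLines))]
  if (!length(dataLines))
    stop("IMSC file has no spectrum rows (after line ", i, ")")
  rows <- lapply(seq_along(dataLines), function(k) {
    v <- .parseNumericLine(dataLines[k], i + k, path)
    if (length(v) != n + 1L)
      stop(sprintf("line %d of '%s': expected %d fields, found %d",
                   i + k, path, n + 1L, length(v)))
    v
  })
  M <- do.call(rbind, rows)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  IMSMeasurement(name, retentionTimes = M[, 1L], inverseMobilities = t,
                 intensities = M[, -1L, drop = FALSE], metadata = meta)
}

.parseNumericLine <- function(line, lineno, path) {
  fields <- trimws(strsplit(line, ",", fixed = TRUE)[[1]])
  v <- suppressWarnings(as.numeric(fields))
  if (any(is.na(v)))
    stop(sprintf("line %d of '%s': non-numeric cell '%s'",
                 lineno, path, fields[which(is.na(v))[1]]))
  v
}

#' Write an IMSC CSV file
#'
#' @param m an \linkS4class{IMSMeasurement}.
#' @param path output file path.
#' @param raw logical; when TRUE the matrix is declared raw instrument data
#'   and negative entries trigger a warning (they are written as-is). The
#'   default auto-detects raw data as an all-integer matrix.
#' @return invisibly, \code{path}.
#' @export
writeIMSC <- function(m, path, raw = NULL) {
  stopifnot(is(m, "IMSMeasurement"))
  S <- intensities(m)
  if (is.null(raw))
    raw <- all(S == round(S))
  if (raw && any(S < 0))
    warning("raw-mode measurement contains negative intensities; ",
            "written as-is")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# name=%s", measurementName(m)), con)
  md <- measurementMetadata(m)
  for (k in names(md))
    writeLines(sprintf("# %s=%s", k, md[[k]]), con)
  fmt <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)
  writeLines(paste(fmt(inverseMobilities(m)), collapse = ","), con)
  body <- cbind(retentionTimes(m), S)
  writeLines(apply(body, 1L, function(v) paste(fmt(v), collapse = ",")), con)
  invisible(path)
}

#' Write a peak list CSV file
#'
#' One line per peak with the mandatory columns (measurement name, peak name,
#' retention time, reduced inverse mobility, signal, volume, retention time
#' index, reduced inverse mobility index) followed by the extra parameters in
#' \code{parameterNames} order.
#'
#' @param pl an \linkS4class{IMSPeakList}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writePeakList <- function(pl, path) {
  stopifnot(is(pl, "IMSPeakList"))
  df <- peaks(pl)[, c(.peakColumns, parameterNames(pl)), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a peak list CSV file
#'
#' Inverse of \code{\link{writePeakList}}. Annotation files may omit volume
#' and the index columns: volume defaults to the signal, and indices are
#' reconstructed by nearest-grid-point snap when \code{measurement} is
#' supplied (ties snap to the lower index), else set to the \code{-1}
#' sentinel.
#'
#' @param path file path.
#' @param measurement optional \linkS4class{IMSMeasurement} whose grids are
#'   used to reconstruct missing indices.
#' @return An \linkS4class{IMSPeakList}.
#' @export
readPeakList <- function(path, measurement = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("measurement_name", "peak_name", "retention_time",
                "inverse_reduced_mobility", "signal")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("peak list is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$peak_name))
    stop("duplicate peak_name in peak list: ",
         df$peak_name[anyDuplicated(df$peak_name)])
  if (is.null(df$volume)) df$volume <- df$signal
  if (is.null(df$retention_time_index) ||
      is.null(df$inverse_reduced_mobility_index)) {
    if (!is.null(measurement)) {
      df$retention_time_index <-
        .snapIndex(df$retention_time, retentionTimes(measurement))
      df$inverse_reduced_mobility_index <-
        .snapIndex(df$inverse_reduced_mobility,
                   inverseMobilities(measurement))
    } else {
      df$retention_time_index <- -1L
      df$inverse_reduced_mobility_index <- -1L
    }
  }
  extras <- setdiff(names(df), .peakColumns)
  IMSPeakList(df, parameterNames = extras)
}

## nearest grid index; ties snap to the lower index (which.min keeps first)
.snapIndex <- function(values, grid) {
  vapply(values, function(v) which.min(abs(grid - v)), integer(1))
}

#' Convert a mobility tolerance to index units
#'
#' On a grid of \code{nPoints} equidistant drift points spanning
#' \code{[0, tMax]} Vs/cm2, a mobility tolerance of \code{tolRim} corresponds
#' to \code{round(nPoints * tolRim / tMax)} grid steps (e.g. 0.003 Vs/cm2 on
#' 2500 points up to 1.45 Vs/cm2 is 5 index units).
#'
#' @param tolRim tolerance in Vs/cm2, >= 0.
#' @param nPoints number of drift grid points, > 1.
#' @param tMax maximum reduced inverse mobility, > 0.
#' @return integer number of index units.
#' @examples
#' rimToleranceIndices(0.003, 2500, 1.45)  # 5
#' @export
rimToleranceIndices <- function(tolRim, nPoints, tMax) {
  if (tMax <= 0) stop("tMax must be positive")
  if (nPoints <= 1) stop("nPoints must exceed 1")
  if (tolRim < 0) stop("tolRim must be >= 0")
  as.integer(round(nPoints * tolRim / tMax))
}
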