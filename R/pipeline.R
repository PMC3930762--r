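## Pipeline orchestration: canonical naming, enumeration of all distinct
## module combinations, and execution. A pipeline is named by concatenating
## module shortcuts with '-': a permutation of the three preprocessing
## modules (bc, dn, s; all mandatory), one candidate detector (lm, cf), then
## peak picking (ms, ce, emc) and peak modeling (pme, or the empty module e)
## in either order. "x-e" and "e-x" are the same computational pipeline, so
## the canonical spelling puts e last.

.prepModules <- c(bc = "baselineCorrection", dn = "denoise", s = "smoothIMSC")
.detModules <- c(lm = "localMaxima", cf = "crossFind")
.pickModules <- c(ms = "mergeByIntensity", ce = "clusterEditPick",
                  emc = "emClusterPick")

#' Parse a pipeline name
#'
#' @param name 5 or 6 dash-joined module shortcuts, e.g.
#'   \code{"dn-s-bc-cf-ce"} or \code{"s-dn-bc-lm-emc-e"} (a trailing
#'   \code{-e} is optional).
#' @return a pipeline spec: list with \code{preprocessing} (character(3)),
#'   \code{detection}, \code{stages} (picking/modeling shortcuts in
#'   execution order) and \code{name} (canonical).
#' @export
parsePipelineName <- function(name) {
  tokens <- strsplit(name, "-", fixed = TRUE)[[1]]
  if (length(tokens) < 5L || length(tokens) > 6L)
    stop("pipeline name must have 5 or 6 modules: ", name)
  prep <- tokens[1:3]
  if (!setequal(prep, c("bc", "dn", "s")))
    stop("first three modules must be a permutation of bc, dn, s: ", name)
  det <- tokens[4]
  if (!det %in% names(.detModules))
    stop("unknown candidate detection module: ", det)
  rest <- tokens[-(1:4)]
  if (length(rest) == 1L) rest <- c(rest, "e")
  isPick <- rest %in% names(.pickModules)
  isModel <- rest %in% c("pme", "e")
  if (any(!isPick & !isModel))
    stop("unknown module: ", paste(rest[!isPick & !isModel], collapse = ", "))
  if (sum(isPick) != 1L)
    stop("exactly one peak picking module required: ", name)
  if (sum(isModel) != 1L)
    stop("exactly one peak modeling module required: ", name)
  ## canonical order: the empty module is always spelled last
  if (rest[1] == "e") rest <- rev(rest)
  spec <- list(preprocessing = prep, detection = det, stages = rest)
  spec$name <- paste(c(prep, det, rest), collapse = "-")
  spec
}

#' Enumerate all distinct pipelines
#'
#' All combinations of a preprocessing order (6 permutations), a candidate
#' detector (2), a picker (3) and a modeling placement (none, after picking,
#' before picking): 6 x 2 x 9 = 108 distinct computational pipelines. With
#' \code{includeRedundant = TRUE} the 144 raw ordered combinations are
#' returned, including the redundant spellings that place the empty module
#' third instead of fourth.
#'
#' @param includeRedundant logical.
#' @return character vector of pipeline names.
#' @export
enumeratePipelines <- function(includeRedundant = FALSE) {
  perms <- list(c("bc", "dn", "s"), c("bc", "s", "dn"),
                c("dn", "bc", "s"), c("dn", "s", "bc"),
                c("s", "bc", "dn"), c("s", "dn", "bc"))
  stageCombos <- list()
  for (p in names(.pickModules)) {
    stageCombos <- c(stageCombos,
                     list(c(p, "e"), c(p, "pme"), c("pme", p)))
    if (includeRedundant)
      stageCombos <- c(stageCombos, list(c("e", p)))
  }
  out <- character(0)
  for (pre in perms)
    for (det in names(.detModules))
      for (st in stageCombos)
        out <- c(out, paste(c(pre, det, st), collapse = "-"))
  out
}

#' Run a peak extraction pipeline
#'
#' Applies the three preprocessing modules in the specified order, detects
#' peak candidates, and runs picking and (optional) modeling in the
#' specified order. The result carries the measurement name, generated peak
#' IDs, coordinates, signal, volume and grid indices, sorted by descending
#' signal.
#'
#' @param spec pipeline name (string) or a spec from
#'   \code{\link{parsePipelineName}}.
#' @param m a raw \linkS4class{IMSMeasurement}.
#' @param params parameter list (see \code{\link{defaultParameters}}).
#' @param verbose log per-stage timing to standard error.
#' @return An \linkS4class{IMSPeakList}.
#' @export
runPipeline <- function(spec, m, params = defaultParameters(),
                        verbose = FALSE) {
  if (is.character(spec)) spec <- parsePipelineName(spec)
  stopifnot(is(m, "IMSMeasurement"))
  stage <- function(label, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", label,
                   conditionMessage(e)), call. = FALSE))
    if (verbose)
      message(sprintf("[%s] %.2f s", label, proc.time()[3] - t0))
    out
  }
  for (p in spec$preprocessing)
    m <- stage(p, get(.prepModules[[p]])(m, params))
  pl <- stage(spec$detection, get(.detModules[[spec$detection]])(m, params))
  for (st in spec$stages) {
    pl <- if (st %in% names(.pickModules))
      stage(st, get(.pickModules[[st]])(pl, params))
    else if (st == "pme")
      stage(st, fitPeakModels(m, pl, params))
    else
      stage(st, emptyModel(pl))
  }
  df <- peaks(pl)
  if (nrow(df)) {
    df <- df[.signalOrder(df), , drop = FALSE]
    df$peak_name <- sprintf("P%d", seq_len(nrow(df)))
    df$measurement_name <- measurementName(m)
    rownames(df) <- NULL
  }
  IMSPeakList(df, parameterNames = parameterNames(pl))
}
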