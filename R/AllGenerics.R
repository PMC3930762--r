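#' Accessors for IMSMeasurement and IMSPeakList
#'
#' @param x an \linkS4class{IMSMeasurement} or \linkS4class{IMSPeakList}.
#' @return \code{measurementName}: character(1); \code{retentionTimes},
#'   \code{inverseMobilities}: numeric grids; \code{intensities}: the
#'   intensity matrix; \code{measurementMetadata}: named list;
#'   \code{peaks}: data.frame of peaks; \code{parameterNames}: character
#'   vector of extra parameter keys.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("measurementName", function(x) standardGeneric("measurementName"))
#' @rdname accessors
#' @export
setGeneric("retentionTimes", function(x) standardGeneric("retentionTimes"))
#' @rdname accessors
#' @export
setGeneric("inverseMobilities",
           function(x) standardGeneric("inverseMobilities"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("intensities<-", function(x, value)
  standardGeneric("intensities<-"))
#' @rdname accessors
#' @export
setGeneric("measurementMetadata",
           function(x) standardGeneric("measurementMetadata"))
#' @rdname accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))
#' @rdname accessors
#' @export
setGeneric("parameterNames", function(x) standardGeneric("parameterNames"))

#' @rdname accessors
#' @export
setMethod("measurementName", "IMSMeasurement", function(x) x@name)
#' @rdname accessors
#' @export
setMethod("retentionTimes", "IMSMeasurement", function(x) x@retentionTimes)
#' @rdname accessors
#' @export
setMethod("inverseMobilities", "IMSMeasurement",
          function(x) x@inverseMobilities)
#' @rdname accessors
#' @export
setMethod("intensities", "IMSMeasurement", function(x) x@intensities)
#' @rdname accessors
#' @param value replacement intensity matrix (same dimensions).
#' @export
setMethod("intensities<-", "IMSMeasurement", function(x, value) {
  x@intensities <- value
  validObject(x)
  x
})
#' @rdname accessors
#' @export
setMethod("measurementMetadata", "IMSMeasurement", function(x) x@metadata)
#' @rdname accessors
#' @export
setMethod("peaks", "IMSPeakList", function(x) x@peaks)
#' @rdname accessors
#' @export
setMethod("parameterNames", "IMSPeakList", function(x) x@parameterNames)
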