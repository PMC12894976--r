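#' Accessors for TPP containers
#'
#' \code{temperatures()} returns the channel temperatures (degrees C),
#' \code{condition()} the condition label, \code{intensities()} the raw
#' reporter-intensity matrix and \code{abundance()} the per-protein
#' LFQ-style abundances (or \code{NULL}).
#'
#' @param x a \linkS4class{ProteomeQuant}.
#' @return See the individual descriptions.
#' @name ProteomeQuant-accessors
NULL

#' @rdname ProteomeQuant-accessors
#' @export
setGeneric("temperatures", function(x) standardGeneric("temperatures"))

#' @rdname ProteomeQuant-accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname ProteomeQuant-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname ProteomeQuant-accessors
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' @rdname ProteomeQuant-accessors
setMethod("temperatures", "ProteomeQuant",
          function(x) colData(x)$temperature)

#' @rdname ProteomeQuant-accessors
setMethod("condition", "ProteomeQuant",
          function(x) metadata(x)$condition)

#' @rdname ProteomeQuant-accessors
setMethod("intensities", "ProteomeQuant",
          function(x) assay(x, "intensity"))

#' @rdname ProteomeQuant-accessors
setMethod("abundance", "ProteomeQuant",
          function(x) rowData(x)$abundance)

#' @rdname meltingPoint
#' @export
setGeneric("meltingPoint", function(object) standardGeneric("meltingPoint"))

#' @rdname meltSlope
#' @export
setGeneric("meltSlope", function(object) standardGeneric("meltSlope"))
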