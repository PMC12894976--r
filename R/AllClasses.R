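#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData colData rowData<- colData<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' The temperature gradient of a ten-channel TMT melting experiment
#'
#' Default channel temperatures (degrees Celsius) for a ten-point thermal
#' gradient as used in TMT10-based thermal proteome profiling.
#'
#' @format Numeric vector of length 10, strictly increasing.
#' @export
defaultTemperatures <- c(30, 34, 38, 43, 47, 52, 56, 60, 66, 70)

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' ProteomeQuant: protein x temperature-channel intensity container
#'
#' A \linkS4class{SummarizedExperiment} holding one TPP condition: a matrix
#' of reporter intensities (proteins in rows, temperature channels in
#' columns, ordered by ascending temperature), the channel temperatures in
#' \code{colData()$temperature}, the condition label in
#' \code{metadata()$condition}, and an optional per-protein abundance (LFQ
#' style) in \code{rowData()$abundance}.
#'
#' @slot .. inherits all slots from SummarizedExperiment.
#' @export
setClass("ProteomeQuant", contains = "SummarizedExperiment")

setValidity("ProteomeQuant", function(object) {
  msg <- character()
  if (!"intensity" %in% names(assays(object)))
    msg <- c(msg, "assay 'intensity' is required")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "protein ids (rownames) must be present and unique")
  if (!"temperature" %in% names(colData(object)))
    msg <- c(msg, "colData column 'temperature' is required")
  else {
    tt <- colData(object)$temperature
    if (length(tt) != ncol(object))
      msg <- c(msg, "one temperature per channel is required")
    if (any(!is.finite(tt)) || any(diff(tt) <= 0))
      msg <- c(msg, "temperatures must be finite and strictly increasing")
  }
  if (!is.character(metadata(object)$condition) ||
      length(metadata(object)$condition) != 1L)
    msg <- c(msg, "metadata 'condition' must be a single label")
  x <- assay(object, "intensity")
  if (any(x < 0, na.rm = TRUE))
    msg <- c(msg, "intensities must be non-negative or missing (NA)")
  if (length(msg)) msg else TRUE
})

#' Construct a ProteomeQuant object
#'
#' @param intensities numeric matrix, proteins x channels; non-negative or
#'   \code{NA} for missing. Rownames are protein accessions.
#' @param temperatures numeric vector of channel temperatures (degrees C);
#'   columns are reordered so temperatures increase.
#' @param condition single condition label, e.g. \code{"control"} or
#'   \code{"ficoll400"}.
#' @param abundance optional per-protein abundance (LFQ-style) vector.
#'
#' @return A \linkS4class{ProteomeQuant}.
#' @examples
#' m <- matrix(runif(20, 1e5, 1e6), nrow = 2,
#'             dimnames = list(c("P1", "P2"), NULL))
#' pq <- ProteomeQuant(m, defaultTemperatures, "control")
#' temperatures(pq)
#' @export
ProteomeQuant <- function(intensities, temperatures, condition,
                          abundance = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (length(temperatures) != ncol(intensities))
    stop("'temperatures' must have one value per intensity column")
  ord <- order(temperatures)
  intensities <- intensities[, ord, drop = FALSE]
  temperatures <- temperatures[ord]
  # deterministic row order independent of input file order
  rord <- order(rownames(intensities))
  intensities <- intensities[rord, , drop = FALSE]
  colnames(intensities) <- sprintf("T%g", temperatures)
  rd <- DataFrame(row.names = rownames(intensities))
  if (!is.null(abundance)) {
    if (length(abundance) != nrow(intensities))
      stop("'abundance' must have one value per protein")
    rd$abundance <- as.numeric(abundance)[rord]
  }
  se <- SummarizedExperiment(
    assays = SimpleList(intensity = intensities),
    rowData = rd,
    colData = DataFrame(temperature = temperatures,
                        row.names = colnames(intensities)),
    metadata = list(condition = as.character(condition))
  )
  new("ProteomeQuant", se)
}

#' CrowderPropertyTable: physico-chemical descriptors of crowding reagents
#'
#' A validated \linkS4class{DFrame} with one row per crowding reagent and
#' the descriptors used by the mechanism regression: molecular weight (kDa),
#' intrinsic viscosity (mL/g), polar atom fraction (dimensionless, in
#' [0, 1]), hydrophobicity index (dimensionless) and polymer topology
#' (linear/branched). Extra columns are preserved as opaque descriptors.
#'
#' @export
setClass("CrowderPropertyTable", contains = "DFrame")

.crowderDescriptors <- c("molecular_weight", "intrinsic_viscosity",
                         "polar_atom_fraction", "hydrophobicity_index",
                         "topology")

setValidity("CrowderPropertyTable", function(object) {
  msg <- character()
  need <- c("reagent", .crowderDescriptors)
  miss <- setdiff(need, colnames(object))
  if (length(miss))
    msg <- c(msg, paste0("missing column(s): ", paste(miss, collapse = ", ")))
  if (nrow(object) == 0L)
    msg <- c(msg, "property table is empty")
  if ("reagent" %in% colnames(object) && anyDuplicated(object$reagent))
    msg <- c(msg, "reagent names must be unique")
  if ("polar_atom_fraction" %in% colnames(object)) {
    paf <- object$polar_atom_fraction
    if (any(paf < 0 | paf > 1, na.rm = TRUE))
      msg <- c(msg, "polar_atom_fraction must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CrowderPropertyTable
#'
#' @param df data.frame with columns \code{reagent}, \code{molecular_weight},
#'   \code{intrinsic_viscosity}, \code{polar_atom_fraction},
#'   \code{hydrophobicity_index}, \code{topology}; optionally
#'   \code{mass_concentration} (mg/mL) and further numeric descriptors.
#' @return A \linkS4class{CrowderPropertyTable}.
#' @export
CrowderPropertyTable <- function(df) {
  new("CrowderPropertyTable", DataFrame(df, check.names = FALSE))
}

#' MeltParams: parameters of the three-parameter sigmoid melting model
#'
#' The melting model is f(T) = (1 - p) / (1 + exp(b - a/T)) + p with
#' temperature T in degrees Celsius: \code{a} (degree-scaled shape, > 0),
#' \code{b} (dimensionless offset, > 0) and \code{plateau} p, the
#' post-transition soluble fraction in [0, 0.5).
#'
#' @slot a numeric(1), > 0.
#' @slot b numeric(1), > 0.
#' @slot plateau numeric(1) in [0, 1); melting point defined only for < 0.5.
#' @export
setClass("MeltParams",
         representation(a = "numeric", b = "numeric", plateau = "numeric"),
         prototype(a = NA_real_, b = NA_real_, plateau = NA_real_))

setValidity("MeltParams", function(object) {
  msg <- character()
  for (s in c("a", "b", "plateau"))
    if (length(slot(object, s)) != 1L)
      msg <- c(msg, sprintf("'%s' must be a single value", s))
  if (length(msg)) return(msg)
  a <- object@a; b <- object@b; p <- object@plateau
  if (is.finite(a) && a <= 0) msg <- c(msg, "'a' must be > 0")
  if (is.finite(b) && b < 0) msg <- c(msg, "'b' must be >= 0")
  if (is.finite(p) && (p < 0 || p >= 1))
    msg <- c(msg, "'plateau' must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname MeltParams-class
#' @param a,b,plateau model parameters (see class description).
#' @return \code{MeltParams()} returns a \linkS4class{MeltParams}.
#' @examples
#' mp <- MeltParams(a = 3000, b = 10, plateau = 0)
#' meltingPoint(mp)
#' @export
MeltParams <- function(a, b, plateau = 0) {
  new("MeltParams", a = as.numeric(a), b = as.numeric(b),
      plateau = as.numeric(plateau))
}

#' MeltFit: summary of one fitted melting curve
#'
#' @slot params \linkS4class{MeltParams} estimate (NaN-filled if the fit did
#'   not converge).
#' @slot tm melting point, degrees C (soluble fraction 0.5).
#' @slot slope derivative of the fitted curve at \code{tm} (per degree C,
#'   <= 0 for a valid fit).
#' @slot r2 coefficient of determination on fold changes.
#' @slot converged logical, optimizer status.
#' @slot qcPass logical, stringency QC outcome (set by [passesQC()]).
#' @export
setClass("MeltFit",
         representation(params = "MeltParams", tm = "numeric",
                        slope = "numeric", r2 = "numeric",
                        converged = "logical", qcPass = "logical"),
         prototype(tm = NA_real_, slope = NA_real_, r2 = NA_real_,
                   converged = FALSE, qcPass = NA))

setValidity("MeltFit", function(object) {
  msg <- character()
  if (isTRUE(object@converged) && is.finite(object@tm)) {
    f <- meltEval(object@params, object@tm)
    if (abs(f - 0.5) > 1e-6)
      msg <- c(msg, "tm must satisfy meltEval(params, tm) == 0.5")
    if (is.finite(object@slope) && object@slope > 0)
      msg <- c(msg, "slope must be <= 0")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProteomeQuant", function(object) {
  cat(sprintf("ProteomeQuant: %d proteins x %d channels, condition '%s'\n",
              nrow(object), ncol(object), condition(object)))
  cat("temperatures (C):", paste(temperatures(object), collapse = " "), "\n")
})

setMethod("show", "MeltFit", function(object) {
  cat(sprintf(
    "MeltFit: Tm=%.3f C, slope=%.4f /C, plateau=%.3f, R2=%.4f, %s%s\n",
    object@tm, object@slope, object@params@plateau, object@r2,
    if (isTRUE(object@converged)) "converged" else "not converged",
    if (isTRUE(object@qcPass)) ", QC pass"
    else if (isFALSE(object@qcPass)) ", QC fail" else ""))
})
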