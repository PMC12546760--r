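#' Fraction of valid simulations in a library
#'
#' A simulation is valid when all 23 transformed electrophysiological
#' features are defined and finite. The complement of this fraction is the
#' "fail" rate reported for prior sampling.
#'
#' @param object a [SimulationLibrary-class].
#' @return Numeric scalar in `[0, 1]`.
#' @export
setGeneric("validFraction", function(object) standardGeneric("validFraction"))

#' @rdname validFraction
#' @export
setMethod("validFraction", "SimulationLibrary",
          function(object) mean(object@valid))

#' Number of simulations in a library
#' @param object a [SimulationLibrary-class].
#' @return Integer count.
#' @export
setGeneric("nSims", function(object) standardGeneric("nSims"))

#' @rdname nSims
#' @export
setMethod("nSims", "SimulationLibrary", function(object) nrow(object@params))

#' Parameter matrix of a library or cohort
#' @param object a [SimulationLibrary-class] or [SyntheticCohort-class].
#' @return n x 13 numeric matrix.
#' @export
setGeneric("parameterMatrix", function(object) standardGeneric("parameterMatrix"))

#' @rdname parameterMatrix
#' @export
setMethod("parameterMatrix", "SimulationLibrary", function(object) object@params)

#' @rdname parameterMatrix
#' @export
setMethod("parameterMatrix", "SyntheticCohort", function(object) object@theta)

#' Feature matrix of a library
#'
#' @param object a [SimulationLibrary-class].
#' @param type `"transformed"` (default), `"raw"`, or `"z"` for the
#'   standardized transformed features.
#' @return n x 23 numeric matrix.
#' @export
setGeneric("featureMatrix", function(object, type = "transformed")
  standardGeneric("featureMatrix"))

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "SimulationLibrary", function(object, type = "transformed") {
  type <- match.arg(type, c("transformed", "raw", "z"))
  switch(type,
         raw = object@rawFeatures,
         transformed = object@features,
         z = standardizeFeatures(object@features, object@standardizer))
})

#' Validity mask of a library
#' @param object a [SimulationLibrary-class].
#' @return Logical vector, `TRUE` for rows with all 23 features defined.
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname validMask
#' @export
setMethod("validMask", "SimulationLibrary", function(object) object@valid)

#' Feature standardizer of a library or posterior model
#' @param object a [SimulationLibrary-class] or [PosteriorModel-class].
#' @return A [FeatureStandardizer-class].
#' @export
setGeneric("standardizer", function(object) standardGeneric("standardizer"))

#' @rdname standardizer
#' @export
setMethod("standardizer", "SimulationLibrary", function(object) object@standardizer)

#' @rdname standardizer
#' @export
setMethod("standardizer", "PosteriorModel", function(object) object@standardizer)

#' Genes selected by a sparse reduced-rank regression model
#'
#' Genes whose encoder row has nonzero Euclidean norm.
#'
#' @param object a [SRRRModel-class].
#' @return Character vector of gene identifiers (or integer indices when the
#'   design matrix had no column names).
#' @export
setGeneric("selectedGenes", function(object) standardGeneric("selectedGenes"))

#' @rdname selectedGenes
#' @export
setMethod("selectedGenes", "SRRRModel", function(object) {
  nz <- rowSums(object@W^2) > 0
  if (!is.null(rownames(object@W))) rownames(object@W)[nz] else which(nz)
})

#' Membrane potential samples of a trace
#' @param object a [VoltageTrace-class].
#' @return Numeric vector (mV).
#' @export
setGeneric("voltage", function(object) standardGeneric("voltage"))

#' @rdname voltage
#' @export
setMethod("voltage", "VoltageTrace", function(object) object@vm)

#' Time grid of a trace
#' @param object a [VoltageTrace-class].
#' @return Numeric vector of sample times (ms).
#' @export
setGeneric("traceTime", function(object) standardGeneric("traceTime"))

#' @rdname traceTime
#' @export
setMethod("traceTime", "VoltageTrace",
          function(object) seq(0, by = object@dt, length.out = length(object@vm)))
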