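#' @rdname HaplotypePanel-accessors
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @rdname HaplotypePanel-accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname HaplotypePanel-accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname HaplotypePanel-accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname HaplotypePanel-accessors
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' @rdname HaplotypePanel-accessors
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' @rdname HaplotypePanel-accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname HaplotypePanel-accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname derivedFreq
#' @export
setGeneric("derivedFreq", function(x) standardGeneric("derivedFreq"))

#' @rdname genotypeMatrix
#' @export
setGeneric("genotypeMatrix", function(x) standardGeneric("genotypeMatrix"))

#' @rdname mafFilter
#' @export
setGeneric("mafFilter", function(x, maf = 0.05) standardGeneric("mafFilter"))

#' @rdname interpolateCM
#' @export
setGeneric("interpolateCM", function(map, bp) standardGeneric("interpolateCM"))

#' @rdname DemographyModel-accessors
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))

#' @rdname rescaleModel
#' @export
setGeneric("rescaleModel", function(model, q) standardGeneric("rescaleModel"))
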