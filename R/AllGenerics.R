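#' @rdname dosages
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname dosages
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname dosages
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname dosages
#' @export
setGeneric("chromosome", function(x) standardGeneric("chromosome"))

#' @rdname bandedAccessors
#' @export
setGeneric("neighborhood", function(x) standardGeneric("neighborhood"))

#' @rdname bandedAccessors
#' @export
setGeneric("bandWeights", function(x) standardGeneric("bandWeights"))

#' @rdname bandedAccessors
#' @export
setGeneric("bandBiases", function(x) standardGeneric("bandBiases"))

#' @rdname bandedAccessors
#' @export
setGeneric("denseWeights", function(x) standardGeneric("denseWeights"))

#' @rdname cvAccessors
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))

#' @rdname cvAccessors
#' @export
setGeneric("accuracies", function(x) standardGeneric("accuracies"))

#' @rdname heritability
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' @rdname fitAccessors
#' @export
setGeneric("lossTrace", function(x) standardGeneric("lossTrace"))

#' @rdname fitAccessors
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))
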