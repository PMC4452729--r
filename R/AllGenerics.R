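#' @rdname zScore
#' @export
setGeneric("zScore", function(x, ...) standardGeneric("zScore"))

#' @rdname zMatrix
#' @export
setGeneric("zMatrix", function(x, ...) standardGeneric("zMatrix"))

#' @rdname consistency
#' @export
setGeneric("consistency", function(x, items, ...) standardGeneric("consistency"))

#' @rdname selectItems
#' @export
setGeneric("selectItems", function(x, ...) standardGeneric("selectItems"))

#' @rdname compositeScore
#' @export
setGeneric("compositeScore", function(x, items, ...) standardGeneric("compositeScore"))

#' @rdname cohort-accessors
#' @export
setGeneric("measureCatalog", function(x) standardGeneric("measureCatalog"))

#' @rdname cohort-accessors
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' @rdname cohort-accessors
#' @export
setGeneric("prenatalGroup", function(x) standardGeneric("prenatalGroup"))

#' @rdname cohort-accessors
#' @export
setGeneric("rearingEnv", function(x) standardGeneric("rearingEnv"))

#' @rdname cohort-accessors
#' @export
setGeneric("perseveration", function(x) standardGeneric("perseveration"))

#' @rdname clusterLabels
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
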