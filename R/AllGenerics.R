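#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @export
setGeneric("binTable", function(x) standardGeneric("binTable"))

#' @export
setGeneric("nbins", function(x) standardGeneric("nbins"))

#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))

#' @export
setGeneric("balancingWeights", function(x) standardGeneric("balancingWeights"))

#' @export
setGeneric("oeMatrix", function(x) standardGeneric("oeMatrix"))

#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))

#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @export
setGeneric("stages", function(x) standardGeneric("stages"))

#' @export
setGeneric("tads", function(x) standardGeneric("tads"))

#' @export
setGeneric("loops", function(x) standardGeneric("loops"))

#' @export
setGeneric("elements", function(x) standardGeneric("elements"))

#' @export
setGeneric("compartmentLabels", function(x, ...) standardGeneric("compartmentLabels"))
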