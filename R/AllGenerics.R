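#' @rdname PirSet-accessors
#' @export
setGeneric("pirRanges", function(x) standardGeneric("pirRanges"))

#' @rdname PirSet-accessors
#' @export
setGeneric("pirGenes", function(x) standardGeneric("pirGenes"))

#' @rdname PirSet-accessors
#' @export
setGeneric("hasRna", function(x) standardGeneric("hasRna"))

#' @rdname PirSet-accessors
#' @export
setGeneric("hasTfbs", function(x, factor) standardGeneric("hasTfbs"))

#' @rdname PirSet-accessors
#' @export
setGeneric("tfbsFactors", function(x) standardGeneric("tfbsFactors"))

#' @rdname EnrichmentResult-accessors
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))

#' @rdname EnrichmentResult-accessors
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))

#' @rdname EnrichmentResult-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
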