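#' @rdname EmbeddedPopulation
#' @param x,object an `EmbeddedPopulation`.
#' @export
setGeneric("embeddingMatrix", function(x) standardGeneric("embeddingMatrix"))

#' @rdname EmbeddedPopulation
#' @export
setGeneric("partyLabels", function(x) standardGeneric("partyLabels"))

#' @rdname EmbeddedPopulation
#' @export
setGeneric("userIds", function(x) standardGeneric("userIds"))

#' @rdname EmbeddedPopulation
#' @export
setGeneric("nPerParty", function(x) standardGeneric("nPerParty"))

#' @rdname poliExact
#' @export
setGeneric("withinPartySum", function(pop, ...) standardGeneric("withinPartySum"))

#' @rdname poliExact
#' @export
setGeneric("distanceSummary", function(pop, ...) standardGeneric("distanceSummary"))

#' @rdname poliExact
#' @export
setGeneric("poliExact", function(pop, ...) standardGeneric("poliExact"))

#' @rdname poliApprox
#' @export
setGeneric("poliApprox", function(pop, config = approxConfig(), ...)
  standardGeneric("poliApprox"))

#' @rdname poliApprox
#' @export
setGeneric("subsamplePopulation", function(pop, fraction, ...)
  standardGeneric("subsamplePopulation"))

#' @rdname poliExact
#' @param x a result object.
#' @export
setGeneric("poliValue", function(x) standardGeneric("poliValue"))
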