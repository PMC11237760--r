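## Accessor generics.  Slot access stays behind these so the internal layout
## can change without breaking callers.

#' @name crisprCensus-accessors
#' @title Accessors for CrisprArray and RepeatTypeCall objects
#' @description Read-only accessors for the S4 containers.  Coordinates are
#'   0-based half-open on the forward strand.
#' @param x a [CrisprArray-class] or [RepeatTypeCall-class] object.
#' @return the corresponding slot value.
NULL

#' @rdname crisprCensus-accessors
#' @export
setGeneric("arrayId", function(x) standardGeneric("arrayId"))
#' @rdname crisprCensus-accessors
#' @export
setGeneric("contigId", function(x) standardGeneric("contigId"))
#' @rdname crisprCensus-accessors
#' @export
setGeneric("arrayStart", function(x) standardGeneric("arrayStart"))
#' @rdname crisprCensus-accessors
#' @export
setGeneric("arrayEnd", function(x) standardGeneric("arrayEnd"))
#' @rdname crisprCensus-accessors
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))
#' @rdname crisprCensus-accessors
#' @export
setGeneric("unitStarts", function(x) standardGeneric("unitStarts"))
#' @rdname crisprCensus-accessors
#' @export
setGeneric("unitEnds", function(x) standardGeneric("unitEnds"))
#' @rdname crisprCensus-accessors
#' @export
setGeneric("repeatSeqs", function(x) standardGeneric("repeatSeqs"))
#' @rdname crisprCensus-accessors
#' @export
setGeneric("spacerSeqs", function(x) standardGeneric("spacerSeqs"))
#' @rdname crisprCensus-accessors
#' @export
setGeneric("consensusRepeat", function(x) standardGeneric("consensusRepeat"))
#' @rdname crisprCensus-accessors
#' @export
setGeneric("conservation", function(x) standardGeneric("conservation"))
#' @rdname crisprCensus-accessors
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))
#' @rdname crisprCensus-accessors
#' @export
setGeneric("truncated", function(x) standardGeneric("truncated"))
#' @rdname crisprCensus-accessors
#' @export
setGeneric("typeLabel", function(x) standardGeneric("typeLabel"))

#' @rdname crisprCensus-accessors
setMethod("arrayId", "CrisprArray", function(x) x@arrayId)
#' @rdname crisprCensus-accessors
setMethod("contigId", "CrisprArray", function(x) x@contigId)
#' @rdname crisprCensus-accessors
setMethod("arrayStart", "CrisprArray", function(x) x@start)
#' @rdname crisprCensus-accessors
setMethod("arrayEnd", "CrisprArray", function(x) x@end)
#' @rdname crisprCensus-accessors
setMethod("nUnits", "CrisprArray", function(x) length(x@unitStarts))
#' @rdname crisprCensus-accessors
setMethod("unitStarts", "CrisprArray", function(x) x@unitStarts)
#' @rdname crisprCensus-accessors
setMethod("unitEnds", "CrisprArray", function(x) x@unitEnds)
#' @rdname crisprCensus-accessors
setMethod("repeatSeqs", "CrisprArray", function(x) x@repeatSeqs)
#' @rdname crisprCensus-accessors
setMethod("spacerSeqs", "CrisprArray", function(x) x@spacerSeqs)
#' @rdname crisprCensus-accessors
setMethod("consensusRepeat", "CrisprArray", function(x) x@consensusRepeat)
#' @rdname crisprCensus-accessors
setMethod("conservation", "CrisprArray", function(x) x@conservation)
#' @rdname crisprCensus-accessors
setMethod("orientation", "CrisprArray", function(x) x@orientation)
#' @rdname crisprCensus-accessors
setMethod("truncated", "CrisprArray", function(x) x@truncated)

#' @rdname crisprCensus-accessors
setMethod("typeLabel", "RepeatTypeCall", function(x) x@label)
#' @rdname crisprCensus-accessors
setMethod("consensusRepeat", "RepeatTypeCall", function(x) x@orientedConsensus)

#' @rdname crisprCensus-accessors
#' @export
setGeneric("truthArrays", function(x) standardGeneric("truthArrays"))
#' @rdname crisprCensus-accessors
#' @export
setGeneric("truthProtospacers", function(x) standardGeneric("truthProtospacers"))
#' @rdname crisprCensus-accessors
setMethod("truthArrays", "TruthTable", function(x) x@arrays)
#' @rdname crisprCensus-accessors
setMethod("truthProtospacers", "TruthTable", function(x) x@protospacers)
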