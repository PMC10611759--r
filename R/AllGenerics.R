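#' @rdname accessors
#' @export
setGeneric("peptide", function(x) standardGeneric("peptide"))

#' @rdname accessors
#' @export
setGeneric("timepoints", function(x) standardGeneric("timepoints"))

#' @rdname accessors
#' @export
setGeneric("percentD", function(x) standardGeneric("percentD"))

#' @rdname accessors
#' @export
setGeneric("residueIds", function(x) standardGeneric("residueIds"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("referenceCoords", function(x) standardGeneric("referenceCoords"))

#' @rdname accessors
#' @export
setGeneric("rates", function(x) standardGeneric("rates"))

#' @rdname accessors
#' @export
setGeneric("foldedFraction", function(x) standardGeneric("foldedFraction"))

#' @rdname accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname accessors
#' @export
setGeneric("correlationMatrix", function(x) standardGeneric("correlationMatrix"))
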