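#' @rdname oddsRatio
#' @export
setGeneric("oddsRatio", function(x, ...) standardGeneric("oddsRatio"))

#' @rdname fisherExactP
#' @export
setGeneric("fisherExactP", function(x, ...) standardGeneric("fisherExactP"))

#' @rdname confusionMetrics
#' @export
setGeneric("confusionMetrics", function(x, ...) standardGeneric("confusionMetrics"))

#' @rdname alertIds
#' @export
setGeneric("alertIds", function(x) standardGeneric("alertIds"))

#' @rdname alertIds
#' @export
setGeneric("alertSmarts", function(x) standardGeneric("alertSmarts"))

#' @rdname matchMatrix
#' @export
setGeneric("matchMatrix", function(x) standardGeneric("matchMatrix"))
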