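#' @rdname methCounts
#' @export
setGeneric("methCounts", function(x) standardGeneric("methCounts"))

#' @rdname methCounts
#' @export
setGeneric("unmethCounts", function(x) standardGeneric("unmethCounts"))

#' @rdname methCounts
#' @export
setGeneric("methCoverage", function(x) standardGeneric("methCoverage"))

#' @rdname methCounts
#' @export
setGeneric("methLevel", function(x) standardGeneric("methLevel"))

#' @rdname methCounts
#' @export
setGeneric("smoothedLevels", function(x) standardGeneric("smoothedLevels"))

#' @rdname methCounts
#' @export
setGeneric("mother", function(x) standardGeneric("mother"))

#' @rdname methCounts
#' @export
setGeneric("treatment", function(x) standardGeneric("treatment"))
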