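#' @rdname ComplexRecord-class
#' @param object,x a \code{ComplexRecord}
#' @export
setGeneric("entryId", function(x) standardGeneric("entryId"))

#' @rdname ComplexRecord-class
#' @export
setGeneric("resolution", function(x) standardGeneric("resolution"))

#' @rdname ComplexRecord-class
#' @export
setGeneric("chains", function(x) standardGeneric("chains"))

#' @rdname ComplexRecord-class
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Chain sequences of a structure
#'
#' @param x a \code{ComplexRecord}
#' @return named character vector of one-letter sequences, one element per
#'   chain instance, named by \code{\link{chainKey}}
#' @export
setGeneric("chainSequences", function(x) standardGeneric("chainSequences"))

#' @rdname InterfaceInstance-class
#' @param x an \code{InterfaceInstance}
#' @export
setGeneric("hostChain", function(x) standardGeneric("hostChain"))

#' @rdname InterfaceInstance-class
#' @export
setGeneric("partnerChain", function(x) standardGeneric("partnerChain"))

#' @rdname InterfaceInstance-class
#' @export
setGeneric("interfaceResidues", function(x) standardGeneric("interfaceResidues"))

#' @rdname InterfaceInstance-class
#' @export
setGeneric("siteId", function(x) standardGeneric("siteId"))

#' @rdname Fingerprint-class
#' @param x a \code{Fingerprint} (or \code{InterfaceGraph} for
#'   \code{interfaceGraph})
#' @export
setGeneric("patternGraph", function(x) standardGeneric("patternGraph"))

#' @rdname Fingerprint-class
#' @export
setGeneric("supportCount", function(x) standardGeneric("supportCount"))

#' @rdname Fingerprint-class
#' @export
setGeneric("canonicalCode", function(x) standardGeneric("canonicalCode"))

#' @rdname InterfaceGraph-class
#' @export
setGeneric("interfaceGraph", function(x) standardGeneric("interfaceGraph"))
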