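#' @rdname ComplexRecord-class
#' @export
setMethod("entryId", "ComplexRecord", function(x) x@entryId)

#' @rdname ComplexRecord-class
#' @export
setMethod("resolution", "ComplexRecord", function(x) x@resolution)

#' @rdname ComplexRecord-class
#' @export
setMethod("chains", "ComplexRecord", function(x) x@chains)

#' @rdname ComplexRecord-class
#' @export
setMethod("atoms", "ComplexRecord", function(x) x@atoms)

#' @rdname chainSequences
#' @export
setMethod("chainSequences", "ComplexRecord", function(x) {
  ch <- x@chains
  if (!nrow(ch)) return(setNames(character(), character()))
  setNames(ch$sequence, chainKey(x@entryId, ch$bio_unit, ch$chain_id))
})

setMethod("show", "ComplexRecord", function(object) {
  ch <- object@chains
  cat("ComplexRecord ", object@entryId, "\n",
      "  method: ", object@method,
      "  resolution: ", format(object@resolution), " A\n",
      "  ", nrow(ch), " chain instance(s) in ",
      length(unique(ch$bio_unit)), " biological unit(s); ",
      sum(!object@atoms$is_hydrogen), " heavy atoms\n", sep = "")
})

#' @rdname InterfaceInstance-class
#' @export
setMethod("hostChain", "InterfaceInstance", function(x) x@hostChain)

#' @rdname InterfaceInstance-class
#' @export
setMethod("partnerChain", "InterfaceInstance", function(x) x@partnerChain)

#' @rdname InterfaceInstance-class
#' @export
setMethod("interfaceResidues", "InterfaceInstance", function(x) x@residues)

#' @rdname InterfaceInstance-class
#' @export
setMethod("siteId", "InterfaceInstance", function(x) x@siteId)

setMethod("show", "InterfaceInstance", function(object) {
  cat("InterfaceInstance ", object@hostChain, " -> ", object@partnerChain,
      ": ", nrow(object@residues), " residues",
      if (!is.na(object@siteId)) paste0(", site ", object@siteId) else "",
      "\n", sep = "")
})

#' @rdname InterfaceGraph-class
#' @export
setMethod("interfaceGraph", "InterfaceGraph", function(x) x@graph)

#' @rdname InterfaceGraph-class
#' @export
setMethod("siteId", "InterfaceGraph", function(x) x@siteId)

setMethod("show", "InterfaceGraph", function(object) {
  g <- object@graph
  cat("InterfaceGraph ", object@graphId, " (site ", object@siteId, "): ",
      igraph::vcount(g), " residues, ", igraph::ecount(g), " contacts\n",
      sep = "")
})

#' @rdname Fingerprint-class
#' @export
setMethod("patternGraph", "Fingerprint", function(x) x@pattern)

#' @rdname Fingerprint-class
#' @export
setMethod("supportCount", "Fingerprint", function(x) x@support)

#' @rdname Fingerprint-class
#' @export
setMethod("canonicalCode", "Fingerprint", function(x) x@code)

#' @rdname Fingerprint-class
#' @export
setMethod("siteId", "Fingerprint", function(x) x@siteId)

setMethod("show", "Fingerprint", function(object) {
  p <- object@pattern
  cat("Fingerprint: ", igraph::vcount(p), " nodes [",
      paste(igraph::V(p)$aa, collapse = ""), "], ",
      igraph::ecount(p), " edges, support ", object@support, "\n", sep = "")
})

setMethod("show", "RelationReport", function(object) {
  cat("RelationReport: ", nrow(object@cooperative), " cooperative pair(s), ",
      nrow(object@distinctive), " distinctive fingerprint(s), ",
      nrow(object@isomorphism), " site pair(s) tested\n", sep = "")
})
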