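#' ComplexRecord: a parsed multi-chain structure
#'
#' Container for one crystal structure entry: heavy/hydrogen atom records,
#' per-chain metadata (biological-unit membership and whether the
#' biological-unit transformation applied to the chain is the identity),
#' experimental method and X-ray resolution.
#'
#' The \code{atoms} slot is a data.frame with columns \code{serial},
#' \code{name}, \code{element}, \code{chain_id}, \code{resno}, \code{icode},
#' \code{aa} (one-letter, non-standard residues mapped to \code{"X"}),
#' \code{x}, \code{y}, \code{z}, \code{is_hydrogen}. The \code{chains} slot
#' has one row per chain instance: \code{chain_id}, \code{bio_unit},
#' \code{transform_identity}, \code{length}, \code{sequence}.
#'
#' @slot entryId entry identifier
#' @slot method experimental method string (e.g. "X-RAY DIFFRACTION")
#' @slot resolution X-ray resolution in Angstrom
#' @slot atoms atom table (see Details)
#' @slot chains chain-instance table (see Details)
#' @export
setClass("ComplexRecord",
  representation(entryId = "character", method = "character",
                 resolution = "numeric", atoms = "data.frame",
                 chains = "data.frame"))

setValidity("ComplexRecord", function(object) {
  msg <- character()
  if (length(object@entryId) != 1L) msg <- c(msg, "entryId must be length 1")
  if (length(object@resolution) != 1L || is.na(object@resolution) ||
      object@resolution <= 0)
    msg <- c(msg, "resolution must be a positive scalar")
  need <- c("chain_id", "bio_unit", "transform_identity", "length", "sequence")
  if (!all(need %in% names(object@chains)))
    msg <- c(msg, "chains table misses required columns")
  if (nrow(object@chains) &&
      anyDuplicated(object@chains[, c("chain_id", "bio_unit")]))
    msg <- c(msg, "duplicate (chain_id, bio_unit) rows")
  if (length(msg)) msg else TRUE
})

#' InterfaceInstance: one chain's residues contacting one partner
#'
#' The host-side interface residue set of an ordered chain pair, carrying
#' provenance (entry, biological unit, resolution) and, once mapped through
#' the cluster multiple alignment, alignment-column coordinates.
#'
#' \code{residues} is a data.frame with columns \code{resno}, \code{icode},
#' \code{aa}, \code{seq_pos} (1-based index in the chain sequence) and
#' \code{msa_column} (NA until \code{\link{mapInterfaces}}).
#'
#' @slot hostChain,partnerChain chain instance keys (\code{\link{chainKey}})
#' @slot entryId entry identifier
#' @slot bioUnit biological unit
#' @slot resolution entry resolution (Angstrom)
#' @slot residues residue table (see Details)
#' @slot clusterId chain-cluster id (NA until clustered)
#' @slot siteId binding-site id (NA until site clustering)
#' @slot functionLabel optional function annotation
#' @export
setClass("InterfaceInstance",
  representation(hostChain = "character", partnerChain = "character",
                 entryId = "character", bioUnit = "integer",
                 resolution = "numeric", residues = "data.frame",
                 clusterId = "integer", siteId = "integer",
                 functionLabel = "character"),
  prototype(clusterId = NA_integer_, siteId = NA_integer_,
            functionLabel = NA_character_))

setValidity("InterfaceInstance", function(object) {
  if (nrow(object@residues) < 1L) return("interface residue set is empty")
  need <- c("resno", "icode", "aa", "seq_pos", "msa_column")
  if (!all(need %in% names(object@residues)))
    return("residues table misses required columns")
  TRUE
})

#' InterfaceGraph: residue contact graph of one interface
#'
#' Undirected graph whose nodes are interface residues (vertex attributes
#' \code{aa}, \code{msa_column}, \code{kd} = Kyte-Doolittle hydropathy,
#' \code{resno}) and whose edges are residue contacts witnessed by a
#' Delaunay heavy-atom edge not longer than the distance cutoff.
#'
#' @slot graphId identifier of this graph
#' @slot siteId binding-site id the interface belongs to
#' @slot proteinId identifier of the protein (representative chain)
#' @slot graph an \pkg{igraph} object
#' @export
setClass("InterfaceGraph",
  representation(graphId = "character", siteId = "integer",
                 proteinId = "character", graph = "ANY"))

setValidity("InterfaceGraph", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must be an igraph object")
  if (igraph::any_loop(g)) return("self-loops are not allowed")
  if (!("aa" %in% igraph::vertex_attr_names(g)))
    return("vertices must carry an 'aa' attribute")
  aa <- igraph::V(g)$aa
  if (!all(aa %in% AA20)) return("node labels outside 20-letter alphabet")
  TRUE
})

#' Fingerprint: a closed frequent labeled subgraph
#'
#' A connected residue-contact pattern occurring in at least the support
#' threshold number of database graphs, such that no one-edge or
#' one-node-plus-edge extension has the same support.
#'
#' @slot pattern connected labeled \pkg{igraph} (vertex attribute \code{aa})
#' @slot support number of database graphs containing the pattern
#' @slot occurrences graph ids of the containing graphs
#' @slot code canonical code string (label-isomorphism invariant)
#' @slot siteId binding site the pattern was mined from (NA if unknown)
#' @export
setClass("Fingerprint",
  representation(pattern = "ANY", support = "integer",
                 occurrences = "character", code = "character",
                 siteId = "integer"),
  prototype(siteId = NA_integer_))

setValidity("Fingerprint", function(object) {
  p <- object@pattern
  if (!igraph::is_igraph(p)) return("pattern must be an igraph object")
  if (igraph::vcount(p) > 1L && !igraph::is_connected(p))
    return("pattern must be connected")
  if (object@support != length(object@occurrences))
    return("support must equal the number of occurrence graphs")
  TRUE
})

#' RelationReport: fingerprint relations of one domain
#'
#' Bundles the relation statistics computed for a domain's binding sites:
#' cooperative fingerprint pairs, distinctive fingerprint sets, pairwise
#' isomorphism counts with their random-graph null p-values, and the
#' assortativity comparison.
#'
#' @slot cooperative data.frame of cooperative pairs
#' @slot distinctive data.frame indexing distinctive fingerprints per site
#' @slot isomorphism data.frame of site pairs, counts and p-values
#' @slot assortativity data.frame of per-fingerprint assortativity values
#' @slot meta list of seeds, replicate counts and dropped-value counts
#' @export
setClass("RelationReport",
  representation(cooperative = "data.frame", distinctive = "data.frame",
                 isomorphism = "data.frame", assortativity = "data.frame",
                 meta = "list"))
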