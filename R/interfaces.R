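## Interface residue detection and de-duplication within a chain cluster.

chainResidueTable <- function(complex, chain_id) {
  at <- complex@atoms
  sel <- at$chain_id == chain_id & !at$is_hydrogen
  rt <- unique(at[sel, c("resno", "icode", "aa"), drop = FALSE])
  rt <- rt[order(rt$resno, rt$icode), , drop = FALSE]
  rt$seq_pos <- seq_len(nrow(rt))
  rownames(rt) <- NULL
  rt
}

#' Detect interface residues
#'
#' For every ordered pair of distinct chains within the same biological
#' unit, collects the host-side residues having at least one heavy atom
#' within \code{cutoff} of any heavy atom of the partner chain. Chain pairs
#' in different biological units are never considered, even if their
#' deposited coordinates are close (crystal packing). Empty interfaces are
#' dropped.
#'
#' @param complex a filtered \code{\linkS4class{ComplexRecord}}
#' @param cutoff heavy-atom contact distance in Angstrom (default 5.0,
#'   inclusive)
#' @return list of \code{\linkS4class{InterfaceInstance}}
#' @export
detectInterfaces <- function(complex, cutoff = 5.0) {
  at <- complex@atoms
  heavy <- at[!at$is_hydrogen, , drop = FALSE]
  ch <- complex@chains
  cut2 <- cutoff^2
  out <- list()
  for (u in unique(ch$bio_unit)) {
    cids <- ch$chain_id[ch$bio_unit == u]
    if (length(cids) < 2L) next
    dat <- lapply(cids, function(cid) {
      a <- heavy[heavy$chain_id == cid, , drop = FALSE]
      rt <- chainResidueTable(complex, cid)
      ridx <- match(resId(cid, a$resno, a$icode),
                    resId(cid, rt$resno, rt$icode))
      list(coords = as.matrix(a[, c("x", "y", "z")]), ridx = ridx, rt = rt)
    })
    names(dat) <- cids
    for (i in seq_along(cids)) for (j in seq_along(cids)) {
      if (i == j) next
      A <- dat[[i]]; B <- dat[[j]]
      d2 <- outer(rowSums(A$coords^2), rowSums(B$coords^2), "+") -
        2 * tcrossprod(A$coords, B$coords)
      hit <- tapply(apply(d2, 1, min), A$ridx, min) <= cut2
      pos <- as.integer(names(hit))[hit]
      if (!length(pos)) next
      r <- A$rt[A$rt$seq_pos %in% pos, , drop = FALSE]
      r$msa_column <- NA_integer_
      out[[length(out) + 1L]] <- new("InterfaceInstance",
        hostChain = chainKey(complex@entryId, u, cids[i]),
        partnerChain = chainKey(complex@entryId, u, cids[j]),
        entryId = complex@entryId, bioUnit = as.integer(u),
        resolution = complex@resolution, residues = r)
    }
  }
  out
}

ifaceResidueKeys <- function(i) {
  r <- i@residues
  if (anyNA(r$msa_column))
    stop("interface not mapped to MSA columns; run mapInterfaces() first")
  paste(r$msa_column, r$aa, sep = ":")
}

#' Interface similarity
#'
#' Number of identical aligned interface residues (same amino-acid type
#' and same alignment column) divided by the cardinality of the smaller of
#' the two residue sets.
#'
#' @param i1,i2 MSA-mapped \code{\linkS4class{InterfaceInstance}} objects
#'   from the same cluster
#' @return similarity in [0, 1]
#' @export
interfaceSimilarity <- function(i1, i2) {
  k1 <- ifaceResidueKeys(i1); k2 <- ifaceResidueKeys(i2)
  if (!length(k1) || !length(k2)) stop("empty interface")
  length(intersect(k1, k2)) / min(length(k1), length(k2))
}

#' Jaccard overlap of two interfaces
#'
#' Intersection over union of the (alignment column, amino acid) residue
#' sets; used to quantify how much two binding sites share residues.
#'
#' @param i1,i2 MSA-mapped \code{\linkS4class{InterfaceInstance}} objects
#' @return Jaccard index in [0, 1]
#' @export
jaccardOverlap <- function(i1, i2) {
  k1 <- ifaceResidueKeys(i1); k2 <- ifaceResidueKeys(i2)
  length(intersect(k1, k2)) / length(union(k1, k2))
}

singleLinkage <- function(n, similar) {
  ## similar: function(i, j) -> logical; returns component id per element,
  ## numbered by first appearance
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (n > 1L) {
    pairs <- utils::combn(n, 2L)
    keep <- apply(pairs, 2L, function(p) similar(p[1], p[2]))
    g <- igraph::add_edges(g, pairs[, keep, drop = FALSE])
  }
  comp <- igraph::components(g)$membership
  match(comp, unique(comp))
}

#' De-duplicate similar interfaces of one cluster
#'
#' Builds a graph whose nodes are interfaces and whose edges join pairs
#' with \code{\link{interfaceSimilarity}} at or above \code{threshold};
#' each connected component is reduced to one representative, the member
#' from the entry with the best (lowest) X-ray resolution, ties broken by
#' input order. All representatives are then remapped onto the single
#' best-resolution chain of the cluster via the alignment columns, so that
#' every surviving interface lives on one physical chain.
#'
#' @param interfaces MSA-mapped interfaces of one chain cluster
#' @param msa the cluster's \code{MsaMap}
#' @param threshold similarity threshold (default 0.8, inclusive)
#' @param complexes optional named list of \code{ComplexRecord}s (by entry
#'   id) used to re-derive residue numbering on the target chain; without
#'   it representatives keep their original host coordinates
#' @return list of representative \code{InterfaceInstance}s
#' @export
dedupInterfaces <- function(interfaces, msa, threshold = 0.8,
                            complexes = NULL) {
  if (!length(interfaces)) return(list())
  n <- length(interfaces)
  comp <- singleLinkage(n, function(i, j)
    interfaceSimilarity(interfaces[[i]], interfaces[[j]]) >= threshold)
  reps <- lapply(unique(comp), function(cl) {
    memb <- which(comp == cl)
    res <- vapply(interfaces[memb], function(x) x@resolution, 0)
    interfaces[[memb[which.min(res)]]]   # which.min: first of ties
  })
  ## remap every representative onto the cluster's best-resolution chain
  host_res <- vapply(interfaces, function(x) x@resolution, 0)
  target <- interfaces[[which.min(host_res)]]@hostChain
  if (!is.null(complexes)) {
    reps <- lapply(reps, remapInterface, target = target, msa = msa,
                   complexes = complexes)
    reps <- reps[!vapply(reps, is.null, TRUE)]
  }
  reps
}

remapInterface <- function(iface, target, msa, complexes) {
  if (iface@hostChain == target) return(iface)
  cm <- msa$columns[[target]]
  if (is.null(cm)) stop("target chain not in MSA: ", target)
  tk <- splitChainKey(target)
  cx <- complexes[[tk$entry_id]]
  if (is.null(cx)) stop("complex not supplied for entry ", tk$entry_id)
  rt <- chainResidueTable(cx, tk$chain_id)
  pos <- match(iface@residues$msa_column, cm)
  keep <- !is.na(pos)
  if (!any(keep)) return(NULL)
  r <- rt[pos[keep], , drop = FALSE]
  r$msa_column <- cm[r$seq_pos]
  rownames(r) <- NULL
  new("InterfaceInstance", hostChain = target,
      partnerChain = iface@partnerChain, entryId = tk$entry_id,
      bioUnit = tk$bio_unit, resolution = cx@resolution, residues = r,
      clusterId = iface@clusterId, siteId = iface@siteId,
      functionLabel = iface@functionLabel)
}

#' Group representative interfaces into binding sites
#'
#' Single-linkage clustering of a cluster's representative interfaces by
#' \code{\link{interfaceSimilarity}} at or above \code{siteThreshold};
#' each connected component is one binding site. Sequence-position
#' similarity stands in for spatial similarity here because all
#' representatives live on near-identical chains.
#'
#' @param reps de-duplicated interfaces (one cluster)
#' @param siteThreshold similarity threshold (default 0.5)
#' @return the interfaces with \code{siteId} assigned (1, 2, ... in input
#'   order of first occurrence)
#' @export
clusterBindingSites <- function(reps, siteThreshold = 0.5) {
  if (!length(reps)) return(list())
  comp <- singleLinkage(length(reps), function(i, j)
    interfaceSimilarity(reps[[i]], reps[[j]]) >= siteThreshold)
  lapply(seq_along(reps), function(k) {
    x <- reps[[k]]; x@siteId <- as.integer(comp[k]); x
  })
}
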