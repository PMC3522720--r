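## Residue contact graphs: Delaunay tessellation intersected with a
## distance cutoff, upgraded from atoms to residues.

#' Delaunay edges of a heavy-atom point set
#'
#' Edges of the 3D Delaunay tessellation of the given coordinates. A tiny
#' deterministic jitter (default 1e-9 Angstrom) breaks cospherical ties.
#' Degenerate inputs where the tessellation is undefined -- fewer than four
#' points, or a collinear/coplanar configuration -- fall back to the
#' complete graph, leaving the physical distance cutoff applied downstream
#' as the only contact criterion.
#'
#' @param coords n x 3 coordinate matrix
#' @param jitter tie-breaking jitter amplitude in Angstrom
#' @return m x 2 integer matrix of edges (1-based, first column smaller)
#' @export
delaunayAtomEdges <- function(coords, jitter = 1e-9) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) return(matrix(integer(), 0L, 2L))
  degenerate <- n < 4L
  if (!degenerate) {
    sv <- svd(scale(coords, scale = FALSE))$d
    if (sv[3] < 1e-8 * max(sv[1], 1)) degenerate <- TRUE
  }
  if (degenerate) {
    e <- t(utils::combn(n, 2L))
    storage.mode(e) <- "integer"
    return(e)
  }
  .delaunay_edges_cpp(coords, jitter)
}

#' Build the residue contact graph of an interface
#'
#' Tessellates the heavy atoms of the host chain's surface residues,
#' keeps Delaunay edges no longer than \code{cutoff}, and upgrades the atom
#' graph to residues: atom contacts within one residue are ignored and all
#' surviving atom contacts between two residues merge into a single edge.
#' Nodes are the interface's residues (non-standard residues, mapped to X,
#' are excluded so node labels stay in the 20-letter alphabet), each
#' carrying its amino acid, alignment column and Kyte-Doolittle hydropathy.
#'
#' @param iface an \code{\linkS4class{InterfaceInstance}}
#' @param complex the \code{\linkS4class{ComplexRecord}} holding the host
#'   chain (entry must match)
#' @param cutoff contact distance in Angstrom (default 5.0, inclusive)
#' @param surface surface-residue criterion passed to
#'   \code{\link{surfaceResidues}}: \code{"rsa"} (relative accessibility
#'   >= \code{rsaMin}) or \code{"all"}
#' @param rsaMin relative accessibility threshold
#' @param graphId identifier; defaults to host->partner
#' @return an \code{\linkS4class{InterfaceGraph}}
#' @export
buildInterfaceGraph <- function(iface, complex, cutoff = 5.0,
                                surface = c("rsa", "all"), rsaMin = 0.05,
                                graphId = NULL) {
  surface <- match.arg(surface)
  hk <- splitChainKey(iface@hostChain)
  if (hk$entry_id != complex@entryId)
    stop("complex entry does not match interface host chain")
  surf <- surfaceResidues(complex, hk$chain_id, rsaMin = rsaMin,
                          mode = surface)
  ir <- iface@residues
  keys_surf <- union(resId(hk$chain_id, surf$resno, surf$icode),
                     resId(hk$chain_id, ir$resno, ir$icode))
  at <- complex@atoms
  sel <- at$chain_id == hk$chain_id & !at$is_hydrogen &
    resId(hk$chain_id, at$resno, at$icode) %in% keys_surf
  a <- at[sel, , drop = FALSE]
  if (!nrow(a)) stop("no resolvable residues for interface host chain")
  coords <- as.matrix(a[, c("x", "y", "z")])
  edges <- delaunayAtomEdges(coords)
  if (nrow(edges)) {
    len2 <- rowSums((coords[edges[, 1], , drop = FALSE] -
                     coords[edges[, 2], , drop = FALSE])^2)
    edges <- edges[len2 <= cutoff^2, , drop = FALSE]
  }
  akey <- resId(hk$chain_id, a$resno, a$icode)
  nodes <- ir[ir$aa %in% AA20, , drop = FALSE]
  if (!nrow(nodes)) stop("no resolvable residues for interface host chain")
  nkey <- resId(hk$chain_id, nodes$resno, nodes$icode)
  ridx <- match(akey, nkey)                 # NA for non-interface residues
  re <- cbind(ridx[edges[, 1]], ridx[edges[, 2]])
  re <- re[!is.na(re[, 1]) & !is.na(re[, 2]) & re[, 1] != re[, 2], ,
           drop = FALSE]
  if (nrow(re)) {
    re <- cbind(pmin(re[, 1], re[, 2]), pmax(re[, 1], re[, 2]))
    re <- unique(re)
  }
  g <- igraph::make_empty_graph(nrow(nodes), directed = FALSE)
  g <- igraph::add_edges(g, t(re))
  igraph::V(g)$aa <- nodes$aa
  igraph::V(g)$msa_column <- nodes$msa_column
  igraph::V(g)$kd <- unname(KD_HYDRO[nodes$aa])
  igraph::V(g)$resno <- nodes$resno
  igraph::V(g)$icode <- nodes$icode
  if (is.null(graphId))
    graphId <- paste(iface@hostChain, iface@partnerChain, sep = "~")
  new("InterfaceGraph", graphId = graphId,
      siteId = if (is.na(iface@siteId)) NA_integer_ else iface@siteId,
      proteinId = iface@hostChain, graph = g)
}

#' Write interface graphs
#'
#' Writes each graph either as GraphML (vertex attributes kept) or as a
#' plain edge-list text file: a \code{#graph id site protein} header, one
#' \code{node <id> <aa>} line per residue and one \code{edge <i> <j>} line
#' per contact.
#'
#' @param graphs list of \code{\linkS4class{InterfaceGraph}}
#' @param dir output directory (created if missing)
#' @param format \code{"edgelist"} or \code{"graphml"}
#' @return paths written, invisibly
#' @export
writeInterfaceGraphs <- function(graphs, dir,
                                 format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(graphs), function(k) {
    ig <- graphs[[k]]
    fn <- file.path(dir, paste0(sprintf("graph%03d", k),
                                if (format == "graphml") ".graphml" else ".txt"))
    if (format == "graphml") {
      igraph::write_graph(ig@graph, fn, format = "graphml")
    } else {
      g <- ig@graph
      el <- igraph::as_edgelist(g, names = FALSE)
      writeLines(c(paste("#graph", ig@graphId, ig@siteId, ig@proteinId),
                   paste("node", seq_len(igraph::vcount(g)),
                         igraph::V(g)$aa),
                   if (nrow(el)) paste("edge", el[, 1], el[, 2])), fn)
    }
    fn
  }, "")
  invisible(paths)
}

#' Read an edge-list interface graph
#'
#' @param path file written by \code{\link{writeInterfaceGraphs}}
#' @return an \code{\linkS4class{InterfaceGraph}}
#' @export
readInterfaceGraph <- function(path) {
  ln <- readLines(path)
  hdr <- strsplit(ln[1], "\\s+")[[1]]
  nl <- ln[startsWith(ln, "node ")]
  el <- ln[startsWith(ln, "edge ")]
  aa <- vapply(strsplit(nl, "\\s+"), `[`, "", 3L)
  g <- igraph::make_empty_graph(length(aa), directed = FALSE)
  if (length(el)) {
    em <- t(vapply(strsplit(el, "\\s+"),
                   function(x) as.integer(x[2:3]), integer(2)))
    g <- igraph::add_edges(g, t(em))
  }
  igraph::V(g)$aa <- aa
  igraph::V(g)$kd <- unname(KD_HYDRO[aa])
  new("InterfaceGraph", graphId = hdr[2], siteId = as.integer(hdr[3]),
      proteinId = hdr[4], graph = g)
}
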