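## Relations between the binding sites of one domain: transactional
## encoding, cooperative pairs, distinctive sets, function association.

#' Transactional encoding of fingerprint occurrences
#'
#' One transaction per fingerprint; the items are the interfaces (graph
#' ids, across every site of the domain) in which the fingerprint occurs
#' by subgraph monomorphism.
#'
#' @param fps list of \code{\linkS4class{Fingerprint}}
#' @param graphs list of \code{\linkS4class{InterfaceGraph}} covering all
#'   sites of the domain
#' @return list with \code{transactions} (named list of graph-id vectors)
#' @export
buildTransactions <- function(fps, graphs) {
  gids <- vapply(graphs, function(g) g@graphId, "")
  tr <- lapply(fps, function(f)
    gids[vapply(graphs, function(g) subgraphOccurs(f, g), TRUE)])
  names(tr) <- vapply(seq_along(fps), function(i)
    paste0("fp", i, "_s", fps[[i]]@siteId), "")
  list(transactions = tr)
}

#' Cooperative fingerprint pairs across binding sites
#'
#' A pair (fingerprint of site i, fingerprint of site j != i) is
#' cooperative when both occur in the same proteins' respective site
#' graphs. The co-occurrence fraction is computed over the proteins that
#' possess both sites; pairs at or above \code{minCoFraction} are
#' reported.
#'
#' @param fpsBySite named list: site id -> list of
#'   \code{\linkS4class{Fingerprint}}
#' @param graphs list of \code{\linkS4class{InterfaceGraph}} (their
#'   \code{proteinId} and \code{siteId} slots define the protein/site
#'   structure)
#' @param minCoFraction reporting threshold (default 0.20)
#' @return data.frame of pairs: sites, fingerprint indices, co-support,
#'   co-fraction, number of proteins with both sites
#' @export
cooperativePairs <- function(fpsBySite, graphs, minCoFraction = 0.20) {
  site_of <- vapply(graphs, function(g) g@siteId, 0L)
  prot_of <- vapply(graphs, function(g) g@proteinId, "")
  sites <- as.integer(names(fpsBySite))
  occurs_in <- function(fp, idx) any(vapply(idx, function(i)
    subgraphOccurs(fp, graphs[[i]]), TRUE))
  out <- list()
  for (a in seq_along(sites)) for (b in seq_along(sites)) {
    if (a >= b) next
    si <- sites[a]; sj <- sites[b]
    prots <- intersect(unique(prot_of[site_of == si]),
                       unique(prot_of[site_of == sj]))
    if (!length(prots)) next
    for (ia in seq_along(fpsBySite[[a]])) for (ib in seq_along(fpsBySite[[b]])) {
      fa <- fpsBySite[[a]][[ia]]; fb <- fpsBySite[[b]][[ib]]
      co <- sum(vapply(prots, function(p) {
        occurs_in(fa, which(prot_of == p & site_of == si)) &&
          occurs_in(fb, which(prot_of == p & site_of == sj))
      }, TRUE))
      frac <- co / length(prots)
      if (co > 0L && frac >= minCoFraction)
        out[[length(out) + 1L]] <- data.frame(
          site_a = si, site_b = sj, fp_a = ia, fp_b = ib,
          co_support = co, co_fraction = frac,
          n_proteins_both = length(prots))
    }
  }
  if (!length(out)) {
    warning("no cooperative pairs (no protein carries two sites, or none co-occur)")
    return(data.frame(site_a = integer(), site_b = integer(),
                      fp_a = integer(), fp_b = integer(),
                      co_support = integer(), co_fraction = numeric(),
                      n_proteins_both = integer()))
  }
  do.call(rbind, out)
}

#' Distinctive fingerprints of one binding site
#'
#' Fingerprints mined from \code{site} that have no label-isomorphic
#' counterpart among any other site's fingerprints and that never occur
#' (as a subgraph) in any other site's interface graphs.
#'
#' @param site site id
#' @param fpsBySite named list: site id -> fingerprints
#' @param graphs all sites' \code{\linkS4class{InterfaceGraph}}s
#' @return list of distinctive \code{\linkS4class{Fingerprint}}
#' @export
distinctiveFingerprints <- function(site, fpsBySite, graphs) {
  key <- as.character(site)
  stopifnot(key %in% names(fpsBySite))
  own <- fpsBySite[[key]]
  other_fps <- unlist(fpsBySite[setdiff(names(fpsBySite), key)],
                      recursive = FALSE)
  other_codes <- vapply(other_fps, function(f) f@code, "")
  other_graphs <- Filter(function(g) g@siteId != site, graphs)
  Filter(function(f) {
    if (f@code %in% other_codes) return(FALSE)
    !any(vapply(other_graphs, function(g) subgraphOccurs(f, g), TRUE))
  }, own)
}

#' Associate fingerprints with interface functions
#'
#' Function labels are consumed from an input site-annotation table, not
#' inferred. Per function label the table reports how many fingerprints
#' its sites carry, how many are distinctive (site-specific within the
#' domain) and how many are shared, i.e. label-isomorphic to a fingerprint
#' of a site annotated with a different function. Sites without a label
#' are pooled under "unannotated".
#'
#' @param fpsBySite named list: site id -> fingerprints
#' @param siteLabels named character vector: site id -> function label
#' @param graphs all sites' interface graphs (for the distinctive test)
#' @return data.frame per function label
#' @export
functionAssociation <- function(fpsBySite, siteLabels, graphs) {
  lab_of <- function(s) {
    l <- siteLabels[as.character(s)]
    if (is.na(l) || !nzchar(l)) "unannotated" else unname(l)
  }
  sites <- names(fpsBySite)
  site_lab <- vapply(sites, lab_of, "")
  dist_by_site <- lapply(sites, function(s)
    distinctiveFingerprints(as.integer(s), fpsBySite, graphs))
  names(dist_by_site) <- sites
  rows <- lapply(unique(site_lab), function(fn) {
    own_sites <- sites[site_lab == fn]
    other_sites <- sites[site_lab != fn]
    own <- unlist(fpsBySite[own_sites], recursive = FALSE)
    other_codes <- vapply(unlist(fpsBySite[other_sites], recursive = FALSE),
                          function(f) f@code, "")
    shared <- sum(vapply(own, function(f) f@code %in% other_codes, TRUE))
    data.frame(fn_label = fn, n_sites = length(own_sites),
               n_fingerprints = length(own),
               n_distinctive = sum(lengths(dist_by_site[own_sites])),
               n_shared = shared, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
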