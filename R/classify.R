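## Interaction typing, the multi-interface preference statistic, domain
## assignment and cohort-level aggregation tables.

#' Classify an interaction
#'
#' An interaction is \emph{homo} when host and partner chain fall into the
#' same sequence cluster and \emph{hetero} otherwise; whether it is an
#' \emph{oligomer} (obligate/permanent) or a \emph{complex} (transient) is
#' read from a supplied per-interaction permanence table rather than
#' predicted. Interactions without a permanence flag are labeled
#' \code{"unknown"} and excluded from preference counts.
#'
#' @param iface an \code{\linkS4class{InterfaceInstance}}
#' @param clusters data.frame \code{cluster_id}, \code{chain} from
#'   \code{\link{buildChainClusters}}
#' @param permanence data.frame with columns \code{chain_a},
#'   \code{chain_b}, \code{permanence} ("permanent" or "transient"),
#'   unordered pairs of chain keys
#' @return one of "homo-oligomer", "homo-complex", "hetero-oligomer",
#'   "hetero-complex", "unknown"
#' @export
classifyInteraction <- function(iface, clusters, permanence) {
  cl <- function(chain) clusters$cluster_id[match(chain, clusters$chain)]
  ca <- cl(iface@hostChain); cb <- cl(iface@partnerChain)
  if (is.na(ca) || is.na(cb)) stop("host or partner chain not clustered")
  homo <- ca == cb
  key <- paste(pmin(permanence$chain_a, permanence$chain_b),
               pmax(permanence$chain_a, permanence$chain_b))
  want <- paste(min(iface@hostChain, iface@partnerChain),
                max(iface@hostChain, iface@partnerChain))
  flag <- permanence$permanence[match(want, key)]
  if (is.na(flag)) return("unknown")
  paste0(if (homo) "homo" else "hetero",
         if (flag == "permanent") "-oligomer" else "-complex")
}

#' Multi-interface preference by interaction type
#'
#' For each interaction type t with n_all total interactions and n_multi
#' interactions involving multi-interface proteins, the preference is
#' (n_multi_t / n_all_t) / (sum n_multi / sum n_all): the enrichment of the
#' type among multi-interface interactions over its background share.
#' Values are reported rounded to two decimals.
#'
#' @param counts data.frame with columns \code{type}, \code{n_all},
#'   \code{n_multi}
#' @return \code{counts} with a \code{preference} column appended
#' @examples
#' computePreference(data.frame(
#'   type = c("homo-oligomer", "homo-complex", "hetero-oligomer",
#'            "hetero-complex"),
#'   n_all = c(647, 13, 38, 6695), n_multi = c(127, 3, 4, 890)))
#' @export
computePreference <- function(counts) {
  stopifnot(all(c("type", "n_all", "n_multi") %in% names(counts)))
  if (any(counts$n_all <= 0)) stop("every type needs n_all > 0")
  tot <- sum(counts$n_multi) / sum(counts$n_all)
  if (tot <= 0) stop("no multi-interface interactions")
  counts$preference <- round((counts$n_multi / counts$n_all) / tot, 2)
  counts
}

#' Assign an interface to annotated domains
#'
#' Looks up which annotated residue ranges (on the representative chain's
#' author numbering) the interface residues fall into. A single domain id
#' is returned when the whole interface fits one range; otherwise all
#' overlapped domain ids are returned (a cross-domain interface when two or
#' more). Residues covered by no range contribute an \code{"unassigned"}
#' tag.
#'
#' @param iface an \code{\linkS4class{InterfaceInstance}} on the
#'   representative chain
#' @param domains data.frame with columns \code{domain_id}, \code{start},
#'   \code{end} (inclusive author residue numbers); SCOP level columns are
#'   carried along if present
#' @return character vector of domain ids (plus "unassigned" if needed)
#' @export
assignDomains <- function(iface, domains) {
  stopifnot(all(c("domain_id", "start", "end") %in% names(domains)),
            all(domains$start <= domains$end))
  pos <- iface@residues$resno
  hits <- lapply(pos, function(p)
    domains$domain_id[domains$start <= p & p <= domains$end])
  out <- unique(unlist(hits))
  if (any(!lengths(hits))) out <- c(out, "unassigned")
  if (!length(out)) "unassigned" else out
}

#' Aggregate multi-interface statistics
#'
#' Produces the cohort-level distribution tables: the histogram of binding
#' sites per protein over proteins with two or more sites; per-level counts
#' of annotation labels and of labels/chains with the multi-interface
#' property; and, when cross-domain interface assignments are supplied, the
#' counts of unordered class pairs they bridge.
#'
#' @param proteins data.frame with \code{protein_id}, \code{n_sites} and
#'   optional annotation columns (e.g. \code{class}, \code{fold},
#'   \code{superfamily}, \code{family}, \code{domain})
#' @param levels annotation columns of \code{proteins} to tabulate
#' @param crossDomain optional data.frame \code{interface_id},
#'   \code{class_a}, \code{class_b}
#' @return list with \code{histogram}, \code{perLevel}, \code{crossDomain}
#' @export
aggregateCounts <- function(proteins,
                            levels = intersect(c("class", "fold",
                                                 "superfamily", "family",
                                                 "domain"), names(proteins)),
                            crossDomain = NULL) {
  stopifnot(all(c("protein_id", "n_sites") %in% names(proteins)))
  multi <- proteins[proteins$n_sites >= 2L, , drop = FALSE]
  tab <- table(multi$n_sites)
  histogram <- data.frame(n_interfaces = as.integer(names(tab)),
                          n_proteins = as.integer(tab))
  perLevel <- do.call(rbind, lapply(levels, function(lv) {
    lab <- proteins[[lv]]
    ok <- !is.na(lab)
    data.frame(level = lv,
               n_labels = length(unique(lab[ok])),
               n_labels_multi = length(unique(lab[ok & proteins$n_sites >= 2L])),
               n_multi_chains = sum(ok & proteins$n_sites >= 2L),
               stringsAsFactors = FALSE)
  }))
  cross <- NULL
  if (!is.null(crossDomain) && nrow(crossDomain)) {
    key <- paste(pmin(crossDomain$class_a, crossDomain$class_b),
                 pmax(crossDomain$class_a, crossDomain$class_b), sep = "~")
    tt <- table(key)
    parts <- strsplit(names(tt), "~", fixed = TRUE)
    cross <- data.frame(class_a = vapply(parts, `[`, "", 1L),
                        class_b = vapply(parts, `[`, "", 2L),
                        n = as.integer(tt), stringsAsFactors = FALSE)
  }
  list(histogram = histogram, perLevel = perLevel, crossDomain = cross)
}

#' Cohort summary shares
#'
#' Small arithmetic summaries of a multi-interface cohort: the percentage
#' of annotated domains having the multi-interface property, the share of
#' multi-interface proteins falling into a chosen set of structure classes,
#' and the average number of interfaces per multi-interface protein.
#'
#' @param nMultiDomains,nDomains multi-interface and total domain counts
#' @param classCounts per-class multi-interface protein counts for the
#'   classes of interest
#' @param nProteins total number of (annotated) multi-interface proteins
#' @param nInterfaces total interface count over \code{nProteinsAll}
#' @param nProteinsAll number of multi-interface proteins the interfaces
#'   belong to
#' @return list with \code{domain_fraction_pct}, \code{class_share_pct},
#'   \code{mean_interfaces} (and its rounded value)
#' @export
cohortShares <- function(nMultiDomains, nDomains, classCounts, nProteins,
                         nInterfaces, nProteinsAll) {
  list(domain_fraction_pct = round(100 * nMultiDomains / nDomains, 1),
       class_share_pct = round(100 * sum(classCounts) / nProteins, 1),
       mean_interfaces = nInterfaces / nProteinsAll,
       mean_interfaces_rounded = round(nInterfaces / nProteinsAll))
}
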