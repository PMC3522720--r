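## Domain-specificity statistics: per-fingerprint assortativity, Welch
## t-tests between domains, and the subsampled isomorphism disparity test.

asIgraphLabeled <- function(g) {
  if (is(g, "Fingerprint")) g <- g@pattern
  if (is(g, "InterfaceGraph")) g <- g@graph
  stopifnot(igraph::is_igraph(g))
  g
}

#' Degree assortativity of a labeled graph
#'
#' Pearson correlation of end-point degrees over the symmetrised edge
#' list. Undefined (NA) when either marginal variance is zero, e.g. for
#' any regular graph; any star is -1.
#'
#' @param g labeled graph (igraph, \code{Fingerprint} or
#'   \code{InterfaceGraph})
#' @return numeric in [-1, 1], or NA when undefined
#' @export
degreeAssortativity <- function(g) {
  g <- asIgraphLabeled(g)
  if (igraph::ecount(g) < 1L) stop("assortativity needs at least one edge")
  r <- suppressWarnings(igraph::assortativity_degree(g, directed = FALSE))
  if (is.nan(r)) NA_real_ else r
}

#' Label (residue-type) assortativity
#'
#' Newman's categorical mixing assortativity over the amino-acid labels:
#' r = (sum_i e_ii - sum_i a_i b_i) / (1 - sum_i a_i b_i) on the edge
#' mixing matrix. Undefined (NA) when all nodes share one label.
#'
#' @param g labeled graph with vertex attribute \code{aa}
#' @return numeric in [-1, 1], or NA when undefined
#' @export
labelAssortativity <- function(g) {
  g <- asIgraphLabeled(g)
  if (igraph::ecount(g) < 1L) stop("assortativity needs at least one edge")
  types <- as.integer(factor(igraph::V(g)$aa))
  if (length(unique(types)) < 2L) return(NA_real_)
  r <- suppressWarnings(igraph::assortativity_nominal(g, types = types,
                                                      directed = FALSE))
  if (is.nan(r)) NA_real_ else r
}

#' Assortativity table of a fingerprint set
#'
#' @param fps list of fingerprints (patterns with >= 1 edge contribute;
#'   edgeless patterns yield NA rows)
#' @return data.frame \code{fingerprint}, \code{degree_assortativity},
#'   \code{label_assortativity}
#' @export
assortativityTable <- function(fps) {
  rows <- lapply(seq_along(fps), function(i) {
    g <- asIgraphLabeled(fps[[i]])
    has_e <- igraph::ecount(g) >= 1L
    data.frame(fingerprint = i,
               degree_assortativity =
                 if (has_e) degreeAssortativity(g) else NA_real_,
               label_assortativity =
                 if (has_e) labelAssortativity(g) else NA_real_)
  })
  do.call(rbind, rows)
}

welchP <- function(x, y) {
  ## degenerate (essentially constant) samples: fall back to comparing means
  tryCatch(stats::t.test(x, y, var.equal = FALSE)$p.value,
           error = function(e)
             if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
}

#' Compare two domains' fingerprint assortativity distributions
#'
#' Two-sided Welch two-sample t-tests of the per-fingerprint degree and
#' label assortativity between two fingerprint sets. Undefined
#' assortativity values are dropped, with counts reported.
#'
#' @param fpsA,fpsB fingerprint lists of the two domains
#' @return list with \code{p_degree}, \code{p_label}, sample sizes and
#'   dropped counts
#' @export
compareDomains <- function(fpsA, fpsB) {
  ta <- assortativityTable(fpsA); tb <- assortativityTable(fpsB)
  res <- list()
  for (metric in c("degree_assortativity", "label_assortativity")) {
    x <- ta[[metric]]; y <- tb[[metric]]
    dx <- sum(is.na(x)); dy <- sum(is.na(y))
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L)
      stop("fewer than 2 defined ", metric, " values in a set")
    key <- if (metric == "degree_assortativity") "degree" else "label"
    res[[paste0("p_", key)]] <- welchP(x, y)
    res[[paste0("n_", key)]] <- c(length(x), length(y))
    res[[paste0("dropped_", key)]] <- c(dx, dy)
  }
  res
}

#' Subsampled isomorphism disparity between two domains
#'
#' Repeatedly samples \code{k} fingerprints with replacement from each
#' domain and counts isomorphic pairs. The observed cross-domain disparity
#' (mean cross-sample count) is referred to the within-domain resampling
#' distribution (counts between two independent samples of the same
#' domain, pooled over both domains) and converted to a two-sided
#' add-one-smoothed p-value.
#'
#' @param fpsA,fpsB fingerprint lists, each of size >= k
#' @param k subsample size (default 50)
#' @param nReps resampling replicates (default 1000)
#' @param seed RNG seed
#' @return list with \code{p}, \code{observed} (mean cross count), and the
#'   within-domain null summary
#' @export
subsampleDisparity <- function(fpsA, fpsB, k = 50L, nReps = 1000L,
                               seed = NULL) {
  if (length(fpsA) < k || length(fpsB) < k)
    stop("both fingerprint sets must have at least k = ", k, " members")
  draw <- function(fps) fps[sample.int(length(fps), k, replace = TRUE)]
  res <- withSeed(seed, {
    cross <- numeric(nReps); within <- numeric(2L * nReps)
    for (r in seq_len(nReps)) {
      cross[r] <- countIsomorphicPairs(draw(fpsA), draw(fpsB))
      within[2L * r - 1L] <- countIsomorphicPairs(draw(fpsA), draw(fpsA))
      within[2L * r] <- countIsomorphicPairs(draw(fpsB), draw(fpsB))
    }
    list(cross = cross, within = within)
  })
  obs <- mean(res$cross)
  lo <- (1 + sum(res$within <= obs)) / (length(res$within) + 1)
  hi <- (1 + sum(res$within >= obs)) / (length(res$within) + 1)
  list(p = min(1, 2 * min(lo, hi)), observed = obs,
       within_mean = mean(res$within), within_sd = stats::sd(res$within),
       k = k, nReps = nReps)
}

#' Relation report for one domain
#'
#' Assembles the full relation analysis of a domain's binding sites:
#' cooperative pairs, distinctive fingerprints, pairwise isomorphism
#' counts with random-graph null p-values, and per-fingerprint
#' assortativity.
#'
#' @param fpsBySite named list: site id -> fingerprints
#' @param graphs the domain's \code{\linkS4class{InterfaceGraph}}s
#' @param minCoFraction cooperative reporting threshold
#' @param nReps null-model replicates per site pair
#' @param seed RNG seed for the null model
#' @return a \code{\linkS4class{RelationReport}}
#' @export
domainRelationReport <- function(fpsBySite, graphs, minCoFraction = 0.20,
                                 nReps = 2000L, seed = 1L) {
  coop <- suppressWarnings(cooperativePairs(fpsBySite, graphs,
                                            minCoFraction))
  sites <- names(fpsBySite)
  dist_rows <- list()
  for (s in sites) {
    dfp <- distinctiveFingerprints(as.integer(s), fpsBySite, graphs)
    own <- fpsBySite[[s]]
    codes <- vapply(own, function(f) f@code, "")
    dcodes <- vapply(dfp, function(f) f@code, "")
    if (length(own))
      dist_rows[[s]] <- data.frame(site = as.integer(s),
                                   fingerprint = seq_along(own),
                                   distinctive = codes %in% dcodes)
  }
  distinctive <- if (length(dist_rows)) do.call(rbind, dist_rows) else
    data.frame(site = integer(), fingerprint = integer(),
               distinctive = logical())
  freqs <- dbLabelFrequencies(graphs)
  iso_rows <- list()
  if (length(sites) > 1L) {
    for (a in seq_along(sites)) for (b in seq_along(sites)) {
      if (a >= b) next
      fa <- fpsBySite[[a]]; fb <- fpsBySite[[b]]
      obs <- countIsomorphicPairs(fa, fb)
      sz <- function(fps) data.frame(
        n_nodes = vapply(fps, function(f) as.integer(igraph::vcount(f@pattern)), 0L),
        n_edges = vapply(fps, function(f) as.integer(igraph::ecount(f@pattern)), 0L))
      pv <- if (length(fa) && length(fb))
        randomNullPvalue(sz(fa), sz(fb), freqs, obs, nReps = nReps,
                         seed = seed + a * 131L + b)
      else list(p = 1, display = "1.0e+00")
      iso_rows[[length(iso_rows) + 1L]] <- data.frame(
        site_a = as.integer(sites[a]), site_b = as.integer(sites[b]),
        n_a = length(fa), n_b = length(fb), observed = obs,
        p = pv$p, p_display = pv$display, stringsAsFactors = FALSE)
    }
  }
  isomorphism <- if (length(iso_rows)) do.call(rbind, iso_rows) else
    data.frame(site_a = integer(), site_b = integer(), n_a = integer(),
               n_b = integer(), observed = integer(), p = numeric(),
               p_display = character())
  assort <- do.call(rbind, lapply(sites, function(s) {
    at <- assortativityTable(fpsBySite[[s]])
    if (nrow(at)) cbind(site = as.integer(s), at) else NULL
  }))
  if (is.null(assort))
    assort <- data.frame(site = integer(), fingerprint = integer(),
                         degree_assortativity = numeric(),
                         label_assortativity = numeric())
  new("RelationReport", cooperative = coop, distinctive = distinctive,
      isomorphism = isomorphism, assortativity = assort,
      meta = list(minCoFraction = minCoFraction, nReps = nReps,
                  seed = seed))
}
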