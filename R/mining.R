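## Closed frequent subgraph mining over interface graph databases.
##
## Patterns are connected node-labeled graphs; support is transaction
## support (one count per database graph containing the pattern under
## subgraph monomorphism). The miner grows patterns breadth-first from
## frequent single nodes, extending only along embeddings actually present
## in the database, de-duplicating candidates by canonical code.

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(seed)
    return(expr)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Support threshold from a local support fraction
#'
#' The absolute support is the number of database graphs times the local
#' support fraction (default 20 percent), rounded up, and never below 2 so
#' that a "frequent" pattern recurs.
#'
#' @param nGraphs database size
#' @param localSupport fraction in (0, 1]
#' @return integer threshold
#' @examples
#' supportThreshold(10)   # 2
#' supportThreshold(100)  # 20
#' @export
supportThreshold <- function(nGraphs, localSupport = 0.20) {
  stopifnot(nGraphs >= 1L)
  max(2L, as.integer(ceiling(nGraphs * localSupport)))
}

## internal pattern/graph representation: list(lab = character labels,
## edges = m x 2 integer matrix with first column smaller). Labels are
## arbitrary strings; amino acids in real data, anything in tests.
asInternalGraph <- function(g) {
  if (is(g, "InterfaceGraph")) g <- g@graph
  if (is(g, "Fingerprint")) g <- g@pattern
  stopifnot(igraph::is_igraph(g))
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  if (nrow(el)) el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  list(lab = as.character(igraph::V(g)$aa), edges = el)
}

asIgraphPattern <- function(p) {
  g <- igraph::make_empty_graph(length(p$lab), directed = FALSE)
  if (nrow(p$edges)) g <- igraph::add_edges(g, t(p$edges))
  igraph::V(g)$aa <- p$lab
  g
}

## label-preserving monomorphism / embedding enumeration via the compiled
## matcher; integer label dictionaries are built per call
matchExists <- function(p, h) {
  dict <- sort(unique(c(p$lab, h$lab)))
  .match_exists_cpp(match(p$lab, dict), p$edges, match(h$lab, dict),
                    h$edges)
}

matchAll <- function(p, h, cap = 5000L) {
  dict <- sort(unique(c(p$lab, h$lab)))
  .match_all_cpp(match(p$lab, dict), p$edges, match(h$lab, dict),
                 h$edges, cap = cap)
}

canonicalCodeInternal <- function(p) {
  n <- length(p$lab)
  if (n == 1L) return(paste0("1|", p$lab, "|"))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(p$edges)) g <- igraph::add_edges(g, t(p$edges))
  colors <- match(p$lab, sort(unique(p$lab)))
  perm <- igraph::canonical_permutation(g, colors = colors)$labeling
  lab2 <- character(n); lab2[perm] <- p$lab
  if (nrow(p$edges)) {
    e2 <- cbind(perm[p$edges[, 1]], perm[p$edges[, 2]])
    e2 <- cbind(pmin(e2[, 1], e2[, 2]), pmax(e2[, 1], e2[, 2]))
    e2 <- e2[order(e2[, 1], e2[, 2]), , drop = FALSE]
    es <- paste(e2[, 1], e2[, 2], sep = "-", collapse = ";")
  } else es <- ""
  paste(n, paste(lab2, collapse = ","), es, sep = "|")
}

#' Canonical code of a labeled graph
#'
#' A string invariant under label-preserving isomorphism: two graphs get
#' the same code exactly when they are isomorphic with matching amino-acid
#' labels. Computed from a canonical vertex labeling (BLISS, with labels as
#' vertex colors).
#'
#' @param g an igraph with vertex attribute \code{aa}, an
#'   \code{\linkS4class{InterfaceGraph}} or a
#'   \code{\linkS4class{Fingerprint}}
#' @return code string
#' @export
graphCanonicalCode <- function(g) canonicalCodeInternal(asInternalGraph(g))

#' Does a pattern occur in a host graph?
#'
#' Label-preserving injective mapping of pattern nodes into host nodes
#' such that every pattern edge maps onto a host edge (monomorphism: the
#' host may have extra edges among the mapped nodes).
#'
#' @param pattern,host labeled graphs (igraph with \code{aa},
#'   \code{InterfaceGraph} or \code{Fingerprint})
#' @return logical
#' @export
subgraphOccurs <- function(pattern, host) {
  matchExists(asInternalGraph(pattern), asInternalGraph(host))
}

#' Are two labeled graphs isomorphic?
#'
#' Exact label-preserving isomorphism (bijective, edges onto edges).
#'
#' @param g1,g2 labeled graphs
#' @return logical
#' @export
isIsomorphic <- function(g1, g2) {
  a <- asInternalGraph(g1); b <- asInternalGraph(g2)
  if (length(a$lab) != length(b$lab) || nrow(a$edges) != nrow(b$edges))
    return(FALSE)
  if (!identical(sort(a$lab), sort(b$lab))) return(FALSE)
  canonicalCodeInternal(a) == canonicalCodeInternal(b)
}

## one-step extensions of pattern p realised inside its occurrence graphs;
## returns list of internal patterns (not yet de-duplicated)
patternExtensions <- function(p, graphs, occ, embCap = 5000L) {
  np <- length(p$lab)
  adj <- matrix(FALSE, np, np)
  if (nrow(p$edges)) {
    adj[p$edges] <- TRUE
    adj[p$edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  seen <- new.env(parent = emptyenv())
  out <- list()
  add_ext <- function(q) {
    key <- paste(paste(q$lab, collapse = ","),
                 paste(q$edges[, 1], q$edges[, 2], sep = "-", collapse = ";"),
                 sep = "|")
    if (!is.null(seen[[key]])) return()
    seen[[key]] <- TRUE
    out[[length(out) + 1L]] <<- q
  }
  for (gi in occ) {
    h <- graphs[[gi]]
    embs <- matchAll(p, h, cap = embCap)
    if (!nrow(embs)) next
    hadj <- lapply(seq_along(h$lab), function(i) integer(0))
    if (nrow(h$edges)) {
      for (e in seq_len(nrow(h$edges))) {
        a <- h$edges[e, 1]; b <- h$edges[e, 2]
        hadj[[a]] <- c(hadj[[a]], b); hadj[[b]] <- c(hadj[[b]], a)
      }
    }
    hem <- matrix(FALSE, length(h$lab), length(h$lab))
    if (nrow(h$edges)) {
      hem[h$edges] <- TRUE
      hem[h$edges[, c(2, 1), drop = FALSE]] <- TRUE
    }
    for (r in seq_len(nrow(embs))) {
      m <- embs[r, ]
      ## (a) close an edge between two already-mapped pattern nodes
      if (np >= 2L) for (u in 1:(np - 1L)) for (v in (u + 1L):np) {
        if (!adj[u, v] && hem[m[u], m[v]])
          add_ext(list(lab = p$lab,
                       edges = rbind(p$edges, c(u, v))))
      }
      ## (b) grow a new node attached to a mapped node
      for (u in seq_len(np)) {
        for (w in hadj[[m[u]]]) {
          if (w %in% m) next
          add_ext(list(lab = c(p$lab, h$lab[w]),
                       edges = rbind(p$edges, c(u, np + 1L))))
        }
      }
    }
  }
  out
}

#' Mine closed frequent subgraph fingerprints
#'
#' Enumerates exactly the connected labeled patterns whose support (number
#' of database graphs containing them) reaches the threshold, and keeps
#' those that are \emph{closed}: no extension by one edge, or by one node
#' plus an edge, has the same support. Output is de-duplicated by canonical
#' code and sorted by size (nodes, then edges) descending, support
#' descending, code; mining is fully deterministic.
#'
#' @param db list of labeled graphs (\code{InterfaceGraph} or igraph with
#'   vertex attribute \code{aa})
#' @param support absolute support threshold; when NULL derived via
#'   \code{\link{supportThreshold}(length(db), localSupport)}
#' @param localSupport local support fraction (default 0.20)
#' @param maxNodes optional cap on pattern size in nodes
#' @param siteId site id stamped on the fingerprints
#' @return list of \code{\linkS4class{Fingerprint}}
#' @export
mineClosedFrequent <- function(db, support = NULL, localSupport = 0.20,
                               maxNodes = Inf, siteId = NA_integer_) {
  stopifnot(length(db) >= 1L)
  graphs <- lapply(db, asInternalGraph)
  gids <- names(db)
  if (is.null(gids)) gids <- sprintf("g%03d", seq_along(db))
  t <- if (is.null(support)) supportThreshold(length(db), localSupport)
       else as.integer(support)
  stopifnot(t >= 1L, t <= length(db))

  pats <- new.env(parent = emptyenv())   # code -> record
  queue <- character(0)
  register <- function(p, occ) {
    code <- canonicalCodeInternal(p)
    if (is.null(pats[[code]])) {
      pats[[code]] <- list(p = p, occ = occ, support = length(occ),
                           closed = TRUE, frequent = length(occ) >= t)
      if (length(occ) >= t) queue <<- c(queue, code)
    }
    code
  }
  ## frequent single-node patterns
  for (l in sort(unique(unlist(lapply(graphs, `[[`, "lab"))))) {
    occ <- which(vapply(graphs, function(g) l %in% g$lab, TRUE))
    if (length(occ) >= t)
      register(list(lab = l, edges = matrix(integer(), 0, 2)), occ)
  }
  qi <- 0L
  while (qi < length(queue)) {
    qi <- qi + 1L
    code <- queue[qi]
    rec <- pats[[code]]
    exts <- patternExtensions(rec$p, graphs, rec$occ)
    for (q in exts) {
      if (length(q$lab) > maxNodes) next
      ecode <- canonicalCodeInternal(q)
      er <- pats[[ecode]]
      if (is.null(er)) {
        occ <- rec$occ[vapply(rec$occ, function(gi)
          matchExists(q, graphs[[gi]]), TRUE)]
        pats[[ecode]] <- er <- list(p = q, occ = occ, support = length(occ),
                                    closed = TRUE,
                                    frequent = length(occ) >= t)
        if (er$frequent) queue <- c(queue, ecode)
      }
      if (er$support == rec$support) {
        rec$closed <- FALSE
        pats[[code]] <- rec
      }
    }
  }
  codes <- ls(pats)
  keep <- Filter(function(cd) pats[[cd]]$frequent && pats[[cd]]$closed, codes)
  fps <- lapply(keep, function(cd) {
    rec <- pats[[cd]]
    new("Fingerprint", pattern = asIgraphPattern(rec$p),
        support = rec$support, occurrences = gids[rec$occ], code = cd,
        siteId = as.integer(siteId))
  })
  nn <- vapply(fps, function(f) as.integer(igraph::vcount(f@pattern)), 0L)
  ne <- vapply(fps, function(f) as.integer(igraph::ecount(f@pattern)), 0L)
  sp <- vapply(fps, function(f) f@support, 0L)
  cd <- vapply(fps, function(f) f@code, "")
  fps[order(-nn, -ne, -sp, cd)]
}

#' Index table of mined fingerprints
#'
#' @param fps list of \code{\linkS4class{Fingerprint}}
#' @return data.frame with id, site, size, support, occurrence list,
#'   canonical code and a \code{trivial} flag (fewer than two edges)
#' @export
fingerprintIndex <- function(fps) {
  data.frame(
    fingerprint_id = seq_along(fps),
    site_id = vapply(fps, function(f) f@siteId, 0L),
    n_nodes = vapply(fps, function(f) as.integer(igraph::vcount(f@pattern)), 0L),
    n_edges = vapply(fps, function(f) as.integer(igraph::ecount(f@pattern)), 0L),
    support = vapply(fps, function(f) f@support, 0L),
    occurrences = vapply(fps, function(f)
      paste(f@occurrences, collapse = ","), ""),
    canonical_code = vapply(fps, function(f) f@code, ""),
    trivial = vapply(fps, function(f) igraph::ecount(f@pattern) < 2L, TRUE),
    stringsAsFactors = FALSE)
}

#' Count isomorphic fingerprints between two sets
#'
#' The number of fingerprints on the smaller side having at least one
#' label-isomorphic counterpart on the other side.
#'
#' @param setA,setB lists of \code{\linkS4class{Fingerprint}} (or labeled
#'   graphs)
#' @return integer count
#' @export
countIsomorphicPairs <- function(setA, setB) {
  codeOf <- function(x) if (is(x, "Fingerprint")) x@code else
    graphCanonicalCode(x)
  ca <- vapply(setA, codeOf, "")
  cb <- vapply(setB, codeOf, "")
  if (length(ca) <= length(cb)) sum(ca %in% cb) else sum(cb %in% ca)
}

#' Random connected labeled graph
#'
#' Null-model generator: a uniformly attached random spanning tree plus the
#' remaining edges drawn uniformly among non-edges, guaranteeing
#' connectivity; labels i.i.d. from the supplied amino-acid frequencies.
#'
#' @param nNodes,nEdges size of the graph (\code{nEdges} between
#'   \code{nNodes - 1} and \code{choose(nNodes, 2)}; 0 for a single node)
#' @param labelFreqs named numeric vector of amino-acid frequencies
#' @return igraph with vertex attribute \code{aa}
#' @export
randomConnectedGraph <- function(nNodes, nEdges, labelFreqs) {
  maxE <- nNodes * (nNodes - 1) / 2
  minE <- if (nNodes <= 1L) 0L else nNodes - 1L
  if (nEdges < minE || nEdges > maxE)
    stop("impossible (n_nodes, n_edges) combination: ", nNodes, ", ", nEdges)
  lab <- sample(names(labelFreqs), nNodes, replace = TRUE,
                prob = labelFreqs)
  g <- igraph::make_empty_graph(nNodes, directed = FALSE)
  if (nNodes > 1L) {
    tree <- cbind(2:nNodes, vapply(2:nNodes, function(i)
      if (i == 2L) 1L else sample.int(i - 1L, 1L), 1L))
    g <- igraph::add_edges(g, t(tree))
    extra <- nEdges - (nNodes - 1L)
    if (extra > 0L) {
      all_pairs <- utils::combn(nNodes, 2L)
      have <- paste(pmin(tree[, 1], tree[, 2]), pmax(tree[, 1], tree[, 2]))
      free <- which(!(paste(all_pairs[1, ], all_pairs[2, ]) %in% have))
      pick <- free[sample.int(length(free), extra)]
      g <- igraph::add_edges(g, all_pairs[, pick, drop = FALSE])
    }
  }
  igraph::V(g)$aa <- lab
  g
}

#' Amino-acid label frequencies of a graph database
#'
#' @param db list of labeled graphs
#' @return named frequency vector over the labels present
#' @export
dbLabelFrequencies <- function(db) {
  lab <- unlist(lapply(db, function(g) asInternalGraph(g)$lab))
  tab <- table(lab)
  tab / sum(tab)
}

#' Random-graph null p-value for an isomorphism count
#'
#' Generates, for each replicate, random connected labeled graphs matching
#' each fingerprint's node and edge count in both sets (labels drawn from
#' \code{labelFreqs}), counts isomorphic pairs, and reports the fraction of
#' replicates reaching at least the observed count. A count of zero is
#' displayed as "< 1/n_reps".
#'
#' @param sizesA,sizesB data.frames with columns \code{n_nodes},
#'   \code{n_edges}, one row per fingerprint
#' @param labelFreqs named amino-acid frequency vector
#' @param observed observed isomorphic-pair count
#' @param nReps Monte-Carlo replicates (default 2000)
#' @param seed RNG seed
#' @return list with \code{p} (numeric), \code{display} (string form),
#'   \code{n_ge} (replicates at or above observed), \code{nReps}
#' @export
randomNullPvalue <- function(sizesA, sizesB, labelFreqs, observed,
                             nReps = 2000L, seed = NULL) {
  stopifnot(nReps >= 1L)
  counts <- withSeed(seed, {
    vapply(seq_len(nReps), function(r) {
      ga <- lapply(seq_len(nrow(sizesA)), function(i)
        randomConnectedGraph(sizesA$n_nodes[i], sizesA$n_edges[i],
                             labelFreqs))
      gb <- lapply(seq_len(nrow(sizesB)), function(i)
        randomConnectedGraph(sizesB$n_nodes[i], sizesB$n_edges[i],
                             labelFreqs))
      countIsomorphicPairs(ga, gb)
    }, 0L)
  })
  k <- sum(counts >= observed)
  p <- k / nReps
  list(p = p,
       display = if (k == 0L) sprintf("< %.1e", 1 / nReps)
                 else sprintf("%.1e", p),
       n_ge = k, nReps = nReps)
}
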