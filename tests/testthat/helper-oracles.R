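## Independent brute-force oracles used to validate the package's
## implementations. Everything here is pure R and deliberately naive.

## small labeled graph constructor (vertex attribute aa)
mkg <- function(aa, edges = integer()) {
  g <- igraph::make_empty_graph(length(aa), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::V(g)$aa <- aa
  g
}

## internal (lab, edges) view of an igraph, independent of package internals
gview <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el)) el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  list(lab = as.character(igraph::V(g)$aa), edges = el)
}

## brute-force label-preserving monomorphism: recursive injective mapping
bruteMatch <- function(p, h) {
  if (igraph::is_igraph(p)) p <- gview(p)
  if (igraph::is_igraph(h)) h <- gview(h)
  np <- length(p$lab); nh <- length(h$lab)
  if (np > nh) return(FALSE)
  hadj <- matrix(FALSE, nh, nh)
  if (nrow(h$edges)) {
    hadj[h$edges] <- TRUE
    hadj[h$edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  rec <- function(map) {
    u <- length(map) + 1L
    if (u > np) return(TRUE)
    for (v in seq_len(nh)) {
      if (v %in% map || h$lab[v] != p$lab[u]) next
      ok <- TRUE
      if (nrow(p$edges)) for (e in seq_len(nrow(p$edges))) {
        a <- p$edges[e, 1]; b <- p$edges[e, 2]
        if (a < u && b == u && !hadj[map[a], v]) { ok <- FALSE; break }
        if (b < u && a == u && !hadj[map[b], v]) { ok <- FALSE; break }
      }
      if (ok && rec(c(map, v))) return(TRUE)
    }
    FALSE
  }
  rec(integer())
}

## brute-force labeled-isomorphism via permutations
bruteIso <- function(g1, g2) {
  a <- gview(g1); b <- gview(g2)
  n <- length(a$lab)
  if (n != length(b$lab) || nrow(a$edges) != nrow(b$edges)) return(FALSE)
  ek <- function(e) sort(paste(e[, 1], e[, 2]))
  bkey <- ek(b$edges)
  for (p in permnList(n)) {       # sigma: node i of g1 -> node p[i] of g2
    if (!all(a$lab == b$lab[p])) next
    if (!nrow(a$edges)) return(TRUE)
    e2 <- cbind(p[a$edges[, 1]], p[a$edges[, 2]])
    e2 <- cbind(pmin(e2[, 1], e2[, 2]), pmax(e2[, 1], e2[, 2]))
    if (identical(ek(e2), bkey)) return(TRUE)
  }
  FALSE
}

permnList <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      if (n == 1L) cache[[key]] <<- list(1L)
      else {
        sub <- permnList(n - 1L)
        out <- list()
        for (s in sub) for (pos in seq_len(n)) {
          out[[length(out) + 1L]] <- append(s, n, after = pos - 1L)
        }
        cache[[key]] <<- out
      }
    }
    cache[[key]]
  }
})

## permutation-minimal canonical key (oracle-side, independent of BLISS)
bruteKey <- function(lab, edges) {
  n <- length(lab)
  if (n == 1L) return(paste0(lab, "|"))
  best <- NULL
  for (p in permnList(n)) {
    inv <- integer(n); inv[p] <- seq_len(n)   # inv maps old id -> new id
    l2 <- lab[p]
    if (nrow(edges)) {
      e2 <- cbind(inv[edges[, 1]], inv[edges[, 2]])
      e2 <- cbind(pmin(e2[, 1], e2[, 2]), pmax(e2[, 1], e2[, 2]))
      e2 <- e2[order(e2[, 1], e2[, 2]), , drop = FALSE]
      key <- paste(paste(l2, collapse = ","),
                   paste(e2[, 1], e2[, 2], sep = "-", collapse = ";"),
                   sep = "|")
    } else key <- paste0(paste(l2, collapse = ","), "|")
    if (is.null(best) || key < best) best <- key
  }
  best
}

## connectivity of (nodes 1..n, edge matrix)
connectedPattern <- function(n, edges) {
  if (n == 1L) return(TRUE)
  if (!nrow(edges)) return(FALSE)
  seen <- c(1L); frontier <- c(1L)
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      nb <- c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
      nxt <- c(nxt, setdiff(nb, seen))
    }
    nxt <- unique(nxt)
    seen <- c(seen, nxt); frontier <- nxt
  }
  length(seen) == n
}

## brute-force closed frequent subgraph enumeration:
## candidates = all connected (node subset, edge subset) subpatterns of the
## database graphs; support via bruteMatch; closed = no frequent proper
## superpattern (one more edge, or one more node and edge) of equal support
bruteClosedFrequent <- function(db, t) {
  views <- lapply(db, gview)
  cand <- new.env(parent = emptyenv())
  for (v in views) {
    n <- length(v$lab)
    for (sz in seq_len(n)) {
      for (S in utils::combn(n, sz, simplify = FALSE)) {
        within <- if (nrow(v$edges))
          which(v$edges[, 1] %in% S & v$edges[, 2] %in% S) else integer()
        if (sz > 1L && length(within) < sz - 1L) next
        esubs <- if (length(within))
          unlist(lapply(seq_along(within), function(k)
            lapply(asplit(utils::combn(seq_along(within), k), 2),
                   function(ix) within[ix])), recursive = FALSE)
          else list(integer())
        if (sz == 1L) esubs <- list(integer())
        for (es in esubs) {
          em <- v$edges[es, , drop = FALSE]
          ren <- match(c(em[, 1], em[, 2]), S)
          em2 <- matrix(ren, ncol = 2)
          if (!connectedPattern(sz, em2)) next
          key <- bruteKey(v$lab[S], em2)
          if (is.null(cand[[key]]))
            cand[[key]] <- list(lab = v$lab[S], edges = em2)
        }
      }
    }
  }
  keys <- ls(cand)
  pats <- lapply(keys, function(k) cand[[k]])
  supp <- vapply(pats, function(p)
    sum(vapply(views, function(v) bruteMatch(p, v), TRUE)), 0L)
  freq <- which(supp >= t)
  is_closed <- vapply(freq, function(i) {
    p <- pats[[i]]
    for (j in freq) {
      if (j == i || supp[j] != supp[i]) next
      q <- pats[[j]]
      one_step <- (length(q$lab) == length(p$lab) &&
                     nrow(q$edges) == nrow(p$edges) + 1L) ||
                  (length(q$lab) == length(p$lab) + 1L &&
                     nrow(q$edges) == nrow(p$edges) + 1L)
      if (one_step && bruteMatch(p, q)) return(FALSE)
    }
    TRUE
  }, TRUE)
  list(keys = keys[freq][is_closed], supports = supp[freq][is_closed],
       patterns = pats[freq][is_closed])
}

## brute-force closed frequent itemsets by power-set enumeration
bruteClosedItemsets <- function(transactions, minsup) {
  items <- sort(unique(unlist(transactions)))
  out <- list()
  for (k in seq_along(items)) {
    for (S in utils::combn(items, k, simplify = FALSE)) {
      sup <- sum(vapply(transactions, function(tr) all(S %in% tr), TRUE))
      if (sup < minsup) next
      closed <- TRUE
      for (extra in setdiff(items, S)) {
        sup2 <- sum(vapply(transactions, function(tr)
          all(c(S, extra) %in% tr), TRUE))
        if (sup2 == sup) { closed <- FALSE; break }
      }
      if (closed) out[[length(out) + 1L]] <-
          list(itemset = paste(S, collapse = ","), support = sup)
    }
  }
  data.frame(itemset = vapply(out, `[[`, "", "itemset"),
             support = vapply(out, function(x) as.integer(x$support), 0L),
             stringsAsFactors = FALSE)
}

## brute-force Delaunay edge oracle: edges of all empty-circumsphere
## tetrahedra (O(n^4) subsets, each tested against all points)
bruteDelaunayEdges <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 4L)
  keys <- character()
  for (q in utils::combn(n, 4L, simplify = FALSE)) {
    A <- 2 * (pts[q[2:4], , drop = FALSE] -
                matrix(pts[q[1], ], 3, 3, byrow = TRUE))
    b <- rowSums(pts[q[2:4], , drop = FALSE]^2) - sum(pts[q[1], ]^2)
    cc <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(cc)) next
    r2 <- sum((pts[q[1], ] - cc)^2)
    d2 <- colSums((t(pts) - cc)^2)
    if (all(d2[-q] > r2 + 1e-9))
      keys <- c(keys, apply(utils::combn(q, 2L), 2L, paste, collapse = "-"))
  }
  unique(keys)
}

## random labeled graph (not necessarily connected) for property tests
randomLabeledGraph <- function(nNodes, nEdges, labels = c("A", "B", "C")) {
  g <- igraph::make_empty_graph(nNodes, directed = FALSE)
  if (nNodes > 1L && nEdges > 0L) {
    all_pairs <- utils::combn(nNodes, 2L)
    pick <- sample.int(ncol(all_pairs), min(nEdges, ncol(all_pairs)))
    g <- igraph::add_edges(g, all_pairs[, pick, drop = FALSE])
  }
  igraph::V(g)$aa <- sample(labels, nNodes, replace = TRUE)
  g
}
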