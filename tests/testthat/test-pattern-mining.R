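test_that("support threshold is 20% of the database, floored at 2", {
  expect_equal(supportThreshold(10), 2L)
  expect_equal(supportThreshold(7), 2L)
  expect_equal(supportThreshold(100), 20L)
  expect_equal(supportThreshold(3, 0.5), 2L)
})

test_that("subgraph occurrence is monomorphism, checked against brute force", {
  tri <- mkg(c("A", "B", "C"), c(1, 2, 2, 3, 1, 3))
  path <- mkg(c("A", "B", "C"), c(1, 2, 2, 3))
  cherry <- mkg(c("A", "B", "C"), c(1, 2, 1, 3))
  expect_true(subgraphOccurs(mkg("A"), tri))
  expect_true(subgraphOccurs(path, tri))   # host may have extra edges
  expect_false(subgraphOccurs(path, cherry))
  set.seed(51)
  for (trial in 1:40) {
    p <- randomLabeledGraph(sample(1:4, 1), sample(0:4, 1))
    h <- randomLabeledGraph(sample(2:6, 1), sample(0:8, 1))
    expect_identical(subgraphOccurs(p, h), bruteMatch(p, h),
                     info = paste("trial", trial))
  }
})

test_that("labeled isomorphism agrees with the permutation oracle", {
  g1 <- mkg(c("A", "B", "C"), c(1, 2, 2, 3))
  expect_true(isIsomorphic(g1, mkg(c("C", "B", "A"), c(3, 2, 2, 1))))
  expect_false(isIsomorphic(g1, mkg(c("A", "B", "D"), c(1, 2, 2, 3))))
  set.seed(52)
  for (trial in 1:60) {
    n <- sample(2:6, 1)
    g <- randomLabeledGraph(n, sample(0:6, 1))
    if (trial %% 2 == 0) {
      ## a shuffled copy must be isomorphic
      p <- sample(n)
      el <- igraph::as_edgelist(g, names = FALSE)
      g2 <- mkg(igraph::V(g)$aa[order(p)],
                as.vector(t(cbind(p[el[, 1]], p[el[, 2]]))))
      expect_true(isIsomorphic(g, g2), info = paste("trial", trial))
    } else {
      h <- randomLabeledGraph(n, sample(0:6, 1))
      expect_identical(isIsomorphic(g, h), bruteIso(g, h),
                       info = paste("trial", trial))
    }
  }
})

test_that("canonical codes are isomorphism-invariant up to 8 nodes", {
  set.seed(53)
  for (trial in 1:40) {
    n <- sample(2:8, 1)
    g <- randomLabeledGraph(n, sample(1:10, 1), labels = c("A", "B"))
    p <- sample(n)
    el <- igraph::as_edgelist(g, names = FALSE)
    g2 <- mkg(igraph::V(g)$aa[order(p)],
              as.vector(t(cbind(p[el[, 1]], p[el[, 2]]))))
    expect_identical(graphCanonicalCode(g), graphCanonicalCode(g2))
    h <- randomLabeledGraph(n, sample(1:10, 1), labels = c("A", "B"))
    expect_identical(graphCanonicalCode(g) == graphCanonicalCode(h),
                     bruteIso(g, h), info = paste("trial", trial))
  }
})

test_that("the miner reproduces the worked closed-set example", {
  db <- list(g1 = mkg(c("A", "B", "C"), c(1, 2, 2, 3)),
             g2 = mkg(c("A", "B", "C"), c(1, 2, 2, 3)),
             g3 = mkg(c("A", "B"), c(1, 2)))
  fps <- mineClosedFrequent(db, support = 2)
  key <- vapply(fps, function(f)
    paste(sort(igraph::V(patternGraph(f))$aa), collapse = ""), "")
  sup <- vapply(fps, supportCount, 0L)
  expect_setequal(paste(key, sup), c("AB 3", "ABC 2"))
  ## B-C alone is frequent but absorbed by the closed A-B-C path
  expect_false(any(key == "BC"))
})

test_that("threshold equal to the database size yields the common graph", {
  g <- mkg(c("A", "C", "D", "E"), c(1, 2, 2, 3, 3, 4, 4, 1))
  fps <- mineClosedFrequent(list(a = g, b = g, c = g), support = 3)
  expect_length(fps, 1L)
  expect_true(isIsomorphic(patternGraph(fps[[1]]), g))
  expect_equal(supportCount(fps[[1]]), 3L)
})

test_that("miner equals brute-force enumeration on random databases", {
  set.seed(54)
  for (trial in 1:25) {
    db <- lapply(seq_len(sample(2:5, 1)), function(i) {
      n <- sample(2:6, 1)
      randomLabeledGraph(n, sample(1:min(8, choose(n, 2)), 1))
    })
    names(db) <- paste0("g", seq_along(db))
    t <- sample(2:max(2, length(db)), 1)
    got <- mineClosedFrequent(db, support = t)
    oracle <- bruteClosedFrequent(db, t)
    got_keys <- vapply(got, function(f) {
      v <- gview(patternGraph(f))
      paste(bruteKey(v$lab, v$edges), supportCount(f))
    }, "")
    oracle_keys <- paste(oracle$keys, oracle$supports)
    expect_setequal(got_keys, oracle_keys)
  }
})

test_that("frequent patterns are anti-monotone and mining is deterministic", {
  set.seed(55)
  db <- lapply(1:5, function(i) randomLabeledGraph(6, 7))
  names(db) <- paste0("g", 1:5)
  fps <- mineClosedFrequent(db, support = 2)
  for (f in fps) {
    p <- patternGraph(f)
    el <- igraph::as_edgelist(p, names = FALSE)
    ## dropping any single edge keeps each connected component frequent
    if (nrow(el) < 2) next
    for (e in seq_len(nrow(el))) {
      q <- igraph::delete_edges(p, e)
      comp <- igraph::components(q)
      for (k in seq_len(comp$no)) {
        sub <- igraph::induced_subgraph(q, which(comp$membership == k))
        supp <- sum(vapply(db, function(g) subgraphOccurs(sub, g), TRUE))
        expect_gte(supp, supportCount(f))
      }
    }
  }
  again <- mineClosedFrequent(db, support = 2)
  expect_identical(vapply(fps, canonicalCode, ""),
                   vapply(again, canonicalCode, ""))
  expect_identical(vapply(fps, supportCount, 0L),
                   vapply(again, supportCount, 0L))
})

test_that("isomorphic pair counting sides with the smaller set", {
  a1 <- mkg(c("A", "B"), c(1, 2)); a2 <- mkg(c("C", "D"), c(1, 2))
  b1 <- mkg(c("B", "A"), c(1, 2)); b2 <- mkg(c("E", "F"), c(1, 2))
  expect_equal(countIsomorphicPairs(list(a1, a2), list(b1, b2)), 1L)
  expect_equal(countIsomorphicPairs(list(a1, a2), list(a2, a1)), 2L)
  expect_equal(countIsomorphicPairs(list(a1), list(b2)), 0L)
  ## the smaller side bounds the count
  expect_equal(countIsomorphicPairs(list(a1), list(b1, a1, b1)), 1L)
})

test_that("random connected graphs honour size constraints and seeds", {
  set.seed(56)
  freqs <- setNames(rep(0.05, 20), miDomains:::AA20)
  g <- randomConnectedGraph(6, 8, freqs)
  expect_equal(igraph::vcount(g), 6)
  expect_equal(igraph::ecount(g), 8)
  expect_true(igraph::is_connected(g))
  expect_error(randomConnectedGraph(4, 2, freqs), "impossible")
  expect_error(randomConnectedGraph(4, 7, freqs), "impossible")
})

test_that("null p-values are sane and monotone in the observed count", {
  freqs <- c(X = 0.5, Y = 0.5)
  szA <- data.frame(n_nodes = 1, n_edges = 0)
  szB <- data.frame(n_nodes = c(1, 1), n_edges = c(0, 0))
  p0 <- randomNullPvalue(szA, szB, freqs, observed = 0, nReps = 200,
                         seed = 57)
  expect_equal(p0$p, 1.0)
  p1 <- randomNullPvalue(szA, szB, freqs, observed = 1, nReps = 2000,
                         seed = 57)
  p2 <- randomNullPvalue(szA, szB, freqs, observed = 2, nReps = 2000,
                         seed = 57)
  expect_lte(p2$p, p1$p)
  expect_match(p2$display, "^<")       # impossible count -> "< 1/n_reps"
  expect_error(randomNullPvalue(data.frame(n_nodes = 3, n_edges = 1),
                                szB, freqs, 0, nReps = 10, seed = 1),
               "impossible")
})
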