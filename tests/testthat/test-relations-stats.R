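test_that("closed itemset mining matches worked examples", {
  got <- mineClosedItemsets(list(c("a", "b", "c"), c("a", "b"),
                                 c("a", "c")), 2)
  expect_setequal(paste(got$itemset, got$support),
                  c("a 3", "a,b 2", "a,c 2"))
  same <- mineClosedItemsets(list(c("x", "y"), c("x", "y"), c("x", "y")), 2)
  expect_equal(nrow(same), 1L)
  expect_equal(same$itemset, "x,y")
  expect_equal(nrow(mineClosedItemsets(list(c("a"), c("b")), 3)), 0L)
})

test_that("closed itemset miner equals power-set brute force", {
  set.seed(61)
  items <- letters[1:8]
  for (trial in 1:30) {
    n_tr <- sample(2:8, 1)
    transactions <- lapply(seq_len(n_tr), function(i)
      sample(items, sample(1:6, 1)))
    minsup <- sample(1:3, 1)
    got <- mineClosedItemsets(transactions, minsup)
    oracle <- bruteClosedItemsets(transactions, minsup)
    expect_setequal(paste(got$itemset, got$support),
                    paste(oracle$itemset, oracle$support))
  }
})

mkFp <- function(aa, edges, site = 1L, support = 2L,
                 occ = c("g1", "g2")) {
  g <- mkg(aa, edges)
  new("Fingerprint", pattern = g, support = as.integer(support),
      occurrences = occ[seq_len(support)], code = graphCanonicalCode(g),
      siteId = as.integer(site))
}

mkIG <- function(aa, edges, id, site, protein) {
  new("InterfaceGraph", graphId = id, siteId = as.integer(site),
      proteinId = protein, graph = mkg(aa, edges))
}

test_that("transactions list the interfaces containing each fingerprint", {
  gs <- list(mkIG(c("A", "C"), c(1, 2), "i1", 1, "p1"),
             mkIG(c("A", "C", "D"), c(1, 2, 2, 3), "i2", 1, "p2"),
             mkIG(c("W", "Y"), c(1, 2), "i3", 2, "p1"))
  fp <- mkFp(c("A", "C"), c(1, 2))
  tr <- buildTransactions(list(fp), gs)
  expect_equal(unname(tr$transactions[[1]]), c("i1", "i2"))
  fpW <- mkFp(c("W", "Y"), c(1, 2), site = 2L)
  tr2 <- buildTransactions(list(fpW), gs)
  expect_equal(unname(tr2$transactions[[1]]), "i3")
})

test_that("cooperative pairs count joint per-protein occurrences", {
  ## three proteins, two sites each; motif pair co-occurs in 2 of 3
  gs <- list(
    mkIG(c("A", "C"), c(1, 2), "p1s1", 1, "p1"),
    mkIG(c("W", "Y"), c(1, 2), "p1s2", 2, "p1"),
    mkIG(c("A", "C"), c(1, 2), "p2s1", 1, "p2"),
    mkIG(c("W", "Y"), c(1, 2), "p2s2", 2, "p2"),
    mkIG(c("A", "C"), c(1, 2), "p3s1", 1, "p3"),
    mkIG(c("G", "H"), c(1, 2), "p3s2", 2, "p3"))
  fpsBySite <- list("1" = list(mkFp(c("A", "C"), c(1, 2), 1L, 3L,
                                    c("p1s1", "p2s1", "p3s1"))),
                    "2" = list(mkFp(c("W", "Y"), c(1, 2), 2L, 2L,
                                    c("p1s2", "p2s2"))))
  cp <- cooperativePairs(fpsBySite, gs, minCoFraction = 0.2)
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$co_support, 2L)
  expect_equal(cp$co_fraction, 2 / 3, tolerance = 1e-12)
  expect_lte(cp$co_support, 2L)  # co-support bounded by min support

  ## disjoint occurrences: nothing to report
  fps0 <- list("1" = list(mkFp(c("D", "E"), c(1, 2), 1L, 1L, "p3s1")),
               "2" = list(mkFp(c("W", "Y"), c(1, 2), 2L, 2L,
                               c("p1s2", "p2s2"))))
  expect_warning(cp0 <- cooperativePairs(fps0, gs, minCoFraction = 0.2))
  expect_equal(nrow(cp0), 0L)
})

test_that("distinctive fingerprints exclude isomorphic or recurring patterns", {
  gs <- list(mkIG(c("A", "C", "W"), c(1, 2, 2, 3), "i1", 1, "p1"),
             mkIG(c("W", "Y"), c(1, 2), "i2", 2, "p1"))
  fpsBySite <- list(
    "1" = list(mkFp(c("A", "C"), c(1, 2), 1L, 1L, "i1"),   # unique
               mkFp("W", integer(), 1L, 1L, "i1")),        # occurs in site 2
    "2" = list(mkFp(c("W", "Y"), c(1, 2), 2L, 1L, "i2")))
  d1 <- distinctiveFingerprints(1L, fpsBySite, gs)
  expect_length(d1, 1L)
  expect_equal(igraph::V(patternGraph(d1[[1]]))$aa, c("A", "C"))

  ## two identical sites: nothing distinctive on either side
  gs2 <- list(mkIG(c("A", "C"), c(1, 2), "i1", 1, "p1"),
              mkIG(c("A", "C"), c(1, 2), "i2", 2, "p1"))
  fps2 <- list("1" = list(mkFp(c("A", "C"), c(1, 2), 1L, 1L, "i1")),
               "2" = list(mkFp(c("A", "C"), c(1, 2), 2L, 1L, "i2")))
  expect_length(distinctiveFingerprints(1L, fps2, gs2), 0L)
  expect_length(distinctiveFingerprints(2L, fps2, gs2), 0L)
})

test_that("function association counts shared and distinctive fingerprints", {
  gs <- list(mkIG(c("A", "C"), c(1, 2), "i1", 1, "p1"),
             mkIG(c("W", "Y"), c(1, 2), "i2", 2, "p1"),
             mkIG(c("A", "C"), c(1, 2), "i3", 3, "p2"))
  fpsBySite <- list(
    "1" = list(mkFp(c("A", "C"), c(1, 2), 1L, 1L, "i1")),
    "2" = list(mkFp(c("W", "Y"), c(1, 2), 2L, 1L, "i2")),
    "3" = list(mkFp(c("A", "C"), c(1, 2), 3L, 1L, "i3")))
  labs <- c("1" = "binding", "2" = "catalysis", "3" = "binding")
  fa <- functionAssociation(fpsBySite, labs, gs)
  bind <- fa[fa$fn_label == "binding", ]
  cat_ <- fa[fa$fn_label == "catalysis", ]
  expect_equal(bind$n_fingerprints, 2L)
  expect_equal(bind$n_shared, 0L)       # A-C shared only within "binding"
  expect_equal(cat_$n_distinctive, 1L)  # W-Y unique in topology + occurrence
  ## unlabeled sites pool under "unannotated"
  fa2 <- functionAssociation(fpsBySite, c("1" = "binding"), gs)
  expect_true("unannotated" %in% fa2$fn_label)
})

test_that("assortativity values match hand-computed oracles", {
  star <- mkg(c("A", "B", "C", "D"), c(1, 2, 1, 3, 1, 4))
  expect_equal(degreeAssortativity(star), -1)
  ## any regular graph: undefined
  square <- mkg(c("A", "B", "A", "B"), c(1, 2, 2, 3, 3, 4, 4, 1))
  expect_true(is.na(degreeAssortativity(square)))
  ## 4-node path: Pearson over the 6 directed endpoint pairs = -0.5
  path4 <- mkg(c("A", "B", "A", "B"), c(1, 2, 2, 3, 3, 4))
  expect_equal(degreeAssortativity(path4),
               stats::cor(c(1, 2, 2, 1, 2, 2), c(2, 1, 2, 2, 2, 1)))
  ## labels: all edges within classes -> 1; perfect bipartite mixing -> -1
  within <- mkg(c("A", "A", "B", "B"), c(1, 2, 3, 4))
  expect_equal(labelAssortativity(within), 1)
  expect_equal(labelAssortativity(square), -1)
  expect_true(is.na(labelAssortativity(mkg(c("A", "A"), c(1, 2)))))
  expect_error(degreeAssortativity(mkg(c("A", "B"))), "edge")
})

test_that("domain comparison t-tests behave on identical and shifted samples", {
  set.seed(62)
  ## stars have degree assortativity -1, 4-node paths -0.5
  mkset <- function(n, star_frac) lapply(seq_len(n), function(i) {
    if (i <= star_frac * n)
      mkFp(c("A", "B", "C", "D"), c(1, 2, 1, 3, 1, 4), 1L, 1L, "x")
    else mkFp(c("A", "B", "C", "D"), c(1, 2, 2, 3, 3, 4), 1L, 1L, "x")
  })
  same <- mkset(20, 0.5)
  res <- compareDomains(same, same)
  expect_equal(res$p_degree, 1.0)
  expect_equal(res$p_label, 1.0)
  shifted <- compareDomains(mkset(50, 0.1), mkset(50, 0.9))
  expect_lt(shifted$p_degree, 0.01)
})

test_that("subsample disparity is calm for identical sets, extreme for disjoint", {
  set.seed(63)
  mk_pool <- function(labels) lapply(1:60, function(i) {
    n <- sample(3:5, 1)
    g <- randomLabeledGraph(n, n - 1, labels = labels)
    while (!igraph::is_connected(g)) g <- randomLabeledGraph(n, n - 1,
                                                             labels = labels)
    mkFp(igraph::V(g)$aa,
         as.vector(t(igraph::as_edgelist(g, names = FALSE))), 1L, 1L, "x")
  })
  A <- mk_pool(c("A", "C"))
  same <- subsampleDisparity(A, A, k = 20, nReps = 100, seed = 64)
  expect_gt(same$p, 0.2)
  B <- mk_pool(c("W", "Y"))
  diff <- subsampleDisparity(A, B, k = 20, nReps = 100, seed = 64)
  expect_lt(diff$p, 0.05)
  ## reproducibility under a fixed seed
  again <- subsampleDisparity(A, B, k = 20, nReps = 100, seed = 64)
  expect_identical(diff$p, again$p)
  expect_error(subsampleDisparity(A[1:5], B, k = 20, nReps = 10, seed = 1),
               "at least k")
})

test_that("relation reports bundle all statistics for a two-site domain", {
  gs <- list(
    mkIG(c("A", "C", "D"), c(1, 2, 2, 3), "p1s1", 1, "p1"),
    mkIG(c("W", "Y", "D"), c(1, 2, 2, 3), "p1s2", 2, "p1"),
    mkIG(c("A", "C", "D"), c(1, 2, 2, 3), "p2s1", 1, "p2"),
    mkIG(c("W", "Y", "D"), c(1, 2, 2, 3), "p2s2", 2, "p2"))
  fpsBySite <- list(
    "1" = mineClosedFrequent(list(p1s1 = gs[[1]], p2s1 = gs[[3]]),
                             support = 2, siteId = 1),
    "2" = mineClosedFrequent(list(p1s2 = gs[[2]], p2s2 = gs[[4]]),
                             support = 2, siteId = 2))
  rr <- domainRelationReport(fpsBySite, gs, nReps = 50, seed = 65)
  expect_s4_class(rr, "RelationReport")
  expect_gt(nrow(rr@cooperative), 0L)
  expect_equal(rr@cooperative$co_fraction[1], 1.0)
  expect_equal(nrow(rr@isomorphism), 1L)
  expect_true(all(rr@isomorphism$p > 0 | rr@isomorphism$observed > 0))
  expect_true(all(rr@assortativity$site %in% c(1L, 2L)))
})
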