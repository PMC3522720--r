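test_that("interface detection respects the heavy-atom cutoff", {
  ## two residues at 4.9 A -> interface on both chains; 5.1 A -> none
  mk <- function(gap) {
    a <- data.frame(resno = 1:30, aa = "A", x = (1:30) * 4, y = 0, z = 0)
    b <- a
    b$y <- 4  # partner anchor so the chains pass filtering
    b$y[15] <- gap
    toyComplex(list(A = a, B = b))
  }
  near <- detectInterfaces(mk(4.9))
  hostA <- Filter(function(i) endsWith(hostChain(i), ":A"), near)[[1]]
  expect_true(15 %in% interfaceResidues(hostA)$resno)

  ## isolate the pair: move all other partner residues out of range
  a <- data.frame(resno = 1:30, aa = "A", x = (1:30) * 4, y = 0, z = 0)
  b51 <- a; b51$y <- 30; b51$y[15] <- 5.1; b51$y[16] <- 4.9
  ifs <- detectInterfaces(toyComplex(list(A = a, B = b51)))
  hostB <- Filter(function(i) endsWith(hostChain(i), ":B"), ifs)[[1]]
  expect_false(15 %in% interfaceResidues(hostB)$resno)
  expect_true(16 %in% interfaceResidues(hostB)$resno)
})

test_that("chains in different biological units never form interfaces", {
  a <- data.frame(resno = 1:30, aa = "A", x = (1:30) * 4, y = 0, z = 0)
  b <- a; b$y <- 3
  cx <- toyComplex(list(A = a, B = b), bioUnit = c(1L, 2L))
  expect_length(detectInterfaces(cx), 0L)
})

test_that("center-star MSA maps identical and gapped members consistently", {
  set.seed(31)
  s <- randomAASeq(30)
  msa <- centerStarMSA(c(a = s, b = s, c = s))
  for (m in msa$columns) expect_identical(m, 1:30)

  ## one member with a single internal deletion skips that column
  del <- paste0(substr(s, 1, 14), substr(s, 16, 30))
  msa2 <- centerStarMSA(c(a = s, b = s, d = del))
  expect_equal(msa2$width, 30L)
  expect_identical(msa2$columns[["a"]], 1:30)
  expect_identical(msa2$columns[["d"]], setdiff(1:30, 15L))
})

test_that("interface similarity and Jaccard follow the set formulas", {
  i1 <- toyInterface(c(3, 5, 9), c("A", "G", "K"))
  i2 <- toyInterface(c(3, 5, 12), c("A", "G", "R"))
  expect_equal(interfaceSimilarity(i1, i2), 2 / 3, tolerance = 1e-12)
  expect_equal(interfaceSimilarity(i1, i1), 1.0)
  expect_equal(interfaceSimilarity(i1, i2), interfaceSimilarity(i2, i1))

  ## same column, different residue type -> no identity
  j1 <- toyInterface(3, "A"); j2 <- toyInterface(3, "V")
  expect_equal(interfaceSimilarity(j1, j2), 0.0)

  k1 <- toyInterface(1:3, c("A", "A", "A"))
  k2 <- toyInterface(3:5, c("A", "A", "A"))
  expect_equal(jaccardOverlap(k1, k2), 0.2)
  expect_equal(jaccardOverlap(k1, k1), 1.0)
  expect_equal(jaccardOverlap(toyInterface(1:2, c("A", "C")),
                              toyInterface(3:4, c("A", "C"))), 0.0)
})

test_that("dedup keeps the best-resolution representative, ties to input order", {
  msa <- structure(list(clusterId = 1L, center = "E1:1:A", width = 20,
                        columns = list()), class = "MsaMap")
  mk <- function(res, entry) toyInterface(1:5, rep("A", 5),
                                          host = paste0(entry, ":1:A"),
                                          entry = entry, resolution = res)
  reps <- dedupInterfaces(list(mk(2.0, "E1"), mk(1.5, "E2"), mk(2.5, "E3")),
                          msa, threshold = 0.8)
  expect_length(reps, 1L)
  expect_equal(reps[[1]]@resolution, 1.5)

  tie <- dedupInterfaces(list(mk(1.8, "E4"), mk(1.8, "E5")), msa)
  expect_length(tie, 1L)
  expect_equal(tie[[1]]@entryId, "E4")

  ## disjoint interfaces are both kept, and dedup never grows the set
  d1 <- mk(2.0, "E6")
  d2 <- toyInterface(11:15, rep("G", 5), host = "E6:1:A", entry = "E6",
                     resolution = 2.0)
  both <- dedupInterfaces(list(d1, d2), msa)
  expect_length(both, 2L)
})

test_that("binding-site clustering separates disjoint and merges similar sites", {
  r1 <- toyInterface(1:10, rep("A", 10))
  r2 <- toyInterface(2:10, rep("A", 9))    # shares 90% of columns
  r3 <- toyInterface(21:30, rep("G", 10))
  sites <- clusterBindingSites(list(r1, r2, r3), siteThreshold = 0.5)
  expect_equal(siteId(sites[[1]]), siteId(sites[[2]]))
  expect_false(siteId(sites[[1]]) == siteId(sites[[3]]))
})

test_that("planted binding sites are recovered on a synthetic cluster", {
  ## three disjoint planted sites on the hub chain
  plan <- list(
    list(host = "A", partner = "B", host_range = 4:9,   partner_range = 4:9),
    list(host = "A", partner = "C", host_range = 16:21, partner_range = 16:21),
    list(host = "A", partner = "D", host_range = 30:35, partner_range = 30:35))
  co <- generateClusterCohort(complexSpec(nChains = 4, chainLength = 40,
                                          interfacePlan = plan, seed = 33),
                              nCopies = 3, seed = 34)
  seqs <- unlist(lapply(co$complexes, chainSequences))
  names(seqs) <- unlist(lapply(co$complexes,
                               function(x) names(chainSequences(x))))
  cl <- buildChainClusters(seqs)
  allif <- unlist(lapply(co$complexes, detectInterfaces), recursive = FALSE)
  cluA <- cl$clusters$cluster_id[grep(":A$", cl$clusters$chain)[1]]
  members <- cl$clusters$chain[cl$clusters$cluster_id == cluA]
  msa <- centerStarMSA(seqs[members], clusterId = cluA)
  ia <- mapInterfaces(Filter(function(i) hostChain(i) %in% members, allif),
                      msa)
  reps <- dedupInterfaces(ia, msa, complexes = co$complexes)
  reps <- clusterBindingSites(reps)
  expect_equal(length(unique(vapply(reps, siteId, 0L))), 3L)
  expect_true(all(vapply(reps, function(r) r@entryId, "") ==
                    co$truth$best_entry))
})

test_that("interaction classification combines cluster identity and permanence", {
  clusters <- data.frame(cluster_id = c(1L, 1L, 2L),
                         chain = c("E1:1:A", "E1:1:B", "E1:1:C"))
  perm <- data.frame(chain_a = c("E1:1:A", "E1:1:A"),
                     chain_b = c("E1:1:B", "E1:1:C"),
                     permanence = c("permanent", "transient"))
  homo <- toyInterface(1:3, rep("A", 3), host = "E1:1:A",
                       partner = "E1:1:B")
  het <- toyInterface(1:3, rep("A", 3), host = "E1:1:A",
                      partner = "E1:1:C")
  expect_equal(classifyInteraction(homo, clusters, perm), "homo-oligomer")
  expect_equal(classifyInteraction(het, clusters, perm), "hetero-complex")
  noflag <- toyInterface(1:3, rep("A", 3), host = "E1:1:B",
                         partner = "E1:1:C")
  expect_equal(classifyInteraction(noflag, clusters, perm), "unknown")
})

test_that("domain assignment tags single, cross-domain and unassigned interfaces", {
  doms <- data.frame(domain_id = c("A", "B"), start = c(1, 51),
                     end = c(50, 100))
  expect_equal(assignDomains(toyInterface(10:20, rep("A", 11)), doms), "A")
  expect_setequal(assignDomains(toyInterface(40:60, rep("A", 21)), doms),
                  c("A", "B"))
  expect_equal(assignDomains(toyInterface(120, "A"), doms), "unassigned")
})

test_that("aggregation histograms multi-interface proteins only", {
  proteins <- data.frame(protein_id = c("p1", "p2", "p3", "p4"),
                         n_sites = c(2L, 2L, 3L, 1L))
  agg <- aggregateCounts(proteins)
  expect_equal(agg$histogram,
               data.frame(n_interfaces = c(2L, 3L), n_proteins = c(2L, 1L)))
})
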