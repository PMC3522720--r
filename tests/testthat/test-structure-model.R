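test_that("parser reads bio-unit membership and transform flags", {
  g <- generateComplex(complexSpec(seed = 2))
  pdb <- tempfile(fileext = ".pdb")
  writeComplexPDB(g$complex, pdb)
  cx <- readComplex(pdb)
  expect_true(all(chains(cx)$transform_identity))
  expect_equal(sort(unique(chains(cx)$bio_unit)), 1L)

  ## a chain under a rotation BIOMT is flagged non-identity
  cx2 <- g$complex
  cx2@chains$transform_identity[cx2@chains$chain_id == "B"] <- FALSE
  pdb2 <- tempfile(fileext = ".pdb")
  writeComplexPDB(cx2, pdb2)
  re <- readComplex(pdb2)
  flags <- setNames(chains(re)$transform_identity, chains(re)$chain_id)
  expect_false(flags[["B"]])
  expect_true(flags[["A"]])
})

test_that("nucleic-acid-only files raise an empty-complex error", {
  pdb <- tempfile(fileext = ".pdb")
  lines <- c("HEADER    DNA", "EXPDTA    X-RAY DIFFRACTION",
             "REMARK   2 RESOLUTION.    2.00 ANGSTROMS.",
             vapply(1:35, function(i) sprintf(
               "ATOM  %5d  P    DA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           P",
               i, i, i * 4.0, 0, 0), ""),
             "END")
  writeLines(lines, pdb)
  expect_error(readComplex(pdb), "no protein chains")
})

test_that("altloc conformers collapse to the highest occupancy", {
  pdb <- tempfile(fileext = ".pdb")
  atom <- function(serial, name, alt, resno, x, occ)
    sprintf("ATOM  %5d  %-3s%1sALA A%4d    %8.3f%8.3f%8.3f%6.2f  0.00           C",
            serial, name, alt, resno, x, 0, 0, occ)
  lines <- c("EXPDTA    X-RAY DIFFRACTION",
             "REMARK   2 RESOLUTION.    2.00 ANGSTROMS.",
             atom(1, "CA", "A", 1, 1.0, 0.4),
             atom(2, "CA", "B", 1, 2.0, 0.6),
             vapply(2:31, function(i) atom(i + 1, "CA", " ", i, i * 4.0, 1.0), ""),
             "END")
  writeLines(lines, pdb)
  cx <- readComplex(pdb)
  a1 <- atoms(cx)
  ca1 <- a1[a1$resno == 1 & a1$name == "CA", ]
  expect_equal(nrow(ca1), 1L)
  expect_equal(ca1$x, 2.0)  # the 0.6-occupancy conformer
})

test_that("filtering drops entries and chains per the retrieval rules", {
  g <- generateComplex(complexSpec(seed = 4))
  good <- g$complex

  lowres <- good; lowres@resolution <- 3.2; lowres@entryId <- "LOWR"
  nmr <- good; nmr@method <- "SOLUTION NMR"; nmr@entryId <- "NMR1"

  ## a 29-residue chain: truncate chain C
  short <- good
  keep <- !(short@atoms$chain_id == "C" & short@atoms$resno > 29)
  short@atoms <- short@atoms[keep, , drop = FALSE]
  rt <- unique(short@atoms[short@atoms$chain_id == "C",
                           c("resno", "icode", "aa")])
  short@chains$length[short@chains$chain_id == "C"] <- nrow(rt)
  short@chains$sequence[short@chains$chain_id == "C"] <-
    paste(rt$aa[order(rt$resno)], collapse = "")
  short@entryId <- "SHRT"

  fl <- filterComplexes(list(good, lowres, nmr, short))
  expect_equal(length(fl$kept), 2L)
  expect_setequal(vapply(fl$kept, entryId, ""), c("SYN001", "SHRT"))
  reasons <- fl$manifest$drop_reason[!fl$manifest$kept]
  expect_true("resolution" %in% reasons)
  expect_true("not_xray" %in% reasons)
  expect_true("short_chain" %in% reasons)
  ## C was short; it was also A's only partner on that range, but A-B remains
  shrt <- fl$kept[[which(vapply(fl$kept, entryId, "") == "SHRT")]]
  expect_setequal(chains(shrt)$chain_id, c("A", "B"))
})

test_that("a bio-unit reduced below two chains is dropped entirely", {
  ## two chains, one of them non-identity -> unit dies
  far <- data.frame(resno = 1:30, aa = "A", x = (1:30) * 4, y = 0, z = 0)
  near <- far; near$y <- 4
  cx <- toyComplex(list(A = far, B = near),
                   transformIdentity = c(TRUE, FALSE))
  fl <- filterComplexes(list(cx))
  expect_equal(length(fl$kept), 0L)
  expect_true(all(c("non_identity_transform", "bio_unit_too_small") %in%
                    fl$manifest$drop_reason))
})

test_that("chains with no partner within the cutoff are removed", {
  a <- data.frame(resno = 1:30, aa = "A", x = (1:30) * 4, y = 0, z = 0)
  b <- a; b$y <- 4          # touches A
  c <- a; c$y <- 100        # touches nothing
  cx <- toyComplex(list(A = a, B = b, C = c))
  fl <- filterComplexes(list(cx))
  expect_equal(length(fl$kept), 1L)
  expect_setequal(chains(fl$kept[[1]])$chain_id, c("A", "B"))
  expect_equal(fl$manifest$drop_reason[fl$manifest$chain_id == "C"],
               "no_partner")
})

test_that("filtering is idempotent and survivors meet all invariants", {
  g1 <- generateComplex(complexSpec(seed = 5))
  g2 <- generateComplex(complexSpec(nChains = 2, seed = 6,
                                    entryId = "SYN002"))
  fl1 <- filterComplexes(list(g1$complex, g2$complex))
  fl2 <- filterComplexes(fl1$kept)
  expect_equal(length(fl2$kept), length(fl1$kept))
  for (k in seq_along(fl1$kept))
    expect_equal(chains(fl2$kept[[k]]), chains(fl1$kept[[k]]))
  for (cx in fl1$kept) {
    ch <- chains(cx)
    expect_true(all(ch$length >= 30))
    expect_true(all(ch$transform_identity))
    expect_true(all(table(ch$bio_unit) >= 2))
  }
})

test_that("PDB round trip preserves chains, residue counts and coordinates", {
  g <- generateComplex(complexSpec(seed = 7))
  fl <- filterComplexes(list(g$complex))
  cx <- fl$kept[[1]]
  pdb <- tempfile(fileext = ".pdb")
  writeComplexPDB(cx, pdb)
  re <- readComplex(pdb)
  expect_identical(chains(re)$chain_id, chains(cx)$chain_id)
  expect_identical(chains(re)$length, chains(cx)$length)
  expect_identical(chains(re)$sequence, chains(cx)$sequence)
  expect_lt(max(abs(as.matrix(atoms(re)[, c("x", "y", "z")]) -
                    as.matrix(atoms(cx)[, c("x", "y", "z")]))), 1e-3)
})
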