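## Synthetic multi-chain complexes, chain-cluster cohorts and labeled
## graph databases with planted motifs.
##
## Geometry is deliberately cartoon-like: chains are laid out as
## piecewise-linear C-alpha traces (3.8 A steps) with one pseudo-side-chain
## atom (CB) per residue, on well-separated lanes; planned interface
## segments are routed to 4.2 A of their partner segment while every
## unplanned inter-chain residue pair stays beyond the 5 A contact cutoff.
## Only distance relationships are consumed downstream.

#' Specification of a synthetic complex
#'
#' @param nChains number of chains (named A, B, C, ...)
#' @param chainLength residues per chain
#' @param interfacePlan list of planned contacts, each
#'   \code{list(host=, partner=, host_range=, partner_range=)} with ranges
#'   of equal length inside the chain; default: chain A touching B and C
#'   on disjoint ranges (a two-site hub)
#' @param mutationRate per-chain substitution rate in [0, 0.1] applied by
#'   \code{\link{generateClusterCohort}}
#' @param resolution X-ray resolution stamped on the entry
#' @param seed RNG seed (sequences and cohort mutations)
#' @param entryId entry identifier
#' @return a \code{ComplexSpec} list
#' @export
complexSpec <- function(nChains = 3L, chainLength = 40L,
                        interfacePlan = NULL, mutationRate = 0.02,
                        resolution = 2.0, seed = 1L, entryId = "SYN001") {
  stopifnot(nChains >= 1L, chainLength >= 5L,
            mutationRate >= 0, mutationRate <= 0.1)
  if (is.null(interfacePlan)) {
    interfacePlan <- list()
    if (nChains >= 2L)
      interfacePlan <- c(interfacePlan, list(list(
        host = "A", partner = "B",
        host_range = 6:13, partner_range = 6:13)))
    if (nChains >= 3L)
      interfacePlan <- c(interfacePlan, list(list(
        host = "A", partner = "C",
        host_range = 24:31, partner_range = 24:31)))
  }
  for (p in interfacePlan) {
    stopifnot(length(p$host_range) == length(p$partner_range),
              max(p$host_range) <= chainLength,
              max(p$partner_range) <= chainLength)
  }
  structure(list(nChains = as.integer(nChains),
                 chainLength = as.integer(chainLength),
                 interfacePlan = interfacePlan,
                 mutationRate = mutationRate, resolution = resolution,
                 seed = as.integer(seed), entryId = entryId),
            class = "ComplexSpec")
}

## lane layout: host chain A runs along x at the origin; every other chain
## sits on its own distant lane; planned partner segments are routed next
## to their host segment.
syntheticCoords <- function(spec) {
  n <- spec$nChains
  L <- spec$chainLength
  ids <- LETTERS[seq_len(n)]
  step <- 3.8
  ca <- array(NA_real_, c(n, L, 3))
  for (c in seq_len(n)) {
    lane_y <- if (c == 1L) 0 else 20 * (if (c %% 2 == 0) 1 else -1)
    lane_z <- if (c == 1L) 0 else 20 * (c - 1)
    for (i in seq_len(L)) ca[c, i, ] <- c(step * i, lane_y, lane_z)
  }
  sgn <- 1
  for (k in seq_along(spec$interfacePlan)) {
    p <- spec$interfacePlan[[k]]
    hc <- match(p$host, ids); pc <- match(p$partner, ids)
    stopifnot(!is.na(hc), !is.na(pc), hc != pc)
    sgn <- if (k %% 2 == 1) 1 else -1
    for (j in seq_along(p$host_range)) {
      hi <- p$host_range[j]; pi <- p$partner_range[j]
      ca[pc, pi, ] <- ca[hc, hi, ] + c(0, sgn * 4.2, 0)
    }
  }
  ## CB offsets point away from the contact plane
  cb <- ca
  cb[, , 3] <- cb[, , 3] + 1.5
  list(ids = ids, ca = ca, cb = cb)
}

randomSequences <- function(spec) {
  ids <- LETTERS[seq_len(spec$nChains)]
  seqs <- vapply(seq_len(spec$nChains), function(c)
    paste(sample(AA20, spec$chainLength, replace = TRUE), collapse = ""),
    "")
  setNames(seqs, ids)
}

buildSyntheticComplex <- function(spec, sequences, resolution = NULL,
                                  entryId = NULL) {
  geo <- syntheticCoords(spec)
  L <- spec$chainLength
  rows <- list(); serial <- 0L
  for (c in seq_len(spec$nChains)) {
    aa <- strsplit(sequences[[geo$ids[c]]], "")[[1]]
    for (i in seq_len(L)) {
      for (atom in c("CA", "CB")) {
        serial <- serial + 1L
        xyz <- if (atom == "CA") geo$ca[c, i, ] else geo$cb[c, i, ]
        rows[[serial]] <- data.frame(
          serial = serial, name = atom, element = "C",
          resid = bio3d::aa123(aa[i]), chain_id = geo$ids[c], resno = i,
          icode = "", aa = aa[i], x = xyz[1], y = xyz[2], z = xyz[3],
          is_hydrogen = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  atoms <- do.call(rbind, rows)
  ## self/cross clash check (>= 3 A everywhere except planned contacts)
  co <- as.matrix(atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(co^2), rowSums(co^2), "+") - 2 * tcrossprod(co)
  same_res <- outer(paste(atoms$chain_id, atoms$resno),
                    paste(atoms$chain_id, atoms$resno), "==")
  if (any(d2[!same_res] < 3^2 - 1e-9))
    stop("infeasible geometry: steric clash in synthetic layout")
  chains <- data.frame(
    chain_id = geo$ids, bio_unit = 1L, transform_identity = TRUE,
    length = L,
    sequence = unname(sequences[geo$ids]), stringsAsFactors = FALSE)
  new("ComplexRecord",
      entryId = if (is.null(entryId)) spec$entryId else entryId,
      method = "X-RAY DIFFRACTION",
      resolution = if (is.null(resolution)) spec$resolution else resolution,
      atoms = atoms, chains = chains)
}

#' Generate a synthetic multi-chain complex
#'
#' Builds the complex described by the spec with fresh random sequences
#' (seeded), optionally writing it as PDB text. The returned ground truth
#' lists the planted interface residue ranges per (host, partner) pair.
#'
#' @param spec a \code{\link{complexSpec}}
#' @param pdbFile optional path; when given the structure is written there
#' @return list with \code{complex} (a
#'   \code{\linkS4class{ComplexRecord}}), \code{sequences} and
#'   \code{truth} (planted interfaces)
#' @export
generateComplex <- function(spec, pdbFile = NULL) {
  stopifnot(inherits(spec, "ComplexSpec"))
  sequences <- withSeed(spec$seed, randomSequences(spec))
  cx <- buildSyntheticComplex(spec, sequences)
  truth <- list(interfaces = lapply(spec$interfacePlan, function(p)
    list(host = p$host, partner = p$partner,
         host_residues = p$host_range, partner_residues = p$partner_range)))
  if (!is.null(pdbFile)) writeComplexPDB(cx, pdbFile)
  list(complex = cx, sequences = sequences, truth = truth)
}

mutateSequence <- function(seq, nMut) {
  if (nMut < 1L) return(seq)
  aa <- strsplit(seq, "")[[1]]
  L <- length(aa)
  interior <- 3:(L - 2L)   # keep ends intact so local alignment spans all
  pos <- sample(interior, min(nMut, length(interior)))
  for (p in pos) aa[p] <- sample(setdiff(AA20, aa[p]), 1L)
  paste(aa, collapse = "")
}

#' Generate a cohort of near-identical complexes
#'
#' Copies of a base complex with per-chain point substitutions (exactly
#' \code{round(mutationRate * chainLength)} interior substitutions per
#' chain per copy; the first copy stays unmutated) and shuffled distinct
#' resolutions. Emulates the same protein crystallised in many entries:
#' each chain's copies form one planted sequence cluster and the planted
#' representative is the entry with the best resolution.
#'
#' @param baseSpec a \code{\link{complexSpec}}
#' @param nCopies number of entries (>= 2)
#' @param mutationRate per-chain substitution rate (default from spec)
#' @param seed RNG seed
#' @return list with \code{complexes} (named by entry id),
#'   \code{sequences}, and \code{truth} (planted clusters, per-entry
#'   resolutions, best entry, planted interfaces)
#' @export
generateClusterCohort <- function(baseSpec, nCopies = 5L,
                                  mutationRate = NULL, seed = 42L) {
  stopifnot(inherits(baseSpec, "ComplexSpec"), nCopies >= 2L)
  if (is.null(mutationRate)) mutationRate <- baseSpec$mutationRate
  base_seqs <- withSeed(baseSpec$seed, randomSequences(baseSpec))
  nMut <- round(mutationRate * baseSpec$chainLength)
  withSeed(seed, {
    resolutions <- sample(seq(1.5, by = 0.05, length.out = nCopies))
    entries <- sprintf("SY%03d", seq_len(nCopies))
    complexes <- list(); all_seqs <- list()
    for (i in seq_len(nCopies)) {
      seqs <- if (i == 1L) base_seqs else
        vapply(base_seqs, mutateSequence, "", nMut = nMut)
      cx <- buildSyntheticComplex(baseSpec, seqs,
                                  resolution = resolutions[i],
                                  entryId = entries[i])
      complexes[[entries[i]]] <- cx
      all_seqs[[entries[i]]] <- seqs
    }
    clusters <- lapply(names(base_seqs), function(cid)
      chainKey(entries, 1L, cid))
    names(clusters) <- names(base_seqs)
    list(complexes = complexes, sequences = all_seqs,
         truth = list(clusters = clusters, resolutions =
                        setNames(resolutions, entries),
                      best_entry = entries[which.min(resolutions)],
                      interfaces = lapply(baseSpec$interfacePlan,
                                          function(p) p)))
  })
}

#' Specification of a synthetic labeled graph database
#'
#' @param nGraphs database size
#' @param nodesRange two integers: min/max background graph order
#' @param plantedMotifs list of \code{list(pattern=, frequency=)} where
#'   \code{pattern} is an igraph with vertex attribute \code{aa} and
#'   \code{frequency} the fraction of graphs receiving an embedded copy
#' @param labelFreqs amino-acid label frequencies (default uniform over
#'   the 20-letter alphabet)
#' @param edgeFactor background edge count = round(edgeFactor * (n - 1))
#' @param seed RNG seed
#' @return a \code{GraphDBSpec} list
#' @export
graphDBSpec <- function(nGraphs = 10L, nodesRange = c(8L, 12L),
                        plantedMotifs = list(),
                        labelFreqs = setNames(rep(1 / 20, 20), AA20),
                        edgeFactor = 1.2, seed = 1L) {
  stopifnot(nGraphs >= 1L, all(labelFreqs > 0))
  for (m in plantedMotifs)
    stopifnot(igraph::vcount(m$pattern) <= nodesRange[1],
              m$frequency > 0, m$frequency <= 1)
  structure(list(nGraphs = as.integer(nGraphs),
                 nodesRange = as.integer(nodesRange),
                 plantedMotifs = plantedMotifs, labelFreqs = labelFreqs,
                 edgeFactor = edgeFactor, seed = as.integer(seed)),
            class = "GraphDBSpec")
}

#' Generate a labeled graph database with planted motifs
#'
#' Random connected background graphs; each planted motif is embedded
#' (disjoint node set, attached by one bridge edge) into
#' \code{round(frequency * nGraphs)} graphs chosen at random. The ground
#' truth records the receiving graphs per motif.
#'
#' @param spec a \code{\link{graphDBSpec}}
#' @return list with \code{db} (named list of igraphs) and \code{truth}
#' @export
generateGraphDB <- function(spec) {
  stopifnot(inherits(spec, "GraphDBSpec"))
  withSeed(spec$seed, {
    n <- spec$nGraphs
    db <- vector("list", n)
    for (g in seq_len(n)) {
      nv <- sample(spec$nodesRange[1]:spec$nodesRange[2], 1L)
      ne <- min(round(spec$edgeFactor * (nv - 1L)), nv * (nv - 1L) / 2)
      db[[g]] <- randomConnectedGraph(nv, ne, spec$labelFreqs)
    }
    truth <- list()
    for (mi in seq_along(spec$plantedMotifs)) {
      m <- spec$plantedMotifs[[mi]]
      k <- round(m$frequency * n)
      into <- sort(sample.int(n, k))
      for (g in into) {
        host <- db[[g]]
        off <- igraph::vcount(host)
        mg <- m$pattern
        host <- igraph::add_vertices(host, igraph::vcount(mg),
                                     aa = igraph::V(mg)$aa)
        mel <- igraph::as_edgelist(mg, names = FALSE)
        if (nrow(mel)) host <- igraph::add_edges(host, t(mel + off))
        bridge <- c(sample.int(off, 1L), off + 1L)
        host <- igraph::add_edges(host, bridge)
        db[[g]] <- host
      }
      truth[[mi]] <- list(graphs = into, planted_support = length(into))
    }
    names(db) <- sprintf("g%03d", seq_len(n))
    list(db = db, truth = truth)
  })
}
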