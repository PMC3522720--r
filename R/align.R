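## Near-identical chain clustering by local sequence alignment.

#' Local pairwise chain alignment
#'
#' Smith-Waterman local alignment (BLOSUM62, gap open 11 / extend 1, the
#' classic protein-search defaults). Sequence similarity is the number of
#' identical aligned residue pairs divided by the alignment length, i.e.
#' computed over the aligned region only, not the full sequence length, so
#' a domain shared by a longer multi-domain chain still scores 1.0.
#'
#' @param seqA,seqB amino-acid strings (length >= 1)
#' @param gapOpening,gapExtension gap penalties (positive)
#' @return a \code{PairAlignment}: list with \code{n_identical},
#'   \code{align_len}, \code{similarity}, \code{score} and
#'   \code{column_map} (data.frame of aligned positions \code{pos_a},
#'   \code{pos_b})
#' @examples
#' alignChainPair("ACDEFGHIKL", "ACDEFGHIKL")$similarity  # 1
#' @export
alignChainPair <- function(seqA, seqB, gapOpening = 11, gapExtension = 1) {
  if (!nzchar(seqA) || !nzchar(seqB)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(seqA, seqB, type = "local",
                                       substitutionMatrix = blosum62(),
                                       gapOpening = gapOpening,
                                       gapExtension = gapExtension)
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  pos_a <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  pos_b <- Biostrings::start(Biostrings::subject(aln)) - 1L
  map_a <- integer(0); map_b <- integer(0); n_id <- 0L
  for (k in seq_along(pa)) {
    ga <- pa[k] == "-"; gb <- sa[k] == "-"
    if (!ga) pos_a <- pos_a + 1L
    if (!gb) pos_b <- pos_b + 1L
    if (!ga && !gb) {
      map_a <- c(map_a, pos_a); map_b <- c(map_b, pos_b)
      if (pa[k] == sa[k]) n_id <- n_id + 1L
    }
  }
  align_len <- length(pa)
  structure(list(n_identical = n_id, align_len = align_len,
                 similarity = if (align_len) n_id / align_len else 0,
                 score = Biostrings::score(aln),
                 column_map = data.frame(pos_a = map_a, pos_b = map_b)),
            class = "PairAlignment")
}

#' Cluster chains by sequence similarity
#'
#' All-vs-all local alignment; chain pairs with similarity at or above
#' \code{minSimilarity} (default 0.975, i.e. mutation rate <= 2.5 percent
#' over the aligned region) and raw score at least \code{minScore} become
#' edges of a similarity graph, whose connected components (single linkage)
#' are the chain clusters. Singletons are emitted as size-1 clusters.
#'
#' Because single linkage can chain through intermediates, the per-cluster
#' minimum pairwise similarity is reported as a diagnostic rather than
#' enforced.
#'
#' @param sequences named character vector of chain sequences (names are
#'   chain instance keys)
#' @param minSimilarity similarity threshold for an edge (default 0.975)
#' @param minScore raw alignment score floor skipping junk pairs
#'   (default 40)
#' @return list with \code{clusters} (data.frame \code{cluster_id},
#'   \code{chain}), \code{edges} (data.frame of similar pairs) and
#'   \code{diagnostics} (per-cluster size and minimum pairwise similarity)
#' @export
buildChainClusters <- function(sequences, minSimilarity = 0.975,
                               minScore = 40) {
  stopifnot(length(sequences) >= 1L, !is.null(names(sequences)))
  chains_v <- names(sequences)
  uniq <- unique(unname(sequences))
  ui <- match(sequences, uniq)
  nu <- length(uniq)
  ## pairwise similarity between unique sequences
  sim_u <- diag(1, nu); score_u <- matrix(Inf, nu, nu)
  if (nu > 1L) {
    for (i in 1:(nu - 1L)) for (j in (i + 1L):nu) {
      pa <- alignChainPair(uniq[i], uniq[j])
      sim_u[i, j] <- sim_u[j, i] <- pa$similarity
      score_u[i, j] <- score_u[j, i] <- pa$score
    }
  }
  n <- length(chains_v)
  ea <- integer(0); eb <- integer(0); es <- numeric(0)
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      s <- sim_u[ui[i], ui[j]]
      sc <- score_u[ui[i], ui[j]]
      if (s >= minSimilarity && sc >= minScore) {
        ea <- c(ea, i); eb <- c(eb, j); es <- c(es, s)
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(ea, eb))
  comp <- igraph::components(g)$membership
  ## stable cluster ids in order of first appearance
  cl_id <- match(comp, unique(comp))
  clusters <- data.frame(cluster_id = cl_id, chain = chains_v,
                         stringsAsFactors = FALSE)
  edges <- data.frame(chain_a = chains_v[ea], chain_b = chains_v[eb],
                      similarity = es, stringsAsFactors = FALSE)
  diag_rows <- lapply(sort(unique(cl_id)), function(cl) {
    memb <- which(cl_id == cl)
    ms <- if (length(memb) > 1L)
      min(sim_u[unique(ui[memb]), unique(ui[memb])]) else NA_real_
    data.frame(cluster_id = cl, size = length(memb), min_similarity = ms)
  })
  list(clusters = clusters, edges = edges,
       diagnostics = do.call(rbind, diag_rows))
}

#' Write chain sequences as FASTA
#'
#' @param sequences named character vector of sequences
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeChainFasta <- function(sequences, path) {
  out <- as.vector(rbind(paste0(">", names(sequences)), unname(sequences)))
  writeLines(out, path)
  invisible(path)
}

#' Read chain sequences from FASTA
#'
#' @param path FASTA file
#' @return named character vector
#' @export
readChainFasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}
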