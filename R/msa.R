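## Center-star multiple sequence alignment for one chain cluster.
##
## Cluster members are >= 97.5% identical by construction, so a center-star
## alignment (all members aligned pairwise to the center sequence, gap runs
## merged with the "once a gap, always a gap" rule) recovers the common
## column coordinates reliably.

globalAlign <- function(a, b) {
  Biostrings::pairwiseAlignment(a, b, type = "global",
                                substitutionMatrix = blosum62(),
                                gapOpening = 11, gapExtension = 1)
}

## gap structure of one center-vs-member alignment:
## center slots 0..Lc (0 = before the first center residue); returns
## gaps[slot+1] = run length, and the member-position mapping
alnGapStructure <- function(aln) {
  ca <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  ma <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  ci <- 0L
  gaps <- integer(sum(ca != "-") + 1L)
  run <- 0L
  m_slot <- integer(0); m_rank <- integer(0); m_center <- integer(0)
  for (k in seq_along(ca)) {
    if (ca[k] == "-") {
      run <- run + 1L
      if (ma[k] != "-") {
        m_slot <- c(m_slot, ci); m_rank <- c(m_rank, run)
        m_center <- c(m_center, NA_integer_)
      }
    } else {
      gaps[ci + 1L] <- run   # run that just ended sits in slot ci
      run <- 0L
      ci <- ci + 1L
      if (ma[k] != "-") {
        m_slot <- c(m_slot, NA_integer_); m_rank <- c(m_rank, NA_integer_)
        m_center <- c(m_center, ci)
      }
    }
  }
  gaps[ci + 1L] <- run
  list(gaps = gaps, m_slot = m_slot, m_rank = m_rank, m_center = m_center)
}

#' Center-star multiple alignment of a chain cluster
#'
#' Chooses the center as the member sequence minimising the summed
#' alignment distance (1 - similarity) to all members, ties broken by
#' longest sequence then lexicographically smallest chain key; aligns every
#' member to the center globally and merges the gap runs (member insertions
#' are right-aligned within each merged run). Identical sequences receive
#' identical column maps.
#'
#' @param sequences named character vector (chain keys -> sequences)
#' @param clusterId integer id recorded in the result
#' @return an \code{MsaMap}: list with \code{clusterId}, \code{center},
#'   \code{width} and \code{columns}, a named list mapping each chain's
#'   residue index (1..length) to its alignment column
#' @export
centerStarMSA <- function(sequences, clusterId = NA_integer_) {
  stopifnot(length(sequences) >= 1L, !is.null(names(sequences)))
  uniq <- unique(unname(sequences))
  ui <- match(sequences, uniq)
  nu <- length(uniq)
  if (nu == 1L) {
    L <- nchar(uniq)
    cols <- lapply(seq_along(sequences), function(i) seq_len(L))
    names(cols) <- names(sequences)
    return(structure(list(clusterId = clusterId, center = names(sequences)[1],
                          width = L, columns = cols), class = "MsaMap"))
  }
  ## center selection over unique sequences, weighted by multiplicity
  mult <- tabulate(ui, nu)
  dist_u <- matrix(0, nu, nu)
  for (i in 1:(nu - 1L)) for (j in (i + 1L):nu) {
    pa <- alignChainPair(uniq[i], uniq[j])
    dist_u[i, j] <- dist_u[j, i] <- 1 - pa$similarity
  }
  tot <- as.vector(dist_u %*% mult)
  first_key <- vapply(seq_len(nu),
                      function(u) min(names(sequences)[ui == u]), "")
  ord <- order(tot, -nchar(uniq), first_key)
  ci <- ord[1]
  center_seq <- uniq[ci]
  Lc <- nchar(center_seq)
  gs <- vector("list", nu)
  master <- integer(Lc + 1L)
  for (u in seq_len(nu)) {
    if (u == ci) next
    gs[[u]] <- alnGapStructure(globalAlign(center_seq, uniq[u]))
    master <- pmax(master, gs[[u]]$gaps)
  }
  ## columns: slot 0 gaps occupy 1..master[1]; center residue i occupies
  ## sum(master[1..i]) + i
  center_col <- cumsum(master[seq_len(Lc)]) + seq_len(Lc)
  width <- Lc + sum(master)
  colmap_u <- vector("list", nu)
  colmap_u[[ci]] <- center_col
  for (u in seq_len(nu)) {
    if (u == ci) next
    g <- gs[[u]]
    L <- nchar(uniq[u])
    cols <- integer(L)
    for (m in seq_len(L)) {
      if (!is.na(g$m_center[m])) {
        cols[m] <- center_col[g$m_center[m]]
      } else {
        s <- g$m_slot[m]          # insertion after center residue s
        r <- g$gaps[s + 1L]       # member run length in this slot
        base <- if (s == 0L) 0L else center_col[s]
        cols[m] <- base + (master[s + 1L] - r) + g$m_rank[m]
      }
    }
    if (anyDuplicated(cols) || any(diff(cols) <= 0))
      stop("internal error: non-monotone column map in center-star MSA")
    colmap_u[[u]] <- cols
  }
  cols <- lapply(seq_along(sequences), function(i) colmap_u[[ui[i]]])
  names(cols) <- names(sequences)
  structure(list(clusterId = clusterId,
                 center = names(sequences)[which(ui == ci)[1]],
                 width = width, columns = cols), class = "MsaMap")
}

#' @export
print.MsaMap <- function(x, ...) {
  cat("MsaMap (cluster ", x$clusterId, "): ", length(x$columns),
      " chains, width ", x$width, ", center ", x$center, "\n", sep = "")
  invisible(x)
}

#' Map interface residues onto alignment columns
#'
#' Rewrites each interface's residue table with the alignment column of its
#' host chain, so that interfaces from differently numbered entries become
#' comparable, and stamps the cluster id.
#'
#' @param interfaces list of \code{\linkS4class{InterfaceInstance}}
#' @param msa an \code{MsaMap} covering all host chains
#' @return the interfaces with \code{msa_column} filled in
#' @export
mapInterfaces <- function(interfaces, msa) {
  lapply(interfaces, function(i) {
    cm <- msa$columns[[i@hostChain]]
    if (is.null(cm)) stop("host chain not in MSA: ", i@hostChain)
    r <- i@residues
    if (any(r$seq_pos > length(cm)))
      stop("residue index outside chain for ", i@hostChain)
    r$msa_column <- cm[r$seq_pos]
    i@residues <- r
    i@clusterId <- as.integer(msa$clusterId)
    i
  })
}
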