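## Retrieval/preprocessing filters applied to parsed structures.

minPairDist2 <- function(a, b) {
  ## squared minimum distance between two coordinate matrices (n x 3)
  if (!nrow(a) || !nrow(b)) return(Inf)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  max(min(d2), 0)
}

chainHeavyCoords <- function(complex, chain_id) {
  at <- complex@atoms
  sel <- at$chain_id == chain_id & !at$is_hydrogen
  as.matrix(at[sel, c("x", "y", "z"), drop = FALSE])
}

#' Filter structure entries and chains
#'
#' Applies the retrieval and preprocessing rules that define the clean data
#' set: keep only X-ray entries with resolution strictly better (smaller)
#' than \code{maxRes}; within each biological unit drop chains carrying a
#' non-identity transformation, chains shorter than \code{minLen} residues,
#' and then (iterating to a fixed point) chains left with no interaction
#' partner, i.e. no heavy atom within \code{contactCutoff} of any other
#' surviving chain of the same unit; finally drop units with fewer than two
#' surviving chains and entries with no unit left.
#'
#' @param complexes list of \code{\linkS4class{ComplexRecord}}
#' @param minLen minimum chain length in residues (default 30)
#' @param maxRes resolution bound in Angstrom; entries must be strictly
#'   better (default 3.0)
#' @param contactCutoff heavy-atom distance (Angstrom) defining an
#'   interaction partner (default 5.0)
#' @return a list with \code{kept} (filtered ComplexRecords), \code{report}
#'   (data.frame of removal counts by reason) and \code{manifest} (one row
#'   per chain instance: entry, chain, unit, length, resolution, kept flag
#'   and drop reason)
#' @export
filterComplexes <- function(complexes, minLen = 30L, maxRes = 3.0,
                            contactCutoff = 5.0) {
  manifest <- list()
  kept <- list()
  note <- function(cx, ch, keep, reason) {
    data.frame(entry_id = cx@entryId, chain_id = ch$chain_id,
               bio_unit = ch$bio_unit, length = ch$length,
               resolution = cx@resolution, kept = keep,
               drop_reason = reason, stringsAsFactors = FALSE)
  }
  for (cx in complexes) {
    ch <- cx@chains
    if (!grepl("X-RAY", toupper(cx@method))) {
      manifest[[length(manifest) + 1L]] <- note(cx, ch, FALSE, "not_xray")
      next
    }
    if (!is.finite(cx@resolution) || cx@resolution >= maxRes) {
      manifest[[length(manifest) + 1L]] <- note(cx, ch, FALSE, "resolution")
      next
    }
    reason <- rep(NA_character_, nrow(ch))
    alive <- rep(TRUE, nrow(ch))
    drop <- function(idx, why) {
      alive[idx] <<- FALSE
      reason[idx] <<- why
    }
    drop(which(!ch$transform_identity), "non_identity_transform")
    drop(which(alive & ch$length < minLen), "short_chain")
    ## partner requirement, iterated to a fixed point
    coords <- lapply(ch$chain_id, chainHeavyCoords, complex = cx)
    cut2 <- contactCutoff^2
    for (u in unique(ch$bio_unit)) {
      repeat {
        idx <- which(alive & ch$bio_unit == u)
        if (length(idx) < 2L) break
        has_partner <- vapply(idx, function(i) {
          any(vapply(setdiff(idx, i), function(j)
            minPairDist2(coords[[i]], coords[[j]]) <= cut2, logical(1)))
        }, logical(1))
        if (all(has_partner)) break
        drop(idx[!has_partner], "no_partner")
      }
      idx <- which(alive & ch$bio_unit == u)
      if (length(idx) == 1L) drop(idx, "bio_unit_too_small")
    }
    manifest[[length(manifest) + 1L]] <-
      note(cx, ch, alive, ifelse(alive, "", reason))
    if (any(alive)) {
      ch2 <- ch[alive, , drop = FALSE]
      rownames(ch2) <- NULL
      at2 <- cx@atoms[cx@atoms$chain_id %in% unique(ch2$chain_id), ,
                      drop = FALSE]
      kept[[length(kept) + 1L]] <-
        new("ComplexRecord", entryId = cx@entryId, method = cx@method,
            resolution = cx@resolution, atoms = at2, chains = ch2)
    }
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(entry_id = character(), chain_id = character(),
               bio_unit = integer(), length = integer(),
               resolution = numeric(), kept = logical(),
               drop_reason = character(), stringsAsFactors = FALSE)
  tab <- table(manifest$drop_reason[!manifest$kept])
  report <- data.frame(reason = names(tab), n = as.integer(tab),
                       stringsAsFactors = FALSE)
  list(kept = kept, report = report, manifest = manifest)
}

#' Write the chain manifest TSV
#'
#' @param manifest the \code{manifest} element of
#'   \code{\link{filterComplexes}}
#' @param path output TSV path
#' @return \code{path}, invisibly
#' @export
writeChainManifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
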