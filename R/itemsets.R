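## Closed frequent itemset mining over the fingerprint/interface
## transactional encoding (LCM-style prefix-preserving closure extension).

#' Mine closed frequent itemsets
#'
#' Enumerates every itemset with support at least \code{minsup} that has no
#' proper superset of equal support. Transactions are sets of item labels;
#' the search walks closures depth-first with prefix-preserving extension,
#' so each closed set is produced exactly once.
#'
#' @param transactions list of character vectors (the items of each
#'   transaction)
#' @param minsup absolute minimum support (>= 1)
#' @return data.frame with \code{itemset} (comma-joined sorted items) and
#'   \code{support}; zero rows when nothing is frequent
#' @examples
#' mineClosedItemsets(list(c("a","b","c"), c("a","b"), c("a","c")), 2)
#' @export
mineClosedItemsets <- function(transactions, minsup = 1L) {
  stopifnot(minsup >= 1L)
  items <- sort(unique(unlist(transactions)))
  n <- length(transactions)
  out_sets <- list(); out_sup <- integer(0)
  if (!length(items) || minsup > n)
    return(data.frame(itemset = character(), support = integer(),
                      stringsAsFactors = FALSE))
  tid <- lapply(items, function(it)
    which(vapply(transactions, function(tr) it %in% tr, TRUE)))
  names(tid) <- items
  closureOf <- function(tids) {
    which(vapply(seq_along(items), function(i)
      all(tids %in% tid[[i]]), TRUE))
  }
  emit <- function(iset, sup) {
    out_sets[[length(out_sets) + 1L]] <<- items[iset]
    out_sup[length(out_sup) + 1L] <<- sup
  }
  dfs <- function(clos, tids, core) {
    for (i in seq_along(items)) {
      if (i <= core || i %in% clos) next
      nt <- intersect(tids, tid[[i]])
      if (length(nt) < minsup) next
      nc <- closureOf(nt)
      ## prefix check: the closure must not pull in items before i that
      ## were absent from the parent closure
      if (any(nc < i & !(nc %in% clos))) next
      emit(nc, length(nt))
      dfs(nc, nt, i)
    }
  }
  root_t <- seq_len(n)
  root_c <- closureOf(root_t)
  if (length(root_c) && length(root_t) >= minsup)
    emit(root_c, length(root_t))
  dfs(root_c, root_t, 0L)
  data.frame(itemset = vapply(out_sets, paste, "", collapse = ","),
             support = out_sup, stringsAsFactors = FALSE)
}
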