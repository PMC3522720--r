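#' @useDynLib miDomains, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

## 20-letter amino-acid alphabet used for all graph node labels.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Kyte-Doolittle hydropathy index.
KD_HYDRO <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
              H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
              P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
              W = -0.9, Y = -1.3)

## Theoretical maximum accessible surface areas (A^2) per residue type
## (Tien et al. 2013), used to normalise SASA into relative accessibility.
MAX_ASA <- c(A = 129, C = 167, D = 193, E = 223, F = 240, G = 104,
             H = 224, I = 197, K = 236, L = 201, M = 224, N = 195,
             P = 159, Q = 225, R = 274, S = 155, T = 172, V = 174,
             W = 285, Y = 263, X = 200)

## van der Waals radii (A) by element for SASA; unknown elements get carbon's.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, H = 1.20)

aaLabelInt <- function(aa) {
  i <- match(aa, AA20)
  if (anyNA(i)) stop("non-standard amino-acid label in graph: ",
                     paste(unique(aa[is.na(i)]), collapse = ", "))
  i
}

#' Chain instance key
#'
#' Chains are identified throughout the package by
#' \code{"<entry>:<bio_unit>:<chain_id>"}, so that the same author chain
#' re-used in two biological units counts as two instances.
#'
#' @param entryId entry identifier
#' @param bioUnit biological unit number
#' @param chainId author chain identifier
#' @return character vector of keys
#' @export
chainKey <- function(entryId, bioUnit, chainId) {
  paste(entryId, bioUnit, chainId, sep = ":")
}

splitChainKey <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  data.frame(entry_id = vapply(parts, `[`, "", 1L),
             bio_unit = as.integer(vapply(parts, `[`, "", 2L)),
             chain_id = vapply(parts, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

## Residue-level identity for (chain, resno, icode) triples.
resId <- function(chain, resno, icode) {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste(chain, resno, icode, sep = "|")
}

stopifnot_scalar_num <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(nm, " must be a finite numeric scalar")
}
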