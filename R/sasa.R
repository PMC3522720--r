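## Solvent accessibility by the Shrake-Rupley rolling-probe method, used
## only to pick surface residues before tessellation.

fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Atomic solvent-accessible surface area
#'
#' Shrake-Rupley numerical SASA: each atom is inflated by the probe radius
#' and sampled with \code{nPoints} evenly spread sphere points; the
#' accessible fraction is the share of points inside no neighbouring
#' inflated sphere.
#'
#' @param coords n x 3 matrix of heavy-atom coordinates (Angstrom)
#' @param elements element symbols (C, N, O, S, ...)
#' @param probe probe radius, default 1.4 (water)
#' @param nPoints sphere sample points per atom (default 92)
#' @return numeric vector of per-atom SASA in Angstrom^2
#' @export
shrakeRupleySASA <- function(coords, elements, probe = 1.4, nPoints = 92L) {
  n <- nrow(coords)
  if (!n) return(numeric())
  r <- VDW_RADII[toupper(elements)]
  r[is.na(r)] <- VDW_RADII[["C"]]
  r <- unname(r) + probe
  sp <- fibonacciSphere(nPoints)
  d2 <- outer(rowSums(coords^2), rowSums(coords^2), "+") -
    2 * tcrossprod(coords)
  asa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] <= (r[i] + r)^2 & seq_len(n) != i)
    pts <- sweep(sp * r[i], 2, coords[i, ], "+")
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      dj2 <- rowSums(sweep(pts, 2, coords[j, ], "-")^2)
      free <- free & dj2 > r[j]^2
      if (!any(free)) break
    }
    asa[i] <- 4 * pi * r[i]^2 * sum(free) / nPoints
  }
  asa
}

#' Surface residues of a chain
#'
#' Flags residues of one chain (taken in isolation) whose relative solvent
#' accessibility -- residue SASA over the residue type's theoretical
#' maximum -- reaches \code{rsaMin}. With \code{mode = "all"} every residue
#' is returned, for data where an accessibility criterion is not
#' meaningful.
#'
#' @param complex a \code{\linkS4class{ComplexRecord}}
#' @param chainId author chain id
#' @param rsaMin relative accessibility threshold (default 0.05)
#' @param mode \code{"rsa"} or \code{"all"}
#' @return residue table (as \code{chainResidueTable}) with an \code{rsa}
#'   column, restricted to surface residues
#' @export
surfaceResidues <- function(complex, chainId, rsaMin = 0.05,
                            mode = c("rsa", "all")) {
  mode <- match.arg(mode)
  rt <- chainResidueTable(complex, chainId)
  at <- complex@atoms
  sel <- at$chain_id == chainId & !at$is_hydrogen
  a <- at[sel, , drop = FALSE]
  if (mode == "all") {
    rt$rsa <- NA_real_
    return(rt)
  }
  asa <- shrakeRupleySASA(as.matrix(a[, c("x", "y", "z")]), a$element)
  ridx <- match(resId(chainId, a$resno, a$icode),
                resId(chainId, rt$resno, rt$icode))
  res_asa <- tapply(asa, ridx, sum)
  rsa <- numeric(nrow(rt))
  rsa[as.integer(names(res_asa))] <- res_asa / MAX_ASA[rt$aa[as.integer(names(res_asa))]]
  rt$rsa <- rsa
  rt[rt$rsa >= rsaMin, , drop = FALSE]
}
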