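## PDB input/output.
##
## Atom records are parsed with bio3d::read.pdb; header metadata that bio3d
## does not expose (REMARK 2 resolution, EXPDTA method, REMARK 350
## biomolecule/BIOMT blocks) is read directly from the text.

IDENTITY_TOL <- 1e-6

parseRemark350 <- function(lines) {
  rl <- grep("^REMARK 350", lines, value = TRUE)
  if (!length(rl)) return(NULL)
  units <- list()
  cur_unit <- NA_integer_
  cur_chains <- character()
  cur_mats <- list()   # matrix index -> 3x4 rows collected
  flush_group <- function() {
    if (is.na(cur_unit) || !length(cur_chains)) return()
    ident <- TRUE
    for (m in cur_mats) {
      if (nrow(m) != 3L) next
      R <- m[, 1:3, drop = FALSE]; t <- m[, 4]
      if (max(abs(R - diag(3))) > IDENTITY_TOL || max(abs(t)) > IDENTITY_TOL)
        ident <- FALSE
    }
    key <- as.character(cur_unit)
    units[[key]] <<- rbind(units[[key]],
      data.frame(chain_id = cur_chains, transform_identity = ident,
                 stringsAsFactors = FALSE))
  }
  for (ln in rl) {
    if (grepl("BIOMOLECULE:", ln)) {
      flush_group()
      cur_unit <- as.integer(sub(".*BIOMOLECULE:\\s*", "", ln))
      cur_chains <- character(); cur_mats <- list()
    } else if (grepl("TO CHAINS:", ln) || grepl("AND CHAINS:", ln)) {
      if (grepl("TO CHAINS:", ln)) { flush_group(); cur_chains <- character(); cur_mats <- list() }
      ch <- sub(".*CHAINS:\\s*", "", ln)
      ch <- trimws(strsplit(ch, ",")[[1]])
      cur_chains <- c(cur_chains, ch[nzchar(ch)])
    } else if (grepl("BIOMT[123]", ln)) {
      f <- strsplit(trimws(sub("^REMARK 350\\s+", "", ln)), "\\s+")[[1]]
      # f: BIOMTk  idx  r1 r2 r3 t
      idx <- as.character(f[2])
      row <- as.numeric(f[3:6])
      cur_mats[[idx]] <- rbind(cur_mats[[idx]], row)
    }
  }
  flush_group()
  units
}

parseHeaderMeta <- function(lines) {
  method <- "UNKNOWN"
  ex <- grep("^EXPDTA", lines, value = TRUE)
  if (length(ex)) method <- trimws(sub("^EXPDTA", "", ex[1]))
  resolution <- Inf
  rr <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rr)) {
    tail_str <- sub(".*RESOLUTION\\.", "", rr[1])
    num <- regmatches(tail_str, regexpr("[0-9]+\\.?[0-9]*", tail_str))
    if (length(num) && nzchar(num)) resolution <- as.numeric(num)
  }
  list(method = method, resolution = resolution)
}

#' Read a multi-chain structure
#'
#' Parses a PDB file into a \code{\linkS4class{ComplexRecord}}: atom records
#' (hydrogens flagged; for alternate locations only the highest-occupancy
#' conformer is kept, ties broken by altloc letter), per-chain
#' biological-unit membership and identity/non-identity transformation flags
#' from the REMARK 350 (BIOMT) block, experimental method and resolution.
#' Chains without a biomolecule assignment fall into unit 1 with an identity
#' transform; a chain listed in several biomolecules yields one chain
#' instance per unit.
#'
#' @param path path to a PDB file
#' @return a \code{\linkS4class{ComplexRecord}}
#' @examples
#' cx <- generateComplex(complexSpec(seed = 1))
#' pdb <- tempfile(fileext = ".pdb")
#' writeComplexPDB(cx$complex, pdb)
#' readComplex(pdb)
#' @export
readComplex <- function(path) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- parseHeaderMeta(lines)
  bio <- parseRemark350(lines)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE,
                                                   verbose = FALSE)),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("empty complex: no protein chains in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  ## altloc: keep the highest-occupancy conformer (ties: altloc order),
  ## preserving the file's atom order
  at$.row <- seq_len(nrow(at))
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  at <- at[order(key, -at$o, at$alt), , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")), ,
           drop = FALSE]
  at <- at[order(at$.row), , drop = FALSE]
  aa <- suppressWarnings(bio3d::aa321(at$resid))
  aa[is.na(aa) | !(aa %in% AA20)] <- "X"
  elesy <- at$elesy
  guess <- toupper(substr(gsub("^[0-9]+", "", at$elety), 1, 1))
  elesy[is.na(elesy) | !nzchar(elesy)] <- guess[is.na(elesy) | !nzchar(elesy)]
  is_h <- toupper(elesy) == "H"
  atoms <- data.frame(serial = at$eleno, name = at$elety, element = toupper(elesy),
                      resid = at$resid, chain_id = at$chain, resno = at$resno,
                      icode = at$insert, aa = aa,
                      x = at$x, y = at$y, z = at$z, is_hydrogen = is_h,
                      stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)

  ## protein chains: majority of residues map into the 20-letter alphabet
  heavy <- atoms[!atoms$is_hydrogen, , drop = FALSE]
  res_tab <- unique(heavy[, c("chain_id", "resno", "icode", "aa")])
  keep_chain <- vapply(split(res_tab$aa, res_tab$chain_id), function(a) {
    sum(a %in% AA20) >= max(1L, ceiling(length(a) / 2))
  }, logical(1))
  prot_chains <- names(keep_chain)[keep_chain]
  if (!length(prot_chains)) stop("empty complex: no protein chains in ", path)
  atoms <- atoms[atoms$chain_id %in% prot_chains, , drop = FALSE]

  entry <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  hl <- grep("^HEADER", lines, value = TRUE)
  if (length(hl)) {
    id <- trimws(substr(hl[1], 63, 80))
    if (nzchar(id)) entry <- id
  }

  ## chain instances per biological unit
  mk_chain_rows <- function(chain_ids, unit, ident) {
    rows <- lapply(chain_ids, function(cid) {
      rt <- res_tab[res_tab$chain_id == cid, , drop = FALSE]
      rt <- rt[order(rt$resno, rt$icode), , drop = FALSE]
      data.frame(chain_id = cid, bio_unit = unit, transform_identity = ident,
                 length = nrow(rt), sequence = paste(rt$aa, collapse = ""),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  chain_rows <- list()
  assigned <- character()
  if (!is.null(bio)) {
    for (ukey in names(bio)) {
      grp <- bio[[ukey]]
      grp <- grp[grp$chain_id %in% prot_chains, , drop = FALSE]
      if (!nrow(grp)) next
      for (ident in unique(grp$transform_identity)) {
        cids <- grp$chain_id[grp$transform_identity == ident]
        chain_rows[[length(chain_rows) + 1L]] <-
          mk_chain_rows(cids, as.integer(ukey), ident)
      }
      assigned <- union(assigned, grp$chain_id)
    }
  }
  left <- setdiff(prot_chains, assigned)
  if (length(left))
    chain_rows[[length(chain_rows) + 1L]] <- mk_chain_rows(left, 1L, TRUE)
  chains <- do.call(rbind, chain_rows)
  chains <- chains[!duplicated(chains[, c("chain_id", "bio_unit")]), , drop = FALSE]
  chains <- chains[order(chains$bio_unit, chains$chain_id), , drop = FALSE]
  rownames(chains) <- NULL

  new("ComplexRecord", entryId = entry, method = meta$method,
      resolution = meta$resolution, atoms = atoms, chains = chains)
}

#' Write a structure back to PDB format
#'
#' Emits REMARK 2 (resolution), EXPDTA, one REMARK 350 biomolecule block per
#' biological unit (identity BIOMT for chains flagged identity, an inverting
#' rotation otherwise, so the flag round-trips) and fixed-width ATOM records.
#'
#' @param complex a \code{\linkS4class{ComplexRecord}}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeComplexPDB <- function(complex, path) {
  stopifnot(is(complex, "ComplexRecord"))
  out <- c(
    sprintf("HEADER    PROTEIN COMPLEX                         01-JAN-00   %s",
            complex@entryId),
    sprintf("EXPDTA    %s", complex@method))
  if (is.finite(complex@resolution))
    out <- c(out, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.",
                          complex@resolution))
  ch <- complex@chains
  mt <- 0L
  for (u in sort(unique(ch$bio_unit))) {
    out <- c(out, sprintf("REMARK 350 BIOMOLECULE: %2d", u))
    sub <- ch[ch$bio_unit == u, , drop = FALSE]
    for (ident in unique(sub$transform_identity)) {
      cids <- sub$chain_id[sub$transform_identity == ident]
      out <- c(out, paste0("REMARK 350 APPLY THE FOLLOWING TO CHAINS: ",
                           paste(cids, collapse = ", ")))
      mt <- mt + 1L
      R <- if (ident) diag(3) else diag(c(-1, -1, 1))
      for (k in 1:3)
        out <- c(out, sprintf("REMARK 350   BIOMT%d %3d%10.6f%10.6f%10.6f     %10.5f",
                              k, mt, R[k, 1], R[k, 2], R[k, 3], 0))
    }
  }
  at <- complex@atoms
  at <- at[order(at$chain_id, at$resno, at$icode, at$serial), , drop = FALSE]
  name_fld <- ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name)
  for (cid in unique(at$chain_id)) {
    rows <- which(at$chain_id == cid)
    out <- c(out, sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$serial[rows], name_fld[rows], at$resid[rows], cid, at$resno[rows],
      ifelse(nzchar(at$icode[rows]), at$icode[rows], " "),
      at$x[rows], at$y[rows], at$z[rows], 1, 0, at$element[rows]))
    out <- c(out, "TER")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}
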