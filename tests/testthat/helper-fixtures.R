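## In-code fixtures: toy complexes and interfaces built directly.

## chains: named list of data.frames with resno, aa, x, y, z (one CA atom
## per residue) or optional name/element columns for multi-atom residues
toyComplex <- function(chains, resolution = 2.0,
                       method = "X-RAY DIFFRACTION", entry = "TOY1",
                       bioUnit = NULL, transformIdentity = NULL) {
  serial <- 0L
  atom_rows <- list()
  chain_rows <- list()
  ids <- names(chains)
  for (k in seq_along(chains)) {
    df <- chains[[k]]
    if (is.null(df$name)) df$name <- "CA"
    if (is.null(df$element)) df$element <- "C"
    if (is.null(df$icode)) df$icode <- ""
    for (r in seq_len(nrow(df))) {
      serial <- serial + 1L
      atom_rows[[serial]] <- data.frame(
        serial = serial, name = df$name[r], element = df$element[r],
        resid = bio3d::aa123(df$aa[r]), chain_id = ids[k],
        resno = df$resno[r], icode = df$icode[r], aa = df$aa[r],
        x = df$x[r], y = df$y[r], z = df$z[r], is_hydrogen = FALSE,
        stringsAsFactors = FALSE)
    }
    rt <- unique(df[, c("resno", "icode", "aa")])
    rt <- rt[order(rt$resno, rt$icode), ]
    chain_rows[[k]] <- data.frame(
      chain_id = ids[k],
      bio_unit = if (is.null(bioUnit)) 1L else bioUnit[k],
      transform_identity = if (is.null(transformIdentity)) TRUE
                           else transformIdentity[k],
      length = nrow(rt), sequence = paste(rt$aa, collapse = ""),
      stringsAsFactors = FALSE)
  }
  new("ComplexRecord", entryId = entry, method = method,
      resolution = resolution, atoms = do.call(rbind, atom_rows),
      chains = do.call(rbind, chain_rows))
}

## interface built from (msa_column, aa) pairs
toyInterface <- function(cols, aa, host = "E1:1:A", partner = "E1:1:B",
                         entry = "E1", resolution = 2.0, site = NA) {
  new("InterfaceInstance", hostChain = host, partnerChain = partner,
      entryId = entry, bioUnit = 1L, resolution = resolution,
      residues = data.frame(resno = cols, icode = "", aa = aa,
                            seq_pos = cols, msa_column = cols,
                            stringsAsFactors = FALSE),
      siteId = as.integer(site))
}

randomAASeq <- function(n) paste(sample(miDomains:::AA20, n, replace = TRUE),
                                 collapse = "")

substituteAt <- function(seq, pos, to = NULL) {
  aa <- strsplit(seq, "")[[1]]
  for (p in pos) {
    repl <- if (is.null(to)) setdiff(miDomains:::AA20, aa[p])[1] else to
    aa[p] <- repl
  }
  paste(aa, collapse = "")
}
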