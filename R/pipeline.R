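## End-to-end orchestration: preprocess -> cluster -> interfaces ->
## graphs -> mine -> relations -> stats, with a JSON run manifest.

#' Pipeline configuration
#'
#' All thresholds default to the analysis' standard parameters: 5 A
#' contact cutoff, 0.8 interface de-duplication similarity, 0.975 chain
#' cluster similarity (mutation rate <= 2.5 percent), 20 percent local
#' support, site threshold 0.5, chain length >= 30, resolution < 3 A.
#'
#' @param structuresDir directory of PDB files
#' @param outDir output directory
#' @param contactCutoff,dedupThreshold,clusterMinSimilarity,localSupport,siteThreshold,minLen,maxRes analysis thresholds
#' @param surface surface-residue mode for graph building
#' @param nullReps replicates for isomorphism null p-values
#' @param minCoFraction cooperative pair threshold
#' @param seed RNG seed for all stochastic stages
#' @return a \code{PipelineConfig} list
#' @export
pipelineConfig <- function(structuresDir, outDir,
                           contactCutoff = 5.0, dedupThreshold = 0.8,
                           clusterMinSimilarity = 0.975,
                           localSupport = 0.20, siteThreshold = 0.5,
                           minLen = 30L, maxRes = 3.0,
                           surface = "rsa", nullReps = 200L,
                           minCoFraction = 0.20, seed = 1L) {
  stopifnot(dedupThreshold >= 0, dedupThreshold <= 1,
            clusterMinSimilarity >= 0, clusterMinSimilarity <= 1,
            localSupport > 0, localSupport <= 1, contactCutoff > 0)
  structure(list(structuresDir = structuresDir, outDir = outDir,
                 contactCutoff = contactCutoff,
                 dedupThreshold = dedupThreshold,
                 clusterMinSimilarity = clusterMinSimilarity,
                 localSupport = localSupport,
                 siteThreshold = siteThreshold, minLen = minLen,
                 maxRes = maxRes, surface = surface, nullReps = nullReps,
                 minCoFraction = minCoFraction, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match \code{\link{pipelineConfig}}
#'   arguments
#' @return a \code{PipelineConfig}
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

stageError <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage,
               conditionMessage(e)), call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes all stages on a directory of structures and writes staged
#' outputs plus a JSON run manifest (config, input checksums, per-stage
#' file lists) into \code{outDir}. Reruns with an identical configuration
#' and inputs produce byte-identical reports.
#'
#' @param cfg a \code{\link{pipelineConfig}}
#' @return the manifest, invisibly
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  out <- cfg$outDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg[setdiff(names(cfg), c())],
                   stages = list())

  ## -- preprocess ----------------------------------------------------
  files <- tryCatch({
    if (!dir.exists(cfg$structuresDir))
      stop("structures directory not found: ", cfg$structuresDir)
    sort(list.files(cfg$structuresDir, pattern = "\\.(pdb|ent)$",
                    full.names = TRUE))
  }, error = function(e) stageError("preprocess", e))
  if (!length(files)) stageError("preprocess",
                                 simpleError("no PDB files found"))
  manifest$inputs <- data.frame(file = basename(files),
                                md5 = unname(tools::md5sum(files)),
                                stringsAsFactors = FALSE)
  flt <- tryCatch({
    complexes <- lapply(files, readComplex)
    filterComplexes(complexes, minLen = cfg$minLen, maxRes = cfg$maxRes,
                    contactCutoff = cfg$contactCutoff)
  }, error = function(e) stageError("preprocess", e))
  writeChainManifest(flt$manifest, file.path(out, "manifest.tsv"))
  manifest$stages$preprocess <- list(n_entries_in = length(files),
                                     n_entries_kept = length(flt$kept))
  complexes <- setNames(flt$kept,
                        vapply(flt$kept, function(x) x@entryId, ""))

  ## -- cluster -------------------------------------------------------
  cl <- tryCatch({
    seqs <- unlist(lapply(complexes, chainSequences))
    names(seqs) <- unlist(lapply(complexes, function(x)
      names(chainSequences(x))))
    writeChainFasta(seqs, file.path(out, "chains.fa"))
    list(seqs = seqs,
         res = buildChainClusters(seqs,
                                  minSimilarity = cfg$clusterMinSimilarity))
  }, error = function(e) stageError("cluster", e))
  utils::write.table(cl$res$clusters, file.path(out, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cl$res$diagnostics,
                     file.path(out, "cluster_diagnostics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$cluster <- list(n_chains = length(cl$seqs),
                                  n_clusters =
                                    max(cl$res$clusters$cluster_id))

  ## -- interfaces ----------------------------------------------------
  ifres <- tryCatch({
    all_if <- unlist(lapply(complexes, detectInterfaces,
                            cutoff = cfg$contactCutoff),
                     recursive = FALSE)
    clu <- cl$res$clusters
    by_cluster <- split(seq_along(all_if), vapply(all_if, function(i)
      clu$cluster_id[match(i@hostChain, clu$chain)], 0L))
    reps_by_cluster <- list(); msas <- list()
    for (cid in names(by_cluster)) {
      members <- clu$chain[clu$cluster_id == as.integer(cid)]
      mseqs <- cl$seqs[members]
      msa <- centerStarMSA(mseqs, clusterId = as.integer(cid))
      ifs <- mapInterfaces(all_if[by_cluster[[cid]]], msa)
      reps <- dedupInterfaces(ifs, msa, threshold = cfg$dedupThreshold,
                              complexes = complexes)
      reps <- clusterBindingSites(reps, siteThreshold = cfg$siteThreshold)
      reps_by_cluster[[cid]] <- reps
      msas[[cid]] <- msa
    }
    list(reps = reps_by_cluster, msas = msas, n_raw = length(all_if))
  }, error = function(e) stageError("interfaces", e))
  iface_tab <- do.call(rbind, lapply(names(ifres$reps), function(cid) {
    reps <- ifres$reps[[cid]]
    if (!length(reps)) return(NULL)
    do.call(rbind, lapply(reps, function(r) data.frame(
      cluster_id = as.integer(cid), site_id = r@siteId,
      host = r@hostChain, partner = r@partnerChain, entry = r@entryId,
      resolution = r@resolution, n_residues = nrow(r@residues),
      residues = paste(sprintf("%s:%d:%s:%s",
                               splitChainKey(r@hostChain)$chain_id,
                               r@residues$resno, r@residues$icode,
                               r@residues$aa), collapse = ","),
      stringsAsFactors = FALSE)))
  }))
  utils::write.table(iface_tab, file.path(out, "interfaces.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$interfaces <-
    list(n_detected = ifres$n_raw,
         n_representatives = sum(lengths(ifres$reps)))

  ## -- graphs --------------------------------------------------------
  graphs_by_cluster <- tryCatch({
    lapply(ifres$reps, function(reps) {
      lapply(reps, function(r)
        buildInterfaceGraph(r, complexes[[r@entryId]],
                            cutoff = cfg$contactCutoff,
                            surface = cfg$surface))
    })
  }, error = function(e) stageError("graphs", e))
  gdir <- file.path(out, "graphs")
  for (cid in names(graphs_by_cluster))
    writeInterfaceGraphs(graphs_by_cluster[[cid]],
                         file.path(gdir, paste0("cluster", cid)))
  manifest$stages$graphs <-
    list(n_graphs = sum(lengths(graphs_by_cluster)))

  ## -- mine ----------------------------------------------------------
  mined <- tryCatch({
    lapply(names(graphs_by_cluster), function(cid) {
      gl <- graphs_by_cluster[[cid]]
      sids <- vapply(gl, function(g) g@siteId, 0L)
      per_site <- lapply(sort(unique(sids)), function(s) {
        db <- gl[sids == s]
        names(db) <- vapply(db, function(g) g@graphId, "")
        if (length(db) < 2L) return(list())
        mineClosedFrequent(db, localSupport = cfg$localSupport,
                           siteId = s)
      })
      names(per_site) <- as.character(sort(unique(sids)))
      per_site
    })
  }, error = function(e) stageError("mine", e))
  names(mined) <- names(graphs_by_cluster)
  fp_tab <- do.call(rbind, lapply(names(mined), function(cid) {
    rows <- do.call(rbind, lapply(mined[[cid]], fingerprintIndex))
    if (!is.null(rows) && nrow(rows)) cbind(cluster_id = as.integer(cid), rows)
  }))
  if (is.null(fp_tab))
    fp_tab <- data.frame(cluster_id = integer(), fingerprint_id = integer())
  utils::write.table(fp_tab, file.path(out, "fingerprints.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$mine <- list(n_fingerprints =
                                 sum(vapply(mined, function(x)
                                   sum(lengths(x)), 0)))

  ## -- relations -----------------------------------------------------
  relations <- tryCatch({
    lapply(names(mined), function(cid) {
      per_site <- mined[[cid]]
      per_site <- per_site[lengths(per_site) > 0L]
      if (length(per_site) < 2L) return(NULL)
      domainRelationReport(per_site, graphs_by_cluster[[cid]],
                           minCoFraction = cfg$minCoFraction,
                           nReps = cfg$nullReps, seed = cfg$seed)
    })
  }, error = function(e) stageError("relations", e))
  names(relations) <- names(mined)
  rel_out <- Filter(Negate(is.null), relations)
  for (cid in names(rel_out)) {
    rr <- rel_out[[cid]]
    utils::write.table(rr@cooperative,
                       file.path(out, paste0("cooperative_c", cid, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rr@isomorphism,
                       file.path(out, paste0("isomorphism_c", cid, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest$stages$relations <- list(n_domains_tested = length(rel_out))

  ## -- stats ---------------------------------------------------------
  proteins <- do.call(rbind, lapply(names(ifres$reps), function(cid) {
    reps <- ifres$reps[[cid]]
    if (!length(reps)) return(NULL)
    data.frame(protein_id = reps[[1]]@hostChain,
               n_sites = length(unique(vapply(reps, function(r)
                 r@siteId, 0L))), stringsAsFactors = FALSE)
  }))
  agg <- if (!is.null(proteins)) aggregateCounts(proteins) else
    list(histogram = data.frame())
  stats <- list(n_entries = length(complexes),
                n_chains = length(cl$seqs),
                n_clusters = max(cl$res$clusters$cluster_id),
                n_multi_interface_proteins =
                  if (!is.null(proteins)) sum(proteins$n_sites >= 2L) else 0L,
                site_histogram = agg$histogram,
                seed = cfg$seed)
  jsonlite::write_json(stats, file.path(out, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$stages$stats <- stats
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
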