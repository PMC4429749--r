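# High-level orchestration: training-set assembly from anchors, per-miRNA
# TSS prediction, and the run-all pipeline behind the command-line interface.

#' Assemble a TSS training set from positive anchors
#'
#' Extracts feature vectors at the positive anchors and at sampled (or
#' supplied) background anchors, producing the classifier input.
#'
#' @param positives stranded 1-bp `GRanges` of verified TSS anchors (ids in
#'   `names()` or metadata column `gene`).
#' @param tracks,motifs named lists as in [featureMatrix()].
#' @param genomeLengths named vector of sequence lengths.
#' @param negatives optional `GRanges` of background anchors; sampled with
#'   [sampleNegatives()] when `NULL`.
#' @param nNegatives number of negatives to sample (default: one per
#'   positive).
#' @param minDistance minimum distance of sampled negatives from any
#'   positive (default 1000).
#' @param seed RNG seed for negative sampling.
#' @param featureSet,span,binSize feature geometry, as in [featureMatrix()].
#' @param provenance free-text provenance recorded in the set.
#' @return a [TssTrainingSet-class].
#' @export
trainingSetFromAnchors <- function(positives, tracks, motifs = list(),
                                   genomeLengths, negatives = NULL,
                                   nNegatives = length(positives),
                                   minDistance = 1000L, seed = 1L,
                                   featureSet = NULL, span = 1000L,
                                   binSize = 200L, provenance = "") {
  if (is.null(negatives))
    negatives <- sampleNegatives(genomeLengths, positives, nNegatives,
                                 minDistance, seed)
  fmP <- featureMatrix(positives, tracks, motifs, featureSet, span, binSize)
  fmN <- featureMatrix(negatives, tracks, motifs, featureSet, span, binSize)
  if (is.null(rownames(fmP$x))) {
    ids <- mcols(positives)$gene
    rownames(fmP$x) <- if (!is.null(ids)) ids else
      sprintf("pos%04d", seq_len(nrow(fmP$x)))
  }
  if (is.null(rownames(fmN$x)))
    rownames(fmN$x) <- sprintf("neg%04d", seq_len(nrow(fmN$x)))
  TssTrainingSet(fmP$x, fmN$x, fmP$layout, provenance)
}

# rbind GRanges whose metadata columns differ, NA-filling missing ones.
.bindCandidates <- function(grs) {
  grs <- grs[vapply(grs, length, integer(1)) > 0L]
  if (length(grs) == 0L) return(GRanges())
  cols <- unique(unlist(lapply(grs, function(g) names(mcols(g)))))
  grs <- lapply(grs, function(g) {
    m <- as.data.frame(mcols(g))
    for (c0 in setdiff(cols, names(m))) m[[c0]] <- NA
    mcols(g) <- DataFrame(m[, cols, drop = FALSE])
    g
  })
  suppressWarnings(do.call(c, grs))
}

#' Predict TSS candidates for every pre-miRNA
#'
#' Intragenic precursors (embedded in the same strand of an annotated gene)
#' are represented by their host gene's recorded TSS; intergenic precursors
#' are scanned over their 10-kb upstream window with the trained classifier.
#'
#' @param model a [TssModel-class].
#' @param mirnas `GRanges` of precursor loci with metadata columns `id`,
#'   `intragenic`, `host_gene`.
#' @param tracks,motifs feature sources, as in [featureMatrix()].
#' @param tssRecords optional `GRanges` of verified gene TSSs (needed for
#'   intragenic resolution; an intragenic miRNA whose host has no record is
#'   scanned instead, with a warning).
#' @param seqLengths named vector of sequence lengths.
#' @param ... passed to [scanUpstreamTss()] (`window`, `step`, `topK`,
#'   `nmsRadius`, `est`, `conservation`).
#' @return `GRanges` of candidates over all miRNAs, with a `method` column
#'   (`"scan"` or `"host_gene"`).
#' @export
predictMirnaTss <- function(model, mirnas, tracks, motifs = list(),
                            tssRecords = NULL, seqLengths = NULL, ...) {
  out <- lapply(seq_along(mirnas), function(i) {
    pm <- mirnas[i]
    if (isTRUE(mcols(pm)$intragenic) && !is.null(tssRecords)) {
      cand <- tryCatch(resolveIntragenic(pm, tssRecords),
                       error = function(e) {
                         warning(conditionMessage(e), "; scanning instead")
                         NULL
                       })
      if (!is.null(cand)) {
        mcols(cand)$method <- "host_gene"
        return(cand)
      }
    }
    cand <- scanUpstreamTss(model, pm, tracks, motifs, seqLengths, ...)
    if (length(cand)) mcols(cand)$method <- "scan"
    cand
  })
  .bindCandidates(out)
}

#' Default run configuration
#'
#' Every tunable pipeline parameter with its documented default; input paths
#' are `NULL` until supplied. Unknown keys in a user configuration are
#' rejected by [runPipeline()].
#'
#' @return named list.
#' @export
defaultRunConfig <- function() {
  list(
    genome = NULL, annotations = NULL, tss_bed = NULL,
    track_tss_tags = NULL, track_h3k4me3 = NULL, track_h3k9ac = NULL,
    track_h3 = NULL,
    motif_Y_patch = NULL, motif_Inr = NULL, motif_CA = NULL,
    motif_GA = NULL, motif_REG = NULL,
    pwms = NULL, mirna_expr = NULL, gene_expr = NULL,
    mti = NULL, gene_graph = NULL, go = NULL,
    est = NULL, conservation = NULL,
    seed = 1L, out_dir = "mirregnet_out",
    span = 1000L, bin_size = 200L, window = 10000L, step = 20L,
    top_k = 10L, nms_radius = 200L, min_neg_distance = 1000L,
    promoter_length = 1000L, export_promoter_length = 5000L,
    coexpr_method = "pcc", coexpr_threshold = 0.9, min_genes = 10L,
    core_threshold = 0.75, matrix_threshold = 0.85,
    freq_cutoff = 0.5, p_cutoff = 0.1,
    go_min_term_size = 2L, go_adjust = "none",
    n_folds = 5L, blacklist_seqids = organelleSeqids())
}

#' Load and validate a run configuration
#'
#' @param path optional YAML file; keys override the defaults of
#'   [defaultRunConfig()]. Unknown keys are an error.
#' @param overrides named list applied on top (e.g. command-line flags).
#' @return the merged configuration list.
#' @export
loadRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- defaultRunConfig()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  for (src in list(user, overrides)) {
    unknown <- setdiff(names(src), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(src)] <- src
  }
  cfg
}

.readInputs <- function(cfg) {
  need <- c("genome", "annotations", "tss_bed", "track_tss_tags",
            "track_h3k4me3", "track_h3k9ac", "track_h3")
  miss <- need[vapply(need, function(k) is.null(cfg[[k]]), logical(1))]
  if (length(miss))
    stop("missing required input path(s): ", paste(miss, collapse = ", "))
  genome <- readGenomeFasta(cfg$genome)
  lens <- genomeLengths(genome)
  tracks <- list(
    tss_tags = readSignalBedGraph(cfg$track_tss_tags, lens, "tss_tags"),
    h3k4me3 = readSignalBedGraph(cfg$track_h3k4me3, lens, "h3k4me3"),
    h3k9ac = readSignalBedGraph(cfg$track_h3k9ac, lens, "h3k9ac"),
    h3 = readSignalBedGraph(cfg$track_h3, lens, "h3"))
  motifClasses <- c("Y_patch", "Inr", "CA", "GA", "REG")
  motifs <- list()
  for (mc in motifClasses) {
    key <- paste0("motif_", mc)
    if (!is.null(cfg[[key]]))
      motifs[[mc]] <- readBedSites(cfg[[key]], motifClass = mc)
  }
  list(genome = genome, lens = lens,
       mirnas = readMirnaAnnotations(cfg$annotations),
       genes = readGeneAnnotations(cfg$annotations),
       tssRecords = readBedSites(cfg$tss_bed),
       tracks = tracks, motifs = motifs)
}

#' Run the full pipeline
#'
#' Executes every stage end to end from a configuration of input paths:
#' training-set assembly and cross-validated SVM training, the 10-kb
#' upstream TSS scan for every miRNA (host-gene rule for intragenic ones),
#' promoter export, coexpression groups, Match-style TFBS scanning with
#' coTFBS statistics and the candidate-TF filter, MTI correlations,
#' DFS expansion to indirect targets, GO enrichment, and network export
#' (SIF + GraphML) — writing every output plus a checksum manifest into
#' `out_dir`.
#'
#' @param cfg configuration list from [loadRunConfig()].
#' @return named list of stage results, invisibly.
#' @export
runPipeline <- function(cfg) {
  outDir <- cfg$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outDir, f)
  log0 <- function(stage, ...) {
    message("[", stage, "] ", ...)
  }
  inp <- .readInputs(cfg)
  log0("inputs", length(inp$mirnas), " miRNAs, ", length(inp$tssRecords),
       " TSS records, ", length(inp$genome), " sequences")

  # --- TSS model
  pos <- filterTrainingTss(inp$tssRecords, inp$genes,
                           cfg$blacklist_seqids)
  ts <- trainingSetFromAnchors(pos, inp$tracks, inp$motifs, inp$lens,
                               minDistance = cfg$min_neg_distance,
                               seed = cfg$seed, span = cfg$span,
                               binSize = cfg$bin_size,
                               provenance = "pipeline run")
  cv <- crossValidate(ts, nFolds = cfg$n_folds, seed = cfg$seed)
  model <- trainTssModel(ts, seed = cfg$seed, span = cfg$span,
                         binSize = cfg$bin_size, cv = cv)
  saveTssModel(model, p("tss_model.rds"))
  utils::write.table(cvFolds(cv), p("cv_metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log0("train-tss", "CV accuracy ", round(cvSummary(cv)["accuracy"], 4))

  # --- TSS prediction
  cand <- predictMirnaTss(model, inp$mirnas, inp$tracks, inp$motifs,
                          inp$tssRecords, inp$lens, window = cfg$window,
                          step = cfg$step, topK = cfg$top_k,
                          nmsRadius = cfg$nms_radius)
  if (length(cand)) {
    bed <- granges(cand)
    mcols(bed)$name <- paste0(mcols(cand)$mirna, "|", mcols(cand)$rank)
    sc <- mcols(cand)$score
    sc[!is.finite(sc)] <- 0
    mcols(bed)$score <- sc
    writeBedSites(bed, p("tss_candidates.bed"))
    utils::write.table(as.data.frame(cand), p("tss_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rank1 <- cand[mcols(cand)$rank == 1L]
    mcols(rank1)$id <- mcols(rank1)$mirna
    exportPromoters(inp$genome, rank1, cfg$promoter_length,
                    p("promoters_1000.fa"))
    exportPromoters(inp$genome, rank1, cfg$export_promoter_length,
                    p("promoters_long.fa"))
  }
  log0("predict-tss", length(cand), " candidates for ",
       length(unique(mcols(cand)$mirna)), " miRNAs")

  res <- list(cv = cv, model = model, candidates = cand)

  # --- coexpression + coTFBS + targets + network (optional inputs)
  if (!is.null(cfg$mirna_expr) && !is.null(cfg$gene_expr)) {
    mirnaExpr <- readExpressionMatrix(cfg$mirna_expr)
    geneExpr <- readExpressionMatrix(cfg$gene_expr)
    groups <- list()
    for (m in rownames(mirnaExpr)) {
      g <- suppressWarnings(
        coexpressedGroup(m, mirnaExpr, geneExpr,
                         method = cfg$coexpr_method,
                         threshold = cfg$coexpr_threshold,
                         minGenes = cfg$min_genes))
      if (!is.null(g) && nrow(g)) groups[[m]] <- g
    }
    groupTab <- do.call(rbind, lapply(names(groups), function(m)
      cbind(mirna = m, groups[[m]])))
    utils::write.table(groupTab, p("coexpression_groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log0("coexpress", length(groups), " groups")
    res$groups <- groups

    if (!is.null(cfg$pwms) && length(cand)) {
      pwms <- readPwms(cfg$pwms)
      rank1 <- cand[mcols(cand)$rank == 1L]
      tssByGene <- inp$tssRecords
      geneIds <- mcols(tssByGene)$name
      promotersByGroup <- list()
      for (m in names(groups)) {
        r1 <- rank1[mcols(rank1)$mirna == m]
        members <- intersect(groups[[m]]$gene, geneIds)
        anch <- c(if (length(r1)) granges(r1[1]) else GRanges(),
                  granges(tssByGene[match(members, geneIds)]))
        ids <- c(if (length(r1)) m else character(0), members)
        if (length(anch) == 0L) next
        mcols(anch)$id <- ids
        promotersByGroup[[m]] <-
          exportPromoters(inp$genome, anch, cfg$promoter_length)
      }
      if (length(promotersByGroup) >= 2L) {
        stats <- cotfbsStats(promotersByGroup, pwms,
                             cfg$core_threshold, cfg$matrix_threshold)
        utils::write.table(stats, p("cotfbs_stats.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        tfCand <- candidateTfs(stats, freqCutoff = cfg$freq_cutoff,
                               pCutoff = cfg$p_cutoff)
        utils::write.table(tfCand, p("candidate_tfs.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        log0("cotfbs", nrow(tfCand), " candidate TF relations")
        res$candidateTfs <- tfCand
      }
    }

    if (!is.null(cfg$mti)) {
      mtis <- mtiCorrelation(readMti(cfg$mti), mirnaExpr, geneExpr)
      utils::write.table(mtis, p("mti_correlations.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      edges <- if (!is.null(cfg$gene_graph)) readGeneGraph(cfg$gene_graph)
               else data.frame(from = character(), to = character())
      go <- if (!is.null(cfg$go)) readGoAnnotations(cfg$go) else NULL
      nets <- list()
      goRows <- list()
      for (m in unique(mtis$mirna)) {
        direct <- mtis$target[mtis$mirna == m]
        forest <- suppressWarnings(expandIndirectTargets(direct, edges))
        tfm <- NULL
        if (!is.null(res$candidateTfs)) {
          sel <- res$candidateTfs[res$candidateTfs$group == m, ,
                                  drop = FALSE]
          if (nrow(sel))
            tfm <- data.frame(tf = sel$pwm, mirna = m,
                              frequency = sel$frequency,
                              p_value = sel$p_value,
                              stringsAsFactors = FALSE)
        }
        net <- buildNetwork(tfm, mtis[mtis$mirna == m, , drop = FALSE],
                            forest)
        exportNetwork(net, p(paste0("network_", m, ".sif")), "sif")
        exportNetwork(net, p(paste0("network_", m, ".graphml")), "graphml")
        nets[[m]] <- net
        if (!is.null(go)) {
          mediated <- unique(c(direct, forest$indirect))
          enr <- tryCatch(
            goEnrichment(mediated, go, minTermSize = cfg$go_min_term_size,
                         adjust = cfg$go_adjust),
            error = function(e) NULL)
          if (!is.null(enr) && nrow(enr))
            goRows[[m]] <- cbind(mirna = m, enr)
        }
      }
      if (length(goRows))
        utils::write.table(do.call(rbind, goRows), p("go_enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      log0("network", length(nets), " miRNA networks")
      res$networks <- nets
    }
  }

  # --- manifest
  files <- setdiff(list.files(outDir, full.names = TRUE),
                   p("manifest.json"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  log0("done", length(files), " output files in ", outDir)
  invisible(res)
}
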