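# Seeded synthetic-data generator: emits every input the pipeline consumes
# (genome, annotations, verified TSSs, signal tracks, motif sites, PWMs,
# expression matrices, MTIs, gene graph, GO annotations) with planted ground
# truth, so the whole pipeline is testable without downloads.

#' Simulation configuration
#'
#' Bundles and validates every generator parameter. The defaults are sized
#' for desk-scale runs (2 chromosomes x 300 kb, 20 miRNAs, 500 genes, 11
#' developmental conditions) with strongly planted structure: Gaussian
#' signal enrichment (Poisson noise) at every true TSS, an H3 dip, core
#' promoter motifs concentrated within +/-100 bp of TSSs, one sharp planted
#' TF motif per coexpressed group inserted into most of the group's
#' promoters, negatively correlated planted miRNA targets, guaranteed
#' indirect-target chains and one enriched GO term.
#'
#' @param seed integer seed; every stage derives its RNG stream from it.
#' @param nChromosomes,chromosomeLength genome shape.
#' @param nMirnas number of pre-miRNAs (placed with >= 14 kb spacing).
#' @param intragenicFraction fraction of miRNAs embedded in host genes
#'   (rounded to a count).
#' @param nGenes,nVerifiedGenes annotated genes and the subset with a unique
#'   verified TSS record (these get signal bumps and serve as training
#'   positives and group promoters).
#' @param nConditions expression conditions (>= 5).
#' @param tssOffsetRange distance of a miRNA TSS upstream of its precursor
#'   5' end, sampled uniformly (bases).
#' @param trackParams per-track list: `background`, `height` (or `depth` for
#'   the H3 dip) and Gaussian `width` (sd, bases).
#' @param trackNoise `"poisson"` (default) or `"none"` (deterministic bump
#'   values).
#' @param motifNearProb,motifNearSites,motifBgRate core-motif placement:
#'   per-TSS probability and count within +/-100 bp, and background rate per
#'   base.
#' @param nTfs,nDecoyPwms,pwmLength,pwmDominant planted and decoy PWMs
#'   (sharp: dominant-base frequency `pwmDominant`).
#' @param plantRate fraction of a group's promoters receiving its TF's
#'   consensus site; `crossPlantRate` the rate elsewhere; `decoyPlantRate`
#'   the decoy insertion rate.
#' @param blockSize,coexprNoiseSd coexpression block size per miRNA group and
#'   the Gaussian noise sd around the shared latent profile.
#' @param nDirectTargets,mtiNoiseSd planted direct targets per group miRNA
#'   and the noise sd of their negated expression profiles.
#' @param chainLength guaranteed gene-graph chain length from each direct
#'   target.
#' @param edgeDensity,nGraphExtra Erdos-Renyi edge probability of the
#'   gene-gene graph and extra (non-planted) graph nodes.
#' @param nBgGoTerms,goBgRate,goPlantedShare background GO terms, their
#'   per-gene annotation rate, and the share of the miRNA-mediated gene set
#'   annotated with the planted term.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L,
                             nChromosomes = 2L,
                             chromosomeLength = 300000L,
                             nMirnas = 20L,
                             intragenicFraction = 0.15,
                             nGenes = 500L,
                             nVerifiedGenes = 150L,
                             nConditions = 11L,
                             tssOffsetRange = c(500L, 3000L),
                             trackParams = list(
                               tss_tags = list(background = 0.2, height = 30,
                                               width = 50),
                               h3k4me3 = list(background = 1, height = 20,
                                              width = 300),
                               h3k9ac = list(background = 1, height = 15,
                                             width = 200),
                               h3 = list(background = 8, depth = 7.5,
                                         width = 150)),
                             trackNoise = c("poisson", "none"),
                             motifNearProb = 0.9,
                             motifNearSites = 2L,
                             motifBgRate = 5e-4,
                             nTfs = 3L,
                             nDecoyPwms = 3L,
                             pwmLength = 10L,
                             pwmDominant = 0.91,
                             plantRate = 0.8,
                             crossPlantRate = 0.05,
                             decoyPlantRate = 0.05,
                             blockSize = 20L,
                             coexprNoiseSd = 0.1,
                             nDirectTargets = 3L,
                             mtiNoiseSd = 0.05,
                             chainLength = 3L,
                             edgeDensity = 0.03,
                             nGraphExtra = 40L,
                             nBgGoTerms = 20L,
                             goBgRate = 0.05,
                             goPlantedShare = 0.9) {
  cfg <- list(seed = as.integer(seed), nChromosomes = as.integer(nChromosomes),
              chromosomeLength = as.integer(chromosomeLength),
              nMirnas = as.integer(nMirnas),
              intragenicFraction = intragenicFraction,
              nGenes = as.integer(nGenes),
              nVerifiedGenes = as.integer(nVerifiedGenes),
              nConditions = as.integer(nConditions),
              tssOffsetRange = as.integer(tssOffsetRange),
              trackParams = trackParams,
              trackNoise = match.arg(trackNoise),
              motifNearProb = motifNearProb,
              motifNearSites = as.integer(motifNearSites),
              motifBgRate = motifBgRate, nTfs = as.integer(nTfs),
              nDecoyPwms = as.integer(nDecoyPwms),
              pwmLength = as.integer(pwmLength), pwmDominant = pwmDominant,
              plantRate = plantRate, crossPlantRate = crossPlantRate,
              decoyPlantRate = decoyPlantRate,
              blockSize = as.integer(blockSize),
              coexprNoiseSd = coexprNoiseSd,
              nDirectTargets = as.integer(nDirectTargets),
              mtiNoiseSd = mtiNoiseSd, chainLength = as.integer(chainLength),
              edgeDensity = edgeDensity, nGraphExtra = as.integer(nGraphExtra),
              nBgGoTerms = as.integer(nBgGoTerms), goBgRate = goBgRate,
              goPlantedShare = goPlantedShare)
  counts <- c(cfg$nChromosomes, cfg$chromosomeLength, cfg$nMirnas, cfg$nGenes,
              cfg$nVerifiedGenes, cfg$nConditions, cfg$nTfs, cfg$pwmLength,
              cfg$blockSize, cfg$nDirectTargets)
  if (any(counts <= 0)) stop("all counts must be positive")
  probs <- c(cfg$intragenicFraction, cfg$motifNearProb, cfg$plantRate,
             cfg$crossPlantRate, cfg$decoyPlantRate, cfg$edgeDensity,
             cfg$goBgRate, cfg$goPlantedShare, cfg$pwmDominant)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(c(cfg$coexprNoiseSd, cfg$mtiNoiseSd) < 0))
    stop("noise sd must be >= 0")
  if (cfg$nConditions < 5L) stop("need at least 5 conditions")
  if (cfg$nTfs * cfg$blockSize > cfg$nVerifiedGenes)
    stop("nVerifiedGenes must cover nTfs * blockSize group genes")
  structure(cfg, class = "SimulationConfig")
}

# Deterministic (seed-free) planted design: id spaces and group/target/graph
# membership, shared by every stage.
.plantedDesign <- function(cfg) {
  mirnas <- sprintf("mir%03d", seq_len(cfg$nMirnas))
  genes <- sprintf("g%04d", seq_len(cfg$nGenes))
  verified <- genes[seq_len(cfg$nVerifiedGenes)]
  groups <- lapply(seq_len(cfg$nTfs), function(i)
    list(mirna = mirnas[i],
         genes = verified[((i - 1) * cfg$blockSize + 1):(i * cfg$blockSize)]))
  names(groups) <- mirnas[seq_len(cfg$nTfs)]
  # direct targets and chain genes from the non-verified tail of the genes
  tail0 <- cfg$nVerifiedGenes
  nT <- cfg$nTfs * cfg$nDirectTargets
  targets <- genes[tail0 + seq_len(nT)]
  chains <- genes[tail0 + nT + seq_len(nT * cfg$chainLength)]
  mtis <- do.call(rbind, lapply(seq_len(cfg$nTfs), function(i) {
    tg <- targets[((i - 1) * cfg$nDirectTargets + 1):(i * cfg$nDirectTargets)]
    data.frame(mirna = mirnas[i], target = tg,
               evidence = c("verified",
                            rep("putative", cfg$nDirectTargets - 1L)),
               source = c("sim_verified_db",
                          rep("sim_prediction", cfg$nDirectTargets - 1L)),
               stringsAsFactors = FALSE)
  }))
  chainOf <- split(chains, rep(targets, each = cfg$chainLength))
  graphExtra <- genes[tail0 + nT + nT * cfg$chainLength +
                        seq_len(min(cfg$nGraphExtra,
                                    cfg$nGenes - tail0 - nT -
                                      nT * cfg$chainLength))]
  tfs <- sprintf("TF%02d", seq_len(cfg$nTfs))
  decoys <- sprintf("decoy%02d", seq_len(cfg$nDecoyPwms))
  mediated <- c(mtis$target[mtis$mirna == mirnas[1]],
                unlist(chainOf[mtis$target[mtis$mirna == mirnas[1]]],
                       use.names = FALSE))
  list(mirnas = mirnas, genes = genes, verified = verified, groups = groups,
       targets = targets, chainOf = chainOf, graphExtra = graphExtra,
       tfs = tfs, decoys = decoys, mtis = mtis, mediated = mediated)
}

.simSeed <- function(cfg, offset) (cfg$seed %% 2000000000L) + offset

#' Simulate the genome, annotations and verified TSSs
#'
#' Draws an i.i.d. uniform background genome, places pre-miRNA loci with
#' >= 14 kb spacing (each with a true TSS 500-3000 bp upstream of the
#' precursor 5' end), flags a configurable fraction as intragenic inside
#' dedicated host genes (whose TSS is the miRNA's true TSS), and places the
#' verified-TSS gene subset on a spaced grid away from all miRNA scan
#' windows. Deterministic for a fixed seed.
#'
#' @param config a [simulationConfig()].
#' @return list with `genome` (`DNAStringSet`), `mirnas` (`GRanges` with
#'   `id`, `intragenic`, `host_gene`), `genes` (`GRanges` with `id`),
#'   `tssRecords` (`GRanges` of verified gene TSSs with `gene`, `name`), and
#'   `truth` (`trueTss` `GRanges` with `mirna`).
#' @export
simulateGenomeAndAnnotations <- function(config) {
  cfg <- config
  d <- .plantedDesign(cfg)
  set.seed(.simSeed(cfg, 0L))
  chroms <- sprintf("Chr%d", seq_len(cfg$nChromosomes))
  lens <- stats::setNames(rep(cfg$chromosomeLength, cfg$nChromosomes), chroms)
  genomeChr <- vapply(chroms, function(s)
    paste(sample(c("A", "C", "G", "T"), cfg$chromosomeLength,
                 replace = TRUE), collapse = ""), character(1))
  # --- pre-miRNA placement
  perChr <- diff(round(seq(0, cfg$nMirnas, length.out = cfg$nChromosomes + 1)))
  nIntra <- round(cfg$intragenicFraction * cfg$nMirnas)
  mirRows <- list()
  mi <- 0L
  for (ci in seq_len(cfg$nChromosomes)) {
    m <- perChr[ci]
    if (m == 0L) next
    slot <- (cfg$chromosomeLength - 28000L) %/% m
    if (slot < 14000L)
      stop("pre-miRNA loci cannot fit with the required spacing; ",
           "use longer chromosomes or fewer miRNAs")
    for (j in seq_len(m)) {
      mi <- mi + 1L
      jitter <- if (slot > 14000L) sample.int(slot - 14000L, 1L) else 0L
      s <- 14000L + (j - 1L) * slot + jitter
      preLen <- sample(80:250, 1L)
      str <- sample(c("+", "-"), 1L)
      mirRows[[mi]] <- data.frame(seqid = chroms[ci], start = s,
                                  end = s + preLen - 1L, strand = str,
                                  id = d$mirnas[mi],
                                  stringsAsFactors = FALSE)
    }
  }
  mir <- do.call(rbind, mirRows)
  intraIdx <- if (nIntra > 0L) seq(cfg$nMirnas - nIntra + 1L, cfg$nMirnas)
              else integer(0)
  mir$intragenic <- seq_len(cfg$nMirnas) %in% intraIdx
  mir$host_gene <- ifelse(mir$intragenic,
                          sprintf("host_%s", mir$id), NA_character_)
  # true TSSs
  off <- sample(cfg$tssOffsetRange[1]:cfg$tssOffsetRange[2], cfg$nMirnas,
                replace = TRUE)
  tssPos <- ifelse(mir$strand == "+", mir$start - off, mir$end + off)
  trueTss <- GRanges(mir$seqid, IRanges(tssPos, width = 1L),
                     strand = mir$strand)
  mcols(trueTss)$mirna <- mir$id
  # --- verified genes on a spaced grid away from miRNA scan windows
  anchor5 <- ifelse(mir$strand == "+", mir$start, mir$end)
  # keep gene TSS signal out of each miRNA's scan window (10 kb upstream of
  # the precursor 5' end, strand-aware) plus a bump-width margin
  forb <- GRanges(mir$seqid,
                  IRanges(pmax(1L, ifelse(mir$strand == "+",
                                          anchor5 - 11500L,
                                          anchor5 - 1500L)),
                          ifelse(mir$strand == "+",
                                 anchor5 + 1500L, anchor5 + 11500L)))
  grid <- do.call(rbind, lapply(chroms, function(s) {
    p <- seq(3000L, cfg$chromosomeLength - 3000L, by = 1500L)
    data.frame(seqid = s, pos = p, stringsAsFactors = FALSE)
  }))
  gridGr <- GRanges(grid$seqid, IRanges(grid$pos, width = 1L))
  free <- grid[countOverlaps(gridGr, forb) == 0L, ]
  if (nrow(free) < cfg$nVerifiedGenes)
    stop("not enough space for verified gene TSSs; use longer chromosomes")
  sel <- free[round(seq(1, nrow(free),
                        length.out = cfg$nVerifiedGenes)), ]
  vStrand <- sample(c("+", "-"), cfg$nVerifiedGenes, replace = TRUE)
  vPos <- sel$pos + sample(-400:400, cfg$nVerifiedGenes, replace = TRUE)
  geneRows <- data.frame(seqid = sel$seqid,
                         start = ifelse(vStrand == "+", vPos, vPos - 1500L),
                         end = ifelse(vStrand == "+", vPos + 1500L, vPos),
                         strand = vStrand, id = d$verified,
                         stringsAsFactors = FALSE)
  tssRecords <- GRanges(sel$seqid, IRanges(vPos, width = 1L),
                        strand = vStrand)
  mcols(tssRecords)$gene <- d$verified
  mcols(tssRecords)$name <- d$verified
  # --- remaining genes anywhere (annotation only, no signal)
  nOther <- cfg$nGenes - cfg$nVerifiedGenes
  if (nOther > 0L) {
    oChr <- sample(chroms, nOther, replace = TRUE)
    oPos <- sample(2000:(cfg$chromosomeLength - 3000L), nOther,
                   replace = TRUE)
    geneRows <- rbind(geneRows,
                      data.frame(seqid = oChr, start = oPos,
                                 end = oPos + 1000L,
                                 strand = sample(c("+", "-"), nOther,
                                                 replace = TRUE),
                                 id = d$genes[(cfg$nVerifiedGenes + 1L):
                                                cfg$nGenes],
                                 stringsAsFactors = FALSE))
  }
  # --- host genes of intragenic miRNAs: span the precursor; the host TSS is
  # the miRNA's true TSS and gets a verified record
  if (nIntra > 0L) {
    hi <- intraIdx
    hostRows <- data.frame(seqid = mir$seqid[hi],
                           start = ifelse(mir$strand[hi] == "+",
                                          tssPos[hi], mir$start[hi] - 500L),
                           end = ifelse(mir$strand[hi] == "+",
                                        mir$end[hi] + 500L, tssPos[hi]),
                           strand = mir$strand[hi],
                           id = mir$host_gene[hi], stringsAsFactors = FALSE)
    geneRows <- rbind(geneRows, hostRows)
    hostTss <- GRanges(mir$seqid[hi], IRanges(tssPos[hi], width = 1L),
                       strand = mir$strand[hi])
    mcols(hostTss)$gene <- mir$host_gene[hi]
    mcols(hostTss)$name <- mir$host_gene[hi]
    tssRecords <- c(tssRecords, hostTss)
  }
  genome <- DNAStringSet(genomeChr)
  names(genome) <- chroms
  mirGr <- GRanges(mir$seqid, IRanges(mir$start, mir$end),
                   strand = mir$strand,
                   seqlengths = lens)
  mcols(mirGr) <- DataFrame(id = mir$id, intragenic = mir$intragenic,
                            host_gene = mir$host_gene)
  geneGr <- GRanges(geneRows$seqid, IRanges(geneRows$start, geneRows$end),
                    strand = geneRows$strand, seqlengths = lens)
  mcols(geneGr) <- DataFrame(id = geneRows$id)
  list(genome = genome, mirnas = mirGr, genes = geneGr,
       tssRecords = tssRecords,
       truth = list(trueTss = trueTss))
}

# Gaussian bump values added in place around centers.
.addBumps <- function(lambda, centers, height, width) {
  hw <- ceiling(4 * width)
  for (c0 in centers) {
    from <- max(1L, c0 - hw)
    to <- min(length(lambda), c0 + hw)
    x <- from:to
    lambda[x] <- lambda[x] + height * exp(-(x - c0)^2 / (2 * width^2))
  }
  lambda
}

#' Simulate signal tracks and core promoter motif sites
#'
#' Plants Gaussian enrichment centered at every true TSS (miRNA TSSs and
#' verified gene TSSs) for TSS tags, H3K4me3 and H3K9ac; nucleosome H3 is a
#' baseline minus a bump, floored at 0 (the TSS dip). Per-base values are
#' Poisson draws around those intensities (or the intensities themselves
#' with `trackNoise = "none"`). Core promoter motif sites (Y patch, Inr, CA,
#' GA, REG) are placed at an elevated rate within +/-100 bp of true TSSs and
#' at a background rate elsewhere.
#'
#' @param config a [simulationConfig()].
#' @param ann result of [simulateGenomeAndAnnotations()].
#' @return list with `tracks` (named list of 4 [SignalTrack-class]) and
#'   `motifs` (named list of 5 `GRanges` with `motif_class`).
#' @export
simulateSignalTracks <- function(config, ann) {
  cfg <- config
  set.seed(.simSeed(cfg, 1L))
  lens <- genomeLengths(ann$genome)
  anchors <- c(granges(ann$truth$trueTss), granges(ann$tssRecords))
  anchorPos <- split(start(anchors), as.character(seqnames(anchors)))
  tracks <- list()
  for (tn in names(cfg$trackParams)) {
    tp <- cfg$trackParams[[tn]]
    vals <- lapply(names(lens), function(s) {
      lambda <- rep(tp$background, lens[s])
      ctr <- anchorPos[[s]]
      if (!is.null(ctr)) {
        if (!is.null(tp$depth)) {
          lambda <- .addBumps(lambda, ctr, -tp$depth, tp$width)
          lambda <- pmax(lambda, 0)
        } else {
          lambda <- .addBumps(lambda, ctr, tp$height, tp$width)
        }
      }
      if (cfg$trackNoise == "poisson") Rle(as.numeric(rpois(lens[s], lambda)))
      else Rle(lambda)
    })
    names(vals) <- names(lens)
    tracks[[tn]] <- SignalTrack(tn, vals)
  }
  motifClasses <- c("Y_patch", "Inr", "CA", "GA", "REG")
  motifs <- lapply(motifClasses, function(mc) {
    rows <- list()
    for (s in names(lens)) {
      nBg <- rpois(1L, cfg$motifBgRate * lens[s])
      bg <- sort(sample.int(lens[s] - 6L, nBg))
      rows[[s]] <- data.frame(seqid = s, start = bg,
                              stringsAsFactors = FALSE)
    }
    near <- lapply(seq_along(anchors), function(i) {
      if (stats::runif(1) > cfg$motifNearProb) return(NULL)
      p <- start(anchors)[i] + sample(-100:100, cfg$motifNearSites,
                                      replace = TRUE)
      data.frame(seqid = as.character(seqnames(anchors))[i], start = p,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, c(rows, near[!vapply(near, is.null, logical(1))]))
    tab <- tab[tab$start >= 1 & tab$start <= lens[tab$seqid] - 6L, ]
    gr <- GRanges(tab$seqid, IRanges(tab$start, width = 6L))
    mcols(gr)$motif_class <- mc
    sort(gr)
  })
  names(motifs) <- motifClasses
  list(tracks = tracks, motifs = motifs)
}

#' Simulate miRNA and gene expression matrices
#'
#' Each planted coexpression block shares its miRNA's latent condition
#' profile plus Gaussian noise (`coexprNoiseSd`); planted direct targets get
#' the negated miRNA profile plus noise (`mtiNoiseSd`); every other entity is
#' an independent standard normal profile. Values are on a log-intensity
#' scale.
#'
#' @param config a [simulationConfig()].
#' @return list with matrices `mirnaExpr` and `geneExpr` (conditions
#'   `stage01`, ...).
#' @export
simulateExpression <- function(config) {
  cfg <- config
  d <- .plantedDesign(cfg)
  set.seed(.simSeed(cfg, 2L))
  conds <- sprintf("stage%02d", seq_len(cfg$nConditions))
  mirnaExpr <- matrix(rnorm(cfg$nMirnas * cfg$nConditions),
                      nrow = cfg$nMirnas,
                      dimnames = list(d$mirnas, conds))
  geneExpr <- matrix(rnorm(cfg$nGenes * cfg$nConditions),
                     nrow = cfg$nGenes,
                     dimnames = list(d$genes, conds))
  for (g in d$groups) {
    prof <- mirnaExpr[g$mirna, ]
    for (gn in g$genes)
      geneExpr[gn, ] <- prof + rnorm(cfg$nConditions, sd = cfg$coexprNoiseSd)
  }
  for (i in seq_len(nrow(d$mtis))) {
    prof <- mirnaExpr[d$mtis$mirna[i], ]
    geneExpr[d$mtis$target[i], ] <-
      -prof + rnorm(cfg$nConditions, sd = cfg$mtiNoiseSd)
  }
  list(mirnaExpr = mirnaExpr, geneExpr = geneExpr)
}

# Sharp PWM around a consensus: dominant base frequency `dom`, rest split.
.consensusPwm <- function(consensus, dom) {
  L <- nchar(consensus)
  m <- matrix((1 - dom) / 3, nrow = 4, ncol = L,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  b <- strsplit(consensus, "")[[1]]
  m[cbind(match(b, rownames(m)), seq_len(L))] <- dom
  m
}

.revcompChr <- function(x)
  as.character(reverseComplement(DNAString(x)))

# Insert `site` into the promoter of a TSS (strand-aware) inside a character
# genome; offset is promoter-relative (1 = 1000 bp upstream of the TSS).
.plantSite <- function(genomeChr, seqid, tssPos, strand, site, offset,
                       promoterLength = 1000L) {
  L <- nchar(site)
  if (strand == "+") {
    from <- tssPos - promoterLength - 1L + offset
    substr(genomeChr[[seqid]], from, from + L - 1L) <- site
  } else {
    to <- tssPos + promoterLength + 1L - offset
    substr(genomeChr[[seqid]], to - L + 1L, to) <- .revcompChr(site)
  }
  genomeChr
}

#' Simulate the trans-regulatory layer
#'
#' Builds the planted and decoy PWMs, inserts each planted TF's consensus
#' site into most (`plantRate`) of its group's promoters in the genome
#' (miRNA promoter plus the coexpression block genes' promoters; elsewhere at
#' `crossPlantRate`), emits the planted MTI table, a directed gene-gene
#' interaction graph (Erdos-Renyi at `edgeDensity` plus guaranteed chains of
#' `chainLength` genes from every direct target, occasional self-loops), and
#' GO annotations in which the planted term covers `goPlantedShare` of the
#' first miRNA's mediated gene set against `nBgGoTerms` background terms.
#'
#' @param config a [simulationConfig()].
#' @param ann result of [simulateGenomeAndAnnotations()]; its genome is
#'   modified and returned.
#' @return list with `genome` (sites planted), `pwms`, `groups` (per-miRNA
#'   member gene ids), `mtis`, `geneEdges`, `goAnnotations`, and `truth`
#'   (`plantedTfs` `data.frame(tf, mirna)`, `goTerm`, `mediated`,
#'   `plantedSites`).
#' @export
simulateRegulatoryLayer <- function(config, ann) {
  cfg <- config
  d <- .plantedDesign(cfg)
  set.seed(.simSeed(cfg, 3L))
  if (cfg$pwmLength > 900L) stop("consensus longer than the promoter")
  bases <- c("A", "C", "G", "T")
  consensi <- vapply(seq_len(cfg$nTfs + cfg$nDecoyPwms), function(i)
    paste(sample(bases, cfg$pwmLength, replace = TRUE), collapse = ""),
    character(1))
  pwms <- lapply(consensi, .consensusPwm, dom = cfg$pwmDominant)
  names(pwms) <- c(d$tfs, d$decoys)
  genomeChr <- as.list(as.character(ann$genome))
  tssOf <- ann$tssRecords
  tssGenes <- mcols(tssOf)$gene
  trueTss <- ann$truth$trueTss
  groupTss <- lapply(d$groups, function(g) {
    gi <- match(g$genes, tssGenes)
    data.frame(id = c(g$mirna, g$genes),
               seqid = c(as.character(seqnames(trueTss))[
                 match(g$mirna, mcols(trueTss)$mirna)],
                 as.character(seqnames(tssOf))[gi]),
               pos = c(start(trueTss)[match(g$mirna, mcols(trueTss)$mirna)],
                       start(tssOf)[gi]),
               strand = c(as.character(strand(trueTss))[
                 match(g$mirna, mcols(trueTss)$mirna)],
                 as.character(strand(tssOf))[gi]),
               stringsAsFactors = FALSE)
  })
  plantedRows <- list()
  for (gi in seq_len(cfg$nTfs)) {
    tf <- d$tfs[gi]
    cons <- consensi[gi]
    for (gj in seq_len(cfg$nTfs)) {
      gt <- groupTss[[gj]]
      nPlant <- if (gi == gj) round(cfg$plantRate * nrow(gt)) else 0L
      pick <- if (gi == gj) sample.int(nrow(gt), nPlant) else
        which(stats::runif(nrow(gt)) < cfg$crossPlantRate)
      for (r in pick) {
        off <- sample(100:(900 - cfg$pwmLength), 1L)
        genomeChr <- .plantSite(genomeChr, gt$seqid[r], gt$pos[r],
                                gt$strand[r], cons, off)
        plantedRows[[length(plantedRows) + 1L]] <-
          data.frame(tf = tf, promoter = gt$id[r], group = names(d$groups)[gj],
                     offset = off, stringsAsFactors = FALSE)
      }
    }
  }
  # decoy sites at background rate across all group promoters
  allTss <- do.call(rbind, groupTss)
  for (di in seq_len(cfg$nDecoyPwms)) {
    cons <- consensi[cfg$nTfs + di]
    pick <- which(stats::runif(nrow(allTss)) < cfg$decoyPlantRate)
    for (r in pick) {
      off <- sample(100:(900 - cfg$pwmLength), 1L)
      genomeChr <- .plantSite(genomeChr, allTss$seqid[r], allTss$pos[r],
                              allTss$strand[r], cons, off)
    }
  }
  genome <- DNAStringSet(unlist(genomeChr))
  names(genome) <- names(ann$genome)
  # --- gene-gene interaction graph
  chainEdges <- do.call(rbind, lapply(names(d$chainOf), function(tg) {
    path <- c(tg, d$chainOf[[tg]])
    data.frame(from = path[-length(path)], to = path[-1],
               stringsAsFactors = FALSE)
  }))
  nodes <- unique(c(d$targets, unlist(d$chainOf, use.names = FALSE),
                    d$graphExtra))
  nn <- length(nodes)
  rnd <- which(matrix(stats::runif(nn * nn) < cfg$edgeDensity, nn, nn),
               arr.ind = TRUE)
  rndEdges <- data.frame(from = nodes[rnd[, 1]], to = nodes[rnd[, 2]],
                         stringsAsFactors = FALSE)
  selfLoops <- data.frame(from = nodes[stats::runif(nn) < 0.02],
                          stringsAsFactors = FALSE)
  selfLoops$to <- selfLoops$from
  geneEdges <- unique(rbind(chainEdges, rndEdges, selfLoops))
  rownames(geneEdges) <- NULL
  # --- GO annotations
  goTerm <- "GO:PL00001"
  nPl <- round(cfg$goPlantedShare * length(d$mediated))
  planted <- data.frame(gene = d$mediated[seq_len(nPl)], term = goTerm,
                        term_name = "planted process",
                        stringsAsFactors = FALSE)
  bgRows <- lapply(seq_len(cfg$nBgGoTerms), function(i) {
    hit <- d$genes[stats::runif(cfg$nGenes) < cfg$goBgRate]
    if (length(hit) == 0L) return(NULL)
    data.frame(gene = hit, term = sprintf("GO:BG%05d", i),
               term_name = sprintf("background process %d", i),
               stringsAsFactors = FALSE)
  })
  goAnnotations <- do.call(rbind, c(list(planted),
                                    bgRows[!vapply(bgRows, is.null,
                                                   logical(1))]))
  groups <- lapply(d$groups, function(g) g$genes)
  list(genome = genome, pwms = pwms, groups = groups, mtis = d$mtis,
       geneEdges = geneEdges, goAnnotations = goAnnotations,
       truth = list(plantedTfs = data.frame(tf = d$tfs,
                                            mirna = names(d$groups),
                                            stringsAsFactors = FALSE),
                    goTerm = goTerm, mediated = d$mediated,
                    plantedSites = do.call(rbind, plantedRows)))
}

#' Group promoters extracted at the simulated true TSSs
#'
#' For each planted coexpressed group, extracts the 1000-bp promoters of the
#' miRNA (at its true TSS) and of the group's genes (at their verified TSS
#' records) from the simulated genome — the input of [cotfbsStats()] when
#' validating coTFBS recovery against ground truth.
#'
#' @param ann result of [simulateGenomeAndAnnotations()].
#' @param reg result of [simulateRegulatoryLayer()] (its genome carries the
#'   planted sites).
#' @param length promoter length (default 1000).
#' @return named list (per miRNA group) of promoter `DNAStringSet`s.
#' @export
simulatedGroupPromoters <- function(ann, reg, length = 1000L) {
  tt <- ann$truth$trueTss
  geneIds <- mcols(ann$tssRecords)$gene
  out <- lapply(names(reg$groups), function(m) {
    genes <- reg$groups[[m]]
    gi <- match(genes, geneIds)
    anch <- suppressWarnings(c(granges(tt[mcols(tt)$mirna == m]),
                               granges(ann$tssRecords[gi])))
    mcols(anch)$id <- c(m, genes)
    exportPromoters(reg$genome, anch, length)
  })
  names(out) <- names(reg$groups)
  out
}

#' Run every simulation stage (and optionally write all input files)
#'
#' @param config a [simulationConfig()].
#' @param outDir optional directory; when given, every pipeline input is
#'   written in its standard format (FASTA, GFF3, BED, bedGraph, JASPAR,
#'   TSV) plus `ground_truth.json`.
#' @return list with all in-memory objects: `genome`, `mirnas`, `genes`,
#'   `tssRecords`, `tracks`, `motifs`, `mirnaExpr`, `geneExpr`, `pwms`,
#'   `groups`, `mtis`, `geneEdges`, `goAnnotations`, `truth`.
#' @export
simulateAll <- function(config, outDir = NULL) {
  ann <- simulateGenomeAndAnnotations(config)
  reg <- simulateRegulatoryLayer(config, ann)
  ann$genome <- reg$genome
  sig <- simulateSignalTracks(config, ann)
  expr <- simulateExpression(config)
  truth <- c(ann$truth, reg$truth)
  sim <- list(genome = ann$genome, mirnas = ann$mirnas, genes = ann$genes,
              tssRecords = ann$tssRecords, tracks = sig$tracks,
              motifs = sig$motifs, mirnaExpr = expr$mirnaExpr,
              geneExpr = expr$geneExpr, pwms = reg$pwms,
              groups = reg$groups, mtis = reg$mtis,
              geneEdges = reg$geneEdges,
              goAnnotations = reg$goAnnotations, truth = truth,
              config = config)
  if (!is.null(outDir)) writeSimulation(sim, outDir)
  sim
}

#' Write a simulation to disk in the pipeline's input formats
#'
#' @param sim result of [simulateAll()].
#' @param outDir output directory (created if missing).
#' @return named character vector of the written file paths, invisibly.
#' @export
writeSimulation <- function(sim, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outDir, f)
  writeXStringSet(sim$genome, p("genome.fa"))
  # GFF3: genes + miRNA precursors (host gene carried as an attribute)
  geneGff <- sim$genes
  mcols(geneGff) <- DataFrame(type = "gene", ID = mcols(sim$genes)$id,
                              Name = mcols(sim$genes)$id,
                              host_gene = NA_character_)
  mirGff <- sim$mirnas
  mcols(mirGff) <- DataFrame(type = "miRNA_primary_transcript",
                             ID = mcols(sim$mirnas)$id,
                             Name = mcols(sim$mirnas)$id,
                             host_gene = ifelse(sim$mirnas$intragenic,
                                                sim$mirnas$host_gene, NA))
  rtracklayer::export(c(geneGff, mirGff), p("annotations.gff3"),
                      format = "gff3")
  tssBed <- sim$tssRecords
  mcols(tssBed) <- DataFrame(name = mcols(sim$tssRecords)$gene)
  writeBedSites(tssBed, p("tss_records.bed"))
  for (tn in names(sim$tracks))
    writeSignalBedGraph(sim$tracks[[tn]], p(paste0(tn, ".bedgraph")))
  for (mc in names(sim$motifs))
    writeBedSites(sim$motifs[[mc]], p(paste0("motif_", mc, ".bed")))
  writePwmsJaspar(sim$pwms, p("pwms.jaspar"))
  writeExpressionMatrix(sim$mirnaExpr, p("mirna_expr.tsv"))
  writeExpressionMatrix(sim$geneExpr, p("gene_expr.tsv"))
  utils::write.table(sim$mtis, p("mti.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$geneEdges, p("gene_graph.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$goAnnotations, p("go_annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tt <- sim$truth$trueTss
  jsonlite::write_json(
    list(true_tss = data.frame(mirna = mcols(tt)$mirna,
                               seqid = as.character(seqnames(tt)),
                               pos = start(tt),
                               strand = as.character(strand(tt))),
         planted_tfs = sim$truth$plantedTfs,
         mtis = sim$mtis,
         groups = sim$groups,
         go_term = sim$truth$goTerm,
         mediated = sim$truth$mediated),
    p("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  files <- list.files(outDir, full.names = TRUE)
  invisible(stats::setNames(files, basename(files)))
}
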