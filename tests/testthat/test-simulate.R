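test_that("configuration validation rejects impossible parameters", {
  expect_error(simulationConfig(nMirnas = 0), "positive")
  expect_error(simulationConfig(plantRate = 1.5), "probabilities")
  expect_error(simulationConfig(coexprNoiseSd = -1), "noise sd")
  expect_error(simulationConfig(nConditions = 3), "at least 5")
  expect_error(simulationConfig(nVerifiedGenes = 10, nTfs = 3,
                                blockSize = 20), "cover")
})

test_that("loci that cannot fit with the required spacing are an error", {
  expect_error(simulateGenomeAndAnnotations(
    smallSimConfig(nMirnas = 30)), "longer chromosomes")
})

test_that("simulation is fully deterministic for a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulateAll(smallSimConfig(seed = 5), outDir = d1)
  simulateAll(smallSimConfig(seed = 5), outDir = d2)
  f1 <- list.files(d1)
  expect_true(length(f1) >= 10)
  expect_setequal(f1, list.files(d2))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  simulateAll(smallSimConfig(seed = 6), outDir = d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "genome.fa"))),
                         unname(tools::md5sum(file.path(d3, "genome.fa")))))
})

test_that("the intragenic fraction is honored by deterministic rounding", {
  cfg <- simulationConfig(seed = 2, nChromosomes = 2L,
                          chromosomeLength = 600000L, nMirnas = 40L,
                          intragenicFraction = 0.15)
  ann <- simulateGenomeAndAnnotations(cfg)
  expect_equal(sum(S4Vectors::mcols(ann$mirnas)$intragenic), 6L)
  # intragenic = TRUE iff a host gene is recorded
  m <- S4Vectors::mcols(ann$mirnas)
  expect_identical(m$intragenic, !is.na(m$host_gene))
  # every host gene has a verified TSS at the miRNA's true TSS
  hosts <- m$host_gene[m$intragenic]
  rec <- S4Vectors::mcols(ann$tssRecords)$gene
  expect_true(all(hosts %in% rec))
  tt <- ann$truth$trueTss
  hostPos <- GenomicRanges::start(ann$tssRecords)[match(hosts, rec)]
  expect_equal(hostPos,
               GenomicRanges::start(tt)[m$intragenic])
})

test_that("pre-miRNA loci respect spacing and upstream room", {
  ann <- simulateGenomeAndAnnotations(smallSimConfig(seed = 4))
  for (s in unique(as.character(GenomicRanges::seqnames(ann$mirnas)))) {
    onS <- ann$mirnas[as.character(GenomicRanges::seqnames(ann$mirnas)) == s]
    st <- sort(GenomicRanges::start(onS))
    if (length(st) > 1) expect_true(all(diff(st) >= 12000))
  }
  # every true TSS lies 500-3000 bp upstream of its precursor 5' end
  tt <- ann$truth$trueTss
  m5 <- ifelse(as.character(GenomicRanges::strand(ann$mirnas)) == "+",
               GenomicRanges::start(ann$mirnas),
               GenomicRanges::end(ann$mirnas))
  d <- abs(GenomicRanges::start(tt) - m5)
  expect_true(all(d >= 500 & d <= 3000))
})

test_that("noise-free tracks equal the planted bump intensities", {
  cfg <- smallSimConfig(seed = 9, trackNoise = "none",
                        trackParams = list(
                          tss_tags = list(background = 0, height = 30,
                                          width = 50),
                          h3 = list(background = 8, depth = 7.5,
                                    width = 150)))
  ann <- simulateGenomeAndAnnotations(cfg)
  sig <- simulateSignalTracks(cfg, ann)
  tt <- ann$truth$trueTss[1]
  s <- as.character(GenomicRanges::seqnames(tt))
  pos <- GenomicRanges::start(tt)
  v <- as.numeric(S4Vectors::runValue(
    IRanges::Views(trackValues(sig$tracks$tss_tags)[[s]], pos, pos)[[1]]))
  vAt <- as.numeric(trackValues(sig$tracks$tss_tags)[[s]][pos])
  # zero background, noise off: the center base is exactly the bump height
  # (neighboring anchors are kilobases away; their tails are < 1e-6)
  expect_equal(vAt, 30, tolerance = 1e-4)
  offPeak <- as.numeric(trackValues(sig$tracks$tss_tags)[[s]][pos + 5000])
  expect_lt(offPeak, 1e-6)
  # H3 dips at the TSS and returns to baseline far away
  h3At <- as.numeric(trackValues(sig$tracks$h3)[[s]][pos])
  expect_equal(h3At, 0.5, tolerance = 1e-3)
  h3Far <- as.numeric(trackValues(sig$tracks$h3)[[s]][pos + 5000])
  expect_equal(h3Far, 8, tolerance = 1e-3)
})

test_that("noise-free expression reproduces planted correlations exactly", {
  cfg <- smallSimConfig(seed = 3, coexprNoiseSd = 0, mtiNoiseSd = 0)
  ex <- simulateExpression(cfg)
  expect_equal(pcc(ex$geneExpr["g0001", ], ex$mirnaExpr["mir001", ]), 1.0)
  # first planted target of mir001
  d <- simulateRegulatoryLayer(cfg, simulateGenomeAndAnnotations(cfg))
  tg <- d$mtis$target[d$mtis$mirna == "mir001"][1]
  expect_equal(pcc(ex$geneExpr[tg, ], ex$mirnaExpr["mir001", ]), -1.0)
})

test_that("planted TF sites are recoverable at their planted offsets", {
  cfg <- smallSimConfig(seed = 12)
  ann <- simulateGenomeAndAnnotations(cfg)
  reg <- simulateRegulatoryLayer(cfg, ann)
  proms <- simulatedGroupPromoters(ann, reg)
  sites <- reg$truth$plantedSites
  # check the first planted site of each TF
  for (tf in unique(sites$tf)) {
    row <- sites[sites$tf == tf, ][1, ]
    prom <- proms[[row$group]][[row$promoter]]
    hits <- scanPromoter(prom, reg$pwms[tf])
    expect_true(any(hits$offset == row$offset & hits$strand == "+"),
                label = paste(tf, "site at planted offset"))
  }
})

test_that("guaranteed chains from direct targets are reachable", {
  cfg <- smallSimConfig(seed = 8)
  ann <- simulateGenomeAndAnnotations(cfg)
  reg <- simulateRegulatoryLayer(cfg, ann)
  direct <- reg$mtis$target[reg$mtis$mirna == "mir001"]
  f <- suppressWarnings(expandIndirectTargets(direct, reg$geneEdges))
  mediated <- setdiff(reg$truth$mediated, direct)
  expect_true(all(mediated %in% f$indirect))
})

test_that("written files re-read into equivalent objects", {
  d <- withr::local_tempdir()
  sim <- simulateAll(smallSimConfig(seed = 5), outDir = d)
  g <- readGenomeFasta(file.path(d, "genome.fa"))
  expect_equal(genomeLengths(g), genomeLengths(sim$genome))
  mir <- readMirnaAnnotations(file.path(d, "annotations.gff3"))
  expect_equal(sort(S4Vectors::mcols(mir)$id),
               sort(S4Vectors::mcols(sim$mirnas)$id))
  expect_equal(sum(S4Vectors::mcols(mir)$intragenic),
               sum(S4Vectors::mcols(sim$mirnas)$intragenic))
  tr <- readSignalBedGraph(file.path(d, "tss_tags.bedgraph"),
                           genomeLengths(g), "tss_tags")
  expect_equal(as.numeric(trackValues(tr)$Chr1),
               as.numeric(trackValues(sim$tracks$tss_tags)$Chr1))
  pw <- readPwms(file.path(d, "pwms.jaspar"))
  expect_setequal(names(pw), names(sim$pwms))
  expect_equal(pw$TF01, sim$pwms$TF01, tolerance = 1e-9,
               ignore_attr = TRUE)
  ex <- readExpressionMatrix(file.path(d, "mirna_expr.tsv"))
  expect_equal(dim(ex), dim(sim$mirnaExpr))
  expect_equal(ex["mir001", ], sim$mirnaExpr["mir001", ],
               tolerance = 1e-9)
  mt <- readMti(file.path(d, "mti.tsv"))
  expect_equal(nrow(mt), nrow(sim$mtis))
  truth <- jsonlite::read_json(file.path(d, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$go_term, sim$truth$goTerm)
  expect_equal(nrow(truth$true_tss), length(sim$truth$trueTss))
})
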