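# Shared toy feature data: two Gaussian clouds, separable at will.
makeToySet <- function(nPos = 30, nNeg = 30, shift = 4, nBins = 10,
                       seed = 1) {
  set.seed(seed)
  pos <- matrix(rnorm(nPos * nBins, mean = shift), nrow = nPos)
  neg <- matrix(rnorm(nNeg * nBins), nrow = nNeg)
  rownames(pos) <- sprintf("pos%03d", seq_len(nPos))
  rownames(neg) <- sprintf("neg%03d", seq_len(nNeg))
  TssTrainingSet(pos, neg,
                 data.frame(feature = "tss_tags", nBins = nBins,
                            stringsAsFactors = FALSE))
}

test_that("training-TSS filtering keeps unique-TSS genes off organelles", {
  tss <- GenomicRanges::GRanges(
    c("Chr1", "Chr1", "Chr1", "Chr1", "ChrM", "Chr2"),
    IRanges::IRanges(c(100, 200, 300, 350, 400, 500), width = 1),
    strand = "+")
  S4Vectors::mcols(tss)$gene <- c("gA", "gB", "gB", "gC", "gD", "gE")
  out <- filterTrainingTss(tss)
  # gB has two records (dropped), gD sits on ChrM (dropped)
  expect_setequal(S4Vectors::mcols(out)$gene, c("gA", "gC", "gE"))
  expect_length(out, 3)

  expect_warning(filterTrainingTss(tss[5]), "no training TSSs")
})

test_that("negative sampling is seeded, distance-respecting and bounded", {
  lens <- c(chr1 = 10000L, chr2 = 8000L)
  pos <- anchorAt(c(2000, 5000, 8000))
  n1 <- sampleNegatives(lens, pos, 50, minDistance = 500, seed = 9)
  n2 <- sampleNegatives(lens, pos, 50, minDistance = 500, seed = 9)
  expect_identical(GenomicRanges::start(n1), GenomicRanges::start(n2))
  expect_identical(as.character(GenomicRanges::strand(n1)),
                   as.character(GenomicRanges::strand(n2)))
  # exhaustive distance check against every positive
  onChr1 <- n1[as.character(GenomicRanges::seqnames(n1)) == "chr1"]
  for (p in GenomicRanges::start(pos))
    expect_true(all(abs(GenomicRanges::start(onChr1) - p) >= 500))
  expect_error(sampleNegatives(c(chr1 = 1000L), anchorAt(500), 10,
                               minDistance = 2000),
               "too small")
})

test_that("cross-validation metrics follow their definitions", {
  ts <- makeToySet(nPos = 10, nNeg = 10, shift = 0)
  # stub predicting all-positive: sensitivity 1, specificity 0, accuracy 0.5
  cv <- crossValidate(ts, nFolds = 5, seed = 1,
                      trainFun = function(x, y) NULL,
                      predictFun = function(m, x) rep("pos", nrow(x)))
  s <- cvSummary(cv)
  expect_equal(unname(s["sensitivity"]), 1)
  expect_equal(unname(s["specificity"]), 0)
  expect_equal(unname(s["accuracy"]), 0.5)

  # designed confusion: one positive and two negatives always misassigned
  # -> pooled TP=9, FN=1, TN=8, FP=2
  cv2 <- crossValidate(ts, nFolds = 5, seed = 1,
    trainFun = function(x, y) NULL,
    predictFun = function(m, x) {
      truth <- ifelse(grepl("^pos", rownames(x)), "pos", "neg")
      flip <- rownames(x) %in% c("pos001", "neg001", "neg002")
      ifelse(flip, ifelse(truth == "pos", "neg", "pos"), truth)
    })
  pf <- cvFolds(cv2)
  tp <- sum(pf$tp); fn <- sum(pf$fn); tn <- sum(pf$tn); fp <- sum(pf$fp)
  expect_equal(c(tp, fn, tn, fp), c(9, 1, 8, 2))
  expect_equal(tp / (tp + fn), 0.9)             # sensitivity
  expect_equal(tn / (tn + fp), 0.8)             # specificity
  expect_equal(tp / (tp + fp), 0.8182, tolerance = 1e-4)  # precision
  expect_equal((tp + tn) / 20, 0.85)            # accuracy
})

test_that("a separable problem cross-validates perfectly and satisfies the accuracy identity", {
  ts <- makeToySet(shift = 6)
  cv <- crossValidate(ts, nFolds = 5, seed = 2)
  expect_equal(unname(cvSummary(cv)), rep(1, 4), tolerance = 1e-12)
  pf <- cvFolds(cv)
  P <- pf$tp + pf$fn; N <- pf$tn + pf$fp
  expect_equal(pf$accuracy,
               (pf$sensitivity * P + pf$specificity * N) / (P + N))
})

test_that("cross-validation is invariant to training-set row order", {
  ts <- makeToySet(shift = 1.2, seed = 5)
  set.seed(99)
  perm <- sample(nrow(ts@positives))
  tsPerm <- TssTrainingSet(ts@positives[perm, ], ts@negatives[rev(seq_len(30)), ],
                           ts@layout)
  cv1 <- crossValidate(ts, nFolds = 5, seed = 3)
  cv2 <- crossValidate(tsPerm, nFolds = 5, seed = 3)
  expect_equal(cvSummary(cv1), cvSummary(cv2))
  expect_error(crossValidate(makeToySet(nPos = 3, nNeg = 30), nFolds = 5),
               "at least 5")
})

test_that("training is seeded-deterministic and enforces the layout", {
  ts <- makeToySet(shift = 3)
  m1 <- trainTssModel(ts, seed = 7)
  m2 <- trainTssModel(ts, seed = 7)
  x <- rbind(ts@positives, ts@negatives)
  expect_identical(tssDecisionValues(m1, x), tssDecisionValues(m2, x))
  # separable toy: training accuracy 1
  dv <- tssDecisionValues(m1, x)
  lab <- ifelse(dv > 0, "pos", "neg")
  expect_equal(lab, c(rep("pos", 30), rep("neg", 30)),
               ignore_attr = TRUE)
  # decision values are larger for the positive class
  expect_gt(min(dv[1:30]), max(dv[31:60]))
  # layout mismatch
  expect_error(tssDecisionValues(m1, x[, 1:5]), "layout mismatch")
  badLayout <- data.frame(feature = "h3", nBins = 10)
  expect_error(tssDecisionValues(m1, x, badLayout), "layout mismatch")
})

test_that("feature selection maximizes accuracy and prefers smaller sets on ties", {
  # two feature blocks; the second is an exact copy of the first, so both
  # candidate sets reach identical accuracy and the smaller one must win
  base <- makeToySet(shift = 6)
  x2p <- cbind(base@positives, base@positives)
  x2n <- cbind(base@negatives, base@negatives)
  layout <- data.frame(feature = c("tss_tags", "h3k4me3"), nBins = 10,
                       stringsAsFactors = FALSE)
  ts <- TssTrainingSet(x2p, x2n, layout)
  res <- selectFeatures(ts, list(c("tss_tags", "h3k4me3"), "tss_tags"),
                        nFolds = 5, seed = 1)
  expect_equal(res$best, "tss_tags")
  expect_equal(nrow(res$table), 2)
  expect_equal(res$table$accuracy[1], res$table$accuracy[2])

  # single candidate: returned trivially
  res1 <- selectFeatures(ts, list("h3k4me3"), nFolds = 5, seed = 1)
  expect_equal(res1$best, "h3k4me3")
})

test_that("feature selection finds the informative feature on synthetic data", {
  set.seed(4)
  n <- 40
  signalP <- matrix(rnorm(n * 10, mean = 3), nrow = n)
  signalN <- matrix(rnorm(n * 10), nrow = n)
  noiseP <- matrix(rnorm(n * 10), nrow = n)
  noiseN <- matrix(rnorm(n * 10), nrow = n)
  layout <- data.frame(feature = c("tss_tags", "h3"), nBins = 10,
                       stringsAsFactors = FALSE)
  ts <- TssTrainingSet(cbind(signalP, noiseP), cbind(signalN, noiseN),
                       layout)
  res <- selectFeatures(ts, list("tss_tags", "h3",
                                 c("tss_tags", "h3")), seed = 1)
  expect_true("tss_tags" %in% res$best)
})

test_that("upstream scanning ranks by score with distance tie-breaks", {
  # flat zero tracks: every position scores identically; ties resolve to the
  # positions closest to the precursor 5' end, at most topK survive
  tr <- list(tss_tags = trackFromVector(rep(0, 30000)))
  ts <- makeToySet(shift = 5, seed = 2)
  model <- trainTssModel(ts, seed = 1)
  pm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20001, 20150),
                               strand = "+")
  S4Vectors::mcols(pm) <- S4Vectors::DataFrame(id = "mirX",
                                               intragenic = FALSE,
                                               host_gene = NA_character_)
  cand <- scanUpstreamTss(model, pm, tr, seqLengths = c(chr1 = 30000L),
                          window = 10000, step = 20, topK = 10)
  expect_lte(length(cand), 10)
  expect_equal(S4Vectors::mcols(cand)$rank, seq_along(cand))
  sc <- S4Vectors::mcols(cand)$score
  expect_true(all(diff(sc) <= 1e-12))
  expect_equal(GenomicRanges::start(cand)[1], 19981)  # closest scan position
  # non-maximum suppression: kept candidates are mutually > 200 bp apart
  d <- as.matrix(dist(GenomicRanges::start(cand)))
  expect_true(all(d[upper.tri(d)] > 200))
})

test_that("empty upstream windows yield an empty candidate set with warning", {
  tr <- list(tss_tags = trackFromVector(rep(0, 1000)))
  model <- trainTssModel(makeToySet(shift = 5), seed = 1)
  pm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100),
                               strand = "+")
  S4Vectors::mcols(pm) <- S4Vectors::DataFrame(id = "mirEdge",
                                               intragenic = FALSE,
                                               host_gene = NA_character_)
  expect_warning(cand <- scanUpstreamTss(model, pm, tr,
                                         seqLengths = c(chr1 = 1000L)),
                 "empty upstream")
  expect_length(cand, 0)
})

test_that("intragenic miRNAs inherit the host gene TSS", {
  pm <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(5000, 5100),
                               strand = "+")
  S4Vectors::mcols(pm) <- S4Vectors::DataFrame(id = "mirH",
                                               intragenic = TRUE,
                                               host_gene = "gHost")
  hostTss <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(4000, width = 1),
                                    strand = "-")
  S4Vectors::mcols(hostTss)$gene <- "gHost"
  cand <- resolveIntragenic(pm, hostTss)
  expect_equal(GenomicRanges::start(cand), 4000)
  expect_equal(S4Vectors::mcols(cand)$rank, 1L)
  expect_equal(S4Vectors::mcols(cand)$evidence, "host_gene")
  # strand comes from the host TSS record
  expect_equal(as.character(GenomicRanges::strand(cand)), "-")

  S4Vectors::mcols(pm)$intragenic <- FALSE
  expect_error(resolveIntragenic(pm, hostTss), "not intragenic")
  S4Vectors::mcols(pm)$intragenic <- TRUE
  S4Vectors::mcols(pm)$host_gene <- "gMissing"
  expect_error(resolveIntragenic(pm, hostTss), "no recorded TSS")
})

test_that("verified-TSS evaluation counts recovery within tolerance", {
  ver <- anchorAt(c(100, 200, 300, 400))
  S4Vectors::mcols(ver)$mirna <- paste0("m", 1:4)
  cand <- anchorAt(c(100, 205, 390, 1000))
  S4Vectors::mcols(cand)$mirna <- paste0("m", 1:4)
  expect_equal(evaluateOnVerified(cand[1], ver[1], 0), 1.0)
  expect_equal(evaluateOnVerified(cand[0], ver, 50), 0.0)
  expect_equal(evaluateOnVerified(cand, ver, 0), 0.25)
  expect_equal(evaluateOnVerified(cand, ver, 10), 0.5)
  expect_equal(evaluateOnVerified(cand, ver, 90), 0.75)
  expect_error(evaluateOnVerified(cand, ver[0], 10), "empty")
})

test_that("models survive a save/load round-trip", {
  ts <- makeToySet(shift = 3)
  m <- trainTssModel(ts, seed = 1)
  f <- withr::local_tempfile(fileext = ".rds")
  saveTssModel(m, f)
  m2 <- readTssModel(f)
  x <- ts@positives
  expect_identical(tssDecisionValues(m, x), tssDecisionValues(m2, x))
  expect_equal(modelFeatureSet(m2), "tss_tags")
})
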