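test_that("information weights match their analytic values", {
  uni <- matrix(0.25, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(informationVector(uni), rep(0, 5))
  deg <- uni; deg[, 2] <- c(1, 0, 0, 0)
  expect_equal(informationVector(deg)[2], log(4))
  half <- uni; half[, 3] <- c(0.5, 0.5, 0, 0)
  expect_equal(informationVector(half)[3], log(2))
})

test_that("matrix similarity is 1 on argmax and 0 on argmin sequences", {
  set.seed(5)
  for (i in 1:10) {
    pwm <- randomPwm(8)
    best <- paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
    worst <- paste(rownames(pwm)[apply(pwm, 2, which.min)], collapse = "")
    expect_equal(matrixSimilarity(pwm, best), 1, tolerance = 1e-12)
    expect_equal(matrixSimilarity(pwm, worst), 0, tolerance = 1e-12)
    s <- randomSeq(8)
    ms <- matrixSimilarity(pwm, s)
    expect_gte(ms, 0); expect_lte(ms, 1)
    expect_equal(ms, mssOracle(pwm, s), tolerance = 1e-12)
  }
})

test_that("an uninformative position contributes nothing", {
  pwm <- cbind(c(0.7, 0.1, 0.1, 0.1), rep(0.25, 4))
  rownames(pwm) <- c("A", "C", "G", "T")
  # position 2 has zero information: any base there is irrelevant
  expect_equal(matrixSimilarity(pwm, "AA"), 1)
  expect_equal(matrixSimilarity(pwm, "AG"), 1)
  expect_error(matrixSimilarity(pwm, "AAA"), "length")
  uni <- matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_warning(s <- matrixSimilarity(uni, "ACGTAC"), "all-zero")
  expect_equal(s, 0)
})

test_that("the core is the 5-window of maximum information, leftmost on ties", {
  uni <- matrix(0.25, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- uni
  for (j in 3:7) pwm[, j] <- c(0.97, 0.01, 0.01, 0.01)
  expect_equal(corePositions(pwm), 3:7)
  expect_warning(expect_equal(corePositions(uni), 1:5), NA)  # leftmost tie
  short <- matrix(0.25, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_warning(corePositions(short), "shorter than 5")
  # a perfect core scores 1 even with mismatches outside it
  win <- strsplit("CCAAAAACC", "")[[1]]
  win[3:7] <- "A"
  expect_equal(coreSimilarity(pwm, paste(win[1:8], collapse = "")), 1)
})

test_that("promoter scanning counts, locates and orients hits correctly", {
  set.seed(6)
  cons <- "ACGTACGTAA"
  m <- matrix(0.03, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
  b <- strsplit(cons, "")[[1]]
  m[cbind(match(b, rownames(m)), 1:10)] <- 0.91
  pwms <- list(TF1 = m)

  # thresholds 0/0: every offset on both strands
  prom <- randomSeq(60)
  hits0 <- scanPromoter(prom, pwms, 0, 0)
  expect_equal(nrow(hits0), 2 * (60 - 10 + 1))

  # planted consensus on the forward strand is found at its offset
  prom2 <- paste0(strrep("C", 20), cons, strrep("G", 20))
  hits <- scanPromoter(prom2, pwms)
  fwd <- hits[hits$strand == "+", ]
  expect_true(any(fwd$offset == 21 & fwd$matrix_similarity > 1 - 1e-9))

  # planted on the reverse strand: reported with strand '-' at the correct
  # forward-coordinate offset
  prom3 <- paste0(strrep("C", 15), revcompChr(cons), strrep("T", 25))
  hits3 <- scanPromoter(prom3, pwms)
  rev <- hits3[hits3$strand == "-", ]
  expect_true(any(rev$offset == 16 & rev$matrix_similarity > 1 - 1e-9))

  expect_equal(nrow(scanPromoter("", pwms)), 0)
})

test_that("minus-strand hits equal forward-strand hits on the reverse complement", {
  set.seed(61)
  for (i in 1:10) {
    pwm <- randomPwm(7)
    prom <- randomSeq(120)
    hits <- scanPromoter(prom, list(P = pwm), 0, 0)
    hitsRc <- scanPromoter(revcompChr(prom), list(P = pwm), 0, 0)
    minus <- hits[hits$strand == "-", ]
    plusRc <- hitsRc[hitsRc$strand == "+", ]
    # map reverse-complement offsets back to forward coordinates
    mapped <- 120 - 7 - plusRc$offset + 2
    expect_setequal(round(minus$matrix_similarity, 10),
                    round(plusRc$matrix_similarity, 10))
    expect_setequal(minus$offset, mapped)
    # scanning agrees with the naive per-window oracle
    fwd <- hits[hits$strand == "+", ]
    ora <- vapply(fwd$offset, function(o)
      mssOracle(pwm, substr(prom, o, o + 6)), numeric(1))
    expect_equal(fwd$matrix_similarity, ora, tolerance = 1e-12)
  }
})

test_that("coTFBS frequency uses promoter presence, not hit counts", {
  hits <- data.frame(promoter = c("p1", "p1", "p1", "p2", "p2"),
                     pwm = "TF1", offset = 1:5, strand = "+",
                     matrix_similarity = 1, core_similarity = 1)
  expect_equal(cotfbsFrequency(hits, "TF1", c("p1", "p2", "p3", "p4")), 0.5)
  expect_equal(cotfbsFrequency(hits, "TF1", c("p1", "p2")), 1.0)
  hits34 <- data.frame(promoter = c("p1", "p2", "p3"), pwm = "TF1",
                       offset = 1, strand = "+", matrix_similarity = 1,
                       core_similarity = 1)
  expect_equal(cotfbsFrequency(hits34, "TF1", paste0("p", 1:4)), 0.75)
  expect_error(cotfbsFrequency(hits, "TF1", character(0)), "empty")
})

test_that("hypergeometric p-values match exact arithmetic", {
  # C(4,4) * C(6,1) / C(10,5) = 6/252
  expect_equal(hypergeomPvalue(10, 4, 5, 4, "point"), 6 / 252,
               tolerance = 1e-12)
  # k at the support maximum: upper tail equals the point mass
  expect_equal(hypergeomPvalue(10, 4, 5, 4, "upper"), 6 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeomPvalue(10, 4, 5, 0, "upper"), 1.0)
  expect_error(hypergeomPvalue(10, 4, 5, 5), "k > K")
  expect_error(hypergeomPvalue(10, 6, 2, 3), "k > n")
  expect_error(hypergeomPvalue(10, 12, 5, 4), "K > N")
  expect_error(hypergeomPvalue(10, 4, 12, 4), "n > N")
})

test_that("upper-tail p is non-increasing in k", {
  for (parms in list(c(30, 10, 12), c(50, 25, 10), c(18, 9, 9))) {
    N <- parms[1]; K <- parms[2]; n <- parms[3]
    ks <- max(0, n - (N - K)):min(K, n)
    ps <- vapply(ks, function(k) hypergeomPvalue(N, K, n, k, "upper"),
                 numeric(1))
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("candidate TFs respect the strict frequency and p cutoffs", {
  stats <- data.frame(
    group = "mirX",
    pwm = c("A", "B", "C", "D"),
    N = 100, K = 10, n = 20, k = 5,
    frequency = c(0.5, 0.75, 0.9, 0.6),
    p_value = c(0.01, 0.1, 0.005, 0.02))
  out <- candidateTfs(stats, group = "mirX")
  # A fails frequency == 0.5 (strict), B fails p == 0.1 (strict)
  expect_equal(out$pwm, c("C", "D"))
  expect_true(all(out$frequency > 0.5 & out$p_value < 0.1))
})

test_that("the coTFBS statistic requires at least two groups", {
  proms <- list(g1 = Biostrings::DNAStringSet(c(p1 = randomSeq(50))))
  pwms <- list(P = randomPwm(6))
  expect_error(cotfbsStats(proms, pwms), "at least 2")
})

test_that("coTFBS counts are internally consistent on scanned groups", {
  set.seed(77)
  cons <- "AAAATTTTGG"
  m <- matrix(0.02, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
  b <- strsplit(cons, "")[[1]]
  m[cbind(match(b, rownames(m)), 1:10)] <- 0.94
  pwms <- list(TF1 = m, decoy = randomPwm(10))
  mk <- function(nWith, nWithout) {
    seqs <- c(vapply(seq_len(nWith), function(i) {
      s <- randomSeq(200); substr(s, 50, 59) <- cons; s
    }, character(1)), vapply(seq_len(nWithout), function(i)
      randomSeq(200), character(1)))
    names(seqs) <- sprintf("p%02d", seq_along(seqs))
    Biostrings::DNAStringSet(seqs)
  }
  groups <- list(gA = mk(4, 1), gB = mk(0, 5))
  st <- cotfbsStats(groups, pwms)
  expect_true(all(st$k <= pmin(st$K, st$n)))
  expect_true(all(st$K <= st$N & st$n <= st$N))
  a <- st[st$group == "gA", ]
  expect_gte(a$frequency[a$pwm == "TF1"], 0.8)
  # the planted motif is the most over-represented PWM in its group
  expect_equal(a$pwm[which.min(a$p_value)], "TF1")
  expect_true(all(st$p_value > 0 & st$p_value <= 1))
})
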