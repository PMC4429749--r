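# Independent oracles and small fixture builders used across the suite.

# Exact binomial coefficients via Pascal's triangle (exact integer doubles
# up to well beyond the sizes used here); independent of stats::dhyper.
chooseExact <- local({
  cache <- list()
  function(n, k) {
    if (k < 0 || k > n) return(0)
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      row <- 1
      for (i in seq_len(n)) row <- c(0, row) + c(row, 0)
      cache[[key]] <<- row
    }
    cache[[key]][k + 1]
  }
})

# Hypergeometric point mass by exact rational arithmetic (ratio of exact
# integers).
hyperPointOracle <- function(N, K, n, k) {
  chooseExact(K, k) * chooseExact(N - K, n - k) / chooseExact(N, n)
}

hyperUpperOracle <- function(N, K, n, k) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(j) hyperPointOracle(N, K, n, j), numeric(1)))
}

# Naive Match-style rescoring of one window (direct formula evaluation).
mssOracle <- function(pwm, window) {
  b <- strsplit(toupper(window), "")[[1]]
  I <- apply(pwm, 2, function(f) sum(ifelse(f > 0, f * log(4 * f), 0)))
  f <- vapply(seq_along(b), function(i) {
    if (b[i] %in% rownames(pwm)) pwm[b[i], i] else min(pwm[, i])
  }, numeric(1))
  cur <- sum(I * f)
  mx <- sum(I * apply(pwm, 2, max))
  mn <- sum(I * apply(pwm, 2, min))
  if (mx == mn) 0 else (cur - mn) / (mx - mn)
}

# Reachable set by transitive closure (repeated boolean matrix products).
reachOracle <- function(adj, sources) {
  nodes <- rownames(adj)
  R <- adj > 0
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  reached <- nodes[colSums(R[sources, , drop = FALSE] > 0) > 0]
  unique(reached)
}

randomPwm <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(runif(4 * L, 0.01, 1), nrow = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  sweep(m, 2, colSums(m), "/")
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

revcompChr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# One-sequence SignalTrack from a plain numeric vector.
trackFromVector <- function(v, seqid = "chr1", feature = "tss_tags") {
  SignalTrack(feature, stats::setNames(list(v), seqid))
}

anchorAt <- function(pos, strand = "+", seqid = "chr1") {
  GenomicRanges::GRanges(seqid, IRanges::IRanges(pos, width = 1),
                         strand = strand)
}

# A small, fast simulation configuration for structural tests (the recovery
# criteria use the full defaults).
smallSimConfig <- function(seed = 1, ...) {
  args <- list(seed = seed, nChromosomes = 2L, chromosomeLength = 150000L,
               nMirnas = 6L, nGenes = 150L, nVerifiedGenes = 60L, nTfs = 2L,
               blockSize = 15L, nGraphExtra = 20L)
  args <- utils::modifyList(args, list(...))
  do.call(simulationConfig, args)
}
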