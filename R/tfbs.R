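# Match-style PWM scanning of promoters, coTFBS frequencies across
# coexpressed groups, and the hypergeometric over-representation filter.

#' Per-position information weights of a PWM
#'
#' `I(i) = sum_b f(i,b) * ln(4 * f(i,b))`, with `0 * ln(0) = 0`; each weight
#' lies in `[0, ln 4]` (0 for a uniform column, ln 4 for a degenerate one).
#'
#' @param pwm 4 x L frequency matrix (rows A, C, G, T; columns summing to 1).
#' @return numeric vector of length L.
#' @export
informationVector <- function(pwm) {
  .checkPwm(pwm)
  apply(pwm, 2, function(f) {
    t <- f * log(4 * f)
    sum(t[f > 0])
  })
}

.checkPwm <- function(pwm) {
  if (!is.matrix(pwm) || nrow(pwm) != 4L)
    stop("PWM must be a 4 x L matrix (rows A, C, G, T)")
  if (ncol(pwm) < 1L) stop("PWM must have at least one position")
  cs <- colSums(pwm)
  if (any(abs(cs - 1) > 1e-9))
    stop("PWM columns must sum to 1 (normalize with normalizePwm())")
  invisible(TRUE)
}

# Encode a sequence as row indices into the scoring matrix: A,C,G,T -> 1..4,
# anything else (N, ambiguity codes) -> 5 (scored with the column minimum).
.encodeSeq <- function(s) {
  v <- match(strsplit(toupper(as.character(s)), "")[[1]],
             c("A", "C", "G", "T"))
  v[is.na(v)] <- 5L
  v
}

# Score all windows of an encoded sequence against an information-weighted
# matrix W (5 x L; row 5 = per-column minimum contribution). Returns the raw
# Current values for offsets 1..(n - L + 1).
.slideScore <- function(codes, W) {
  L <- ncol(W)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  cur <- numeric(n)
  for (i in seq_len(L))
    cur <- cur + unname(W[, i])[codes[seq_len(n) + i - 1L]]
  cur
}

.scoreMatrices <- function(pwm) {
  I <- informationVector(pwm)
  W <- rbind(pwm, apply(pwm, 2, min)) * rep(I, each = 5L)
  maxS <- sum(I * apply(pwm, 2, max))
  minS <- sum(I * apply(pwm, 2, min))
  list(W = W, max = maxS, min = minS, I = I)
}

#' Matrix similarity score of a window against a PWM
#'
#' Match-style information-weighted score, normalized to `[0, 1]`:
#' `MSS = (Current - Min) / (Max - Min)` with
#' `Current = sum_i I(i) * f(i, b_i)`, `Max`/`Min` the per-position
#' maxima/minima. Ambiguous bases contribute the column minimum. A PWM with
#' all-zero information (uniform everywhere) scores 0 with a warning.
#'
#' @param pwm 4 x L frequency matrix.
#' @param window character or `DNAString` of length exactly L.
#' @return score in `[0, 1]`.
#' @export
matrixSimilarity <- function(pwm, window) {
  codes <- .encodeSeq(window)
  if (length(codes) != ncol(pwm))
    stop("window length ", length(codes), " != PWM length ", ncol(pwm))
  sm <- .scoreMatrices(pwm)
  if (sm$max - sm$min <= 0) {
    warning("all-zero information matrix; similarity defined as 0")
    return(0)
  }
  (.slideScore(codes, sm$W) - sm$min) / (sm$max - sm$min)
}

#' Core positions of a PWM
#'
#' The 5 consecutive positions maximizing the summed information weight
#' (leftmost window on ties). For PWMs shorter than 5 positions the whole
#' matrix is the core (flagged with a warning).
#'
#' @param pwm 4 x L frequency matrix.
#' @return integer vector of core positions.
#' @export
corePositions <- function(pwm) {
  L <- ncol(pwm)
  if (L < 5L) {
    warning("PWM shorter than 5 positions; core = whole matrix")
    return(seq_len(L))
  }
  I <- informationVector(pwm)
  winSums <- vapply(seq_len(L - 4L), function(s) sum(I[s:(s + 4L)]),
                    numeric(1))
  s <- which.max(winSums)  # which.max takes the leftmost maximum
  s:(s + 4L)
}

#' Core similarity score
#'
#' [matrixSimilarity()] restricted to the core positions (the 5 consecutive
#' highest-information positions).
#'
#' @param pwm 4 x L frequency matrix.
#' @param window character or `DNAString` of length L (the full motif
#'   window; the core sub-window is extracted internally).
#' @return score in `[0, 1]`.
#' @export
coreSimilarity <- function(pwm, window) {
  codes <- .encodeSeq(window)
  if (length(codes) != ncol(pwm))
    stop("window length ", length(codes), " != PWM length ", ncol(pwm))
  core <- suppressWarnings(corePositions(pwm))
  sub <- pwm[, core, drop = FALSE]
  sm <- .scoreMatrices(sub)
  if (sm$max - sm$min <= 0) {
    warning("all-zero information core; similarity defined as 0")
    return(0)
  }
  (.slideScore(codes[core], sm$W) - sm$min) / (sm$max - sm$min)
}

#' Scan a promoter for TFBS hits
#'
#' Slides each PWM over both strands of the promoter (the minus strand via
#' the reverse complement) and reports every window whose core similarity
#' and matrix similarity reach the thresholds. Offsets are 1-based positions
#' of the window's leftmost base in forward-strand coordinates.
#'
#' @param promoter character or `DNAString` promoter sequence.
#' @param pwms named list of 4 x L frequency matrices.
#' @param coreThreshold minimum core similarity (default 0.75).
#' @param matrixThreshold minimum matrix similarity (default 0.85).
#' @return `data.frame` with columns `pwm`, `offset`, `strand`,
#'   `matrix_similarity`, `core_similarity`, sorted by offset; empty for an
#'   empty sequence.
#' @export
scanPromoter <- function(promoter, pwms, coreThreshold = 0.75,
                         matrixThreshold = 0.85) {
  stopifnot(coreThreshold >= 0, coreThreshold <= 1,
            matrixThreshold >= 0, matrixThreshold <= 1)
  empty <- data.frame(pwm = character(), offset = integer(),
                      strand = character(), matrix_similarity = numeric(),
                      core_similarity = numeric(), stringsAsFactors = FALSE)
  seqChr <- toupper(as.character(promoter))
  n <- nchar(seqChr)
  if (n == 0L) return(empty)
  fwd <- .encodeSeq(seqChr)
  rev <- .encodeSeq(reverseComplement(DNAString(seqChr)))
  rows <- list()
  for (id in names(pwms)) {
    pwm <- pwms[[id]]
    L <- ncol(pwm)
    if (L > n) next
    sm <- .scoreMatrices(pwm)
    core <- suppressWarnings(corePositions(pwm))
    smc <- .scoreMatrices(pwm[, core, drop = FALSE])
    rng <- sm$max - sm$min
    rngc <- smc$max - smc$min
    for (str in c("+", "-")) {
      codes <- if (str == "+") fwd else rev
      cur <- .slideScore(codes, sm$W)
      mss <- if (rng > 0) (cur - sm$min) / rng else rep(0, length(cur))
      # core windows start core[1]-1 bases into each motif window
      nOff <- length(cur)
      curC <- .slideScore(codes, smc$W)
      curC <- curC[core[1]:(core[1] + nOff - 1L)]
      css <- if (rngc > 0) (curC - smc$min) / rngc else rep(0, nOff)
      hit <- which(mss >= matrixThreshold & css >= coreThreshold)
      if (length(hit)) {
        offset <- if (str == "+") hit else n - L - hit + 2L
        rows[[length(rows) + 1L]] <-
          data.frame(pwm = id, offset = offset, strand = str,
                     matrix_similarity = mss[hit], core_similarity = css[hit],
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$offset, out$pwm, out$strand), , drop = FALSE]
}

#' Scan a set of promoters
#'
#' @param promoters named `DNAStringSet` (or named character vector).
#' @inheritParams scanPromoter
#' @return `data.frame` as [scanPromoter()] plus a `promoter` column.
#' @export
scanPromoterSet <- function(promoters, pwms, coreThreshold = 0.75,
                            matrixThreshold = 0.85) {
  rows <- lapply(names(promoters), function(id) {
    h <- scanPromoter(promoters[[id]], pwms, coreThreshold, matrixThreshold)
    if (nrow(h)) cbind(promoter = id, h, stringsAsFactors = FALSE) else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(promoter = character(), pwm = character(),
                      offset = integer(), strand = character(),
                      matrix_similarity = numeric(),
                      core_similarity = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' coTFBS frequency of one PWM in a promoter group
#'
#' Fraction of the group's promoters containing at least one hit of the PWM
#' (multiple hits in one promoter count once).
#'
#' @param hits `data.frame` from [scanPromoterSet()].
#' @param pwmId the PWM.
#' @param promoterIds character vector of the group's promoter ids (>= 1).
#' @return fraction in `[0, 1]`.
#' @export
cotfbsFrequency <- function(hits, pwmId, promoterIds) {
  if (length(promoterIds) == 0L) stop("empty promoter group")
  withHit <- unique(hits$promoter[hits$pwm == pwmId])
  sum(promoterIds %in% withHit) / length(promoterIds)
}

#' Hypergeometric p-value
#'
#' Point mass `P(X = k) = C(K, k) C(N - K, n - k) / C(N, n)` or upper tail
#' `P(X >= k)`; computed via `stats::dhyper`/`stats::phyper` (log-space
#' internally, stable for large arguments). The upper tail is the
#' over-representation p-value reported throughout the package.
#'
#' @param N population size (total detections across all groups).
#' @param K successes in the population (detections of this TFBS/term).
#' @param n draws (detections in the group / query of interest).
#' @param k observed successes in the draws.
#' @param tail `"upper"` (default) for `P(X >= k)` or `"point"` for
#'   `P(X = k)`.
#' @return probability; errors on inconsistent counts (`k > K`, `k > n`,
#'   `K > N` or `n > N`).
#' @export
hypergeomPvalue <- function(N, K, n, k, tail = c("upper", "point")) {
  tail <- match.arg(tail)
  if (any(c(N, K, n, k) < 0)) stop("counts must be non-negative")
  if (k > K) stop("inconsistent counts: k > K")
  if (k > n) stop("inconsistent counts: k > n")
  if (K > N) stop("inconsistent counts: K > N")
  if (n > N) stop("inconsistent counts: n > N")
  if (tail == "point") stats::dhyper(k, K, N - K, n)
  else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' coTFBS statistics over all coexpressed groups
#'
#' Computes, for every (group, PWM) pair, the presence counts feeding the
#' hypergeometric test: `N` = total (promoter, PWM) detections over all
#' groups, `K` = detections of this PWM over all groups, `n` = detections in
#' this group, `k` = detections of this PWM in this group (each promoter
#' contributes 0/1 per PWM), plus the coTFBS `frequency` (fraction of group
#' promoters with >= 1 hit) and the upper-tail p-value.
#'
#' @param promotersByGroup named list (one entry per miRNA group) of named
#'   `DNAStringSet`s: the promoters of the miRNA and its coexpressed genes.
#' @param pwms named list of 4 x L frequency matrices.
#' @param coreThreshold,matrixThreshold scan thresholds.
#' @return `data.frame` with columns `group`, `pwm`, `N`, `K`, `n`, `k`,
#'   `frequency`, `p_value`.
#' @export
cotfbsStats <- function(promotersByGroup, pwms, coreThreshold = 0.75,
                        matrixThreshold = 0.85) {
  if (length(promotersByGroup) < 2L)
    stop("the coTFBS statistic needs at least 2 coexpressed groups ",
         "(the background is all groups in the run)")
  presence <- lapply(promotersByGroup, function(proms) {
    hits <- scanPromoterSet(proms, pwms, coreThreshold, matrixThreshold)
    vapply(names(pwms), function(id)
      length(unique(hits$promoter[hits$pwm == id])), integer(1))
  })
  sizes <- vapply(promotersByGroup, length, integer(1))
  kMat <- do.call(rbind, presence)      # groups x pwms
  K <- colSums(kMat)
  n <- rowSums(kMat)
  N <- sum(kMat)
  rows <- list()
  for (g in seq_along(promotersByGroup)) {
    for (p in seq_along(pwms)) {
      k <- kMat[g, p]
      pv <- if (N == 0L) 1 else hypergeomPvalue(N, K[p], n[g], k, "upper")
      rows[[length(rows) + 1L]] <- data.frame(
        group = names(promotersByGroup)[g], pwm = names(pwms)[p],
        N = N, K = unname(K[p]), n = unname(n[g]), k = unname(k),
        frequency = k / sizes[g], p_value = pv, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Candidate TFs for a coexpressed group
#'
#' Filters the coTFBS statistics of one group to `frequency > freqCutoff`
#' (strict) and `p_value < pCutoff` (strict), sorted by increasing p, ties
#' by decreasing frequency, then PWM id. These are the reliable
#' trans-regulator candidates for the group's miRNA.
#'
#' @param stats `data.frame` from [cotfbsStats()].
#' @param group group (miRNA) id; `NULL` keeps all groups.
#' @param freqCutoff coTFBS frequency cutoff (default 0.5).
#' @param pCutoff p-value cutoff (default 0.1).
#' @return filtered, ranked `data.frame` (possibly empty).
#' @export
candidateTfs <- function(stats, group = NULL, freqCutoff = 0.5,
                         pCutoff = 0.1) {
  if (length(unique(stats$group)) < 2L && is.null(group))
    stop("the coTFBS statistic needs at least 2 groups")
  if (!is.null(group)) stats <- stats[stats$group == group, , drop = FALSE]
  keep <- stats$frequency > freqCutoff & stats$p_value < pCutoff
  out <- stats[keep, , drop = FALSE]
  out <- out[order(out$p_value, -out$frequency, out$pwm), , drop = FALSE]
  rownames(out) <- NULL
  out
}
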