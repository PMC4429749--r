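# Train, select, validate and apply the binary TSS classifier; scan the
# 10 kb upstream of pre-miRNAs and rank TSS candidates.

#' Filter verified gene TSS records for training
#'
#' Keeps exactly one TSS per gene for genes having exactly one recorded TSS
#' (genes with multiple recorded TSSs are dropped entirely) and drops records
#' on blacklisted sequences (organelles by default, where no TSS-relevant
#' sequencing exists).
#'
#' @param tssRecords `GRanges` of 1-bp TSS records with a metadata column
#'   `gene` (or `name`) carrying gene ids.
#' @param geneAnnotations optional `GRanges` with metadata column `id`; when
#'   given, only TSSs of annotated genes are kept.
#' @param blacklistSeqids sequence names to drop (default
#'   [organelleSeqids()]).
#' @return `GRanges` of positive training anchors (possibly empty, with a
#'   warning).
#' @export
filterTrainingTss <- function(tssRecords, geneAnnotations = NULL,
                              blacklistSeqids = organelleSeqids()) {
  genes <- mcols(tssRecords)$gene
  if (is.null(genes)) genes <- mcols(tssRecords)$name
  if (is.null(genes)) stop("TSS records must carry gene ids ('gene' or 'name')")
  keep <- !(as.character(seqnames(tssRecords)) %in% blacklistSeqids)
  tssRecords <- tssRecords[keep]
  genes <- genes[keep]
  tab <- table(genes)
  unique1 <- names(tab)[tab == 1L]
  out <- tssRecords[genes %in% unique1]
  if (!is.null(geneAnnotations)) {
    ann <- mcols(geneAnnotations)$id
    g <- mcols(out)$gene
    if (is.null(g)) g <- mcols(out)$name
    out <- out[g %in% ann]
  }
  if (length(out) == 0L) warning("no training TSSs survive filtering")
  out
}

#' Sample background (negative) anchors
#'
#' Draws `n` positions uniformly over the genome, each at distance >=
#' `minDistance` from every positive anchor, without replacement;
#' reproducible for a fixed seed. Strands are assigned uniformly at random.
#'
#' @param genomeLengths named integer vector of sequence lengths.
#' @param positiveAnchors `GRanges` of positive anchors to keep away from.
#' @param n number of negatives (> 0).
#' @param minDistance minimum distance to any positive (bases).
#' @param seed RNG seed.
#' @return `GRanges` of 1-bp negative anchors named `neg0001`, ...
#' @export
sampleNegatives <- function(genomeLengths, positiveAnchors, n,
                            minDistance = 1000L, seed = 1L) {
  if (n <= 0) stop("'n' must be positive")
  if (minDistance < 0) stop("'minDistance' must be >= 0")
  allowed <- lapply(names(genomeLengths), function(s) {
    full <- IRanges(1L, as.integer(genomeLengths[s]))
    pos <- positiveAnchors[as.character(seqnames(positiveAnchors)) == s]
    if (length(pos) == 0L) return(full)
    excl <- IRanges(pmax(1L, start(pos) - as.integer(minDistance) + 1L),
                    pmin(as.integer(genomeLengths[s]),
                         start(pos) + as.integer(minDistance) - 1L))
    IRanges::setdiff(full, IRanges::reduce(excl))
  })
  names(allowed) <- names(genomeLengths)
  widths <- vapply(allowed, function(x) sum(as.numeric(IRanges::width(x))),
                   numeric(1))
  total <- sum(widths)
  if (total < n)
    stop("allowed background space too small (", total, " bases) for n = ", n,
         "; reduce 'minDistance' or 'n'")
  set.seed(seed)
  offs <- sort(sample.int(total, n))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  # map cumulative offsets to (seqid, position)
  pieces <- list()
  cum <- 0
  for (s in names(allowed)) {
    w <- widths[s]
    sel <- offs > cum & offs <= cum + w
    if (any(sel)) {
      within <- offs[sel] - cum
      ir <- allowed[[s]]
      cw <- cumsum(as.numeric(IRanges::width(ir)))
      idx <- findInterval(within - 1, c(0, cw), rightmost.closed = FALSE)
      posn <- start(ir)[idx] + (within - c(0, cw)[idx] - 1)
      pieces[[s]] <- GRanges(s, IRanges(posn, width = 1L))
    }
    cum <- cum + w
  }
  out <- suppressWarnings(do.call(c, unname(pieces)))
  strand(out) <- strands
  names(out) <- sprintf("neg%04d", seq_len(n))
  out
}

# Fit a soft-margin SVM on a scaled feature matrix; internal, shared by
# training and cross-validation. Decision values are oriented so that larger
# means more TSS-like.
.fitSvm <- function(x, y, hyper, seed) {
  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- scale(x, center = center, scale = scl)
  gamma <- if (is.null(hyper$gamma)) 1 / ncol(x) else hyper$gamma
  set.seed(seed)
  fit <- e1071::svm(xs, y, kernel = hyper$kernel, cost = hyper$cost,
                    gamma = gamma, scale = FALSE)
  dv <- attr(predict(fit, xs, decision.values = TRUE), "decision.values")[, 1]
  flip <- mean(dv[y == "pos"]) < mean(dv[y == "neg"])
  list(fit = fit, center = center, scale = scl, flip = flip,
       hyper = list(kernel = hyper$kernel, cost = hyper$cost, gamma = gamma))
}

.svmDecision <- function(m, x) {
  xs <- scale(x, center = m$center, scale = m$scale)
  dv <- attr(predict(m$fit, xs, decision.values = TRUE), "decision.values")[, 1]
  if (m$flip) -dv else dv
}

.defaultHyper <- function(hyper = list()) {
  utils::modifyList(list(kernel = "radial", cost = 1, gamma = NULL), hyper)
}

# Column indices of a feature subset within a layout.
.layoutColumns <- function(layout, featureSet) {
  featureSet <- canonicalFeatureOrder(featureSet)
  unknown <- setdiff(featureSet, layout$feature)
  if (length(unknown))
    stop("feature(s) not in layout: ", paste(unknown, collapse = ", "))
  offsets <- c(0, cumsum(layout$nBins))
  idx <- unlist(lapply(match(featureSet, layout$feature), function(i)
    (offsets[i] + 1):offsets[i + 1]))
  list(idx = idx,
       layout = data.frame(feature = featureSet,
                           nBins = layout$nBins[match(featureSet,
                                                      layout$feature)],
                           stringsAsFactors = FALSE))
}

#' Restrict a training set to a feature subset
#' @param trainingSet a [TssTrainingSet-class].
#' @param featureSet feature names to keep.
#' @return a [TssTrainingSet-class] over the subset, canonical order.
#' @export
subsetTrainingSet <- function(trainingSet, featureSet) {
  lc <- .layoutColumns(trainingSet@layout, featureSet)
  TssTrainingSet(trainingSet@positives[, lc$idx, drop = FALSE],
                 trainingSet@negatives[, lc$idx, drop = FALSE],
                 lc$layout, trainingSet@provenance)
}

#' Stratified k-fold cross-validation of the TSS classifier
#'
#' Folds are assigned per class after ordering samples by id (row name), so
#' the metrics do not depend on the storage order of the training set.
#' Reported per fold and as fold means: sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), precision TP/(TP+FP), accuracy (TP+TN)/total.
#'
#' @param trainingSet a [TssTrainingSet-class].
#' @param nFolds number of folds (default 5); each class must have at least
#'   `nFolds` members.
#' @param seed RNG seed for fold assignment and training.
#' @param hyper SVM hyperparameters (list with `kernel`, `cost`, `gamma`).
#' @param trainFun,predictFun optional classifier plug-in: `trainFun(x, y)`
#'   returns a fitted object, `predictFun(object, x)` returns labels in
#'   `c("neg", "pos")`. Defaults use the package SVM.
#' @return a [CvMetrics-class].
#' @export
crossValidate <- function(trainingSet, nFolds = 5L, seed = 1L,
                          hyper = list(), trainFun = NULL,
                          predictFun = NULL) {
  hyper <- .defaultHyper(hyper)
  if (is.null(trainFun)) {
    trainFun <- function(x, y) .fitSvm(x, y, hyper, seed)
    predictFun <- function(m, x)
      ifelse(.svmDecision(m, x) > 0, "pos", "neg")
  }
  pos <- trainingSet@positives
  neg <- trainingSet@negatives
  if (nrow(pos) < nFolds || nrow(neg) < nFolds)
    stop("each class needs at least ", nFolds, " members")
  foldOf <- function(m, cls) {
    ids <- rownames(m)
    if (is.null(ids)) ids <- sprintf("%s%06d", cls, seq_len(nrow(m)))
    ord <- order(ids)
    set.seed(seed)
    f <- sample(rep_len(seq_len(nFolds), nrow(m)))
    out <- integer(nrow(m))
    out[ord] <- f
    out
  }
  fp <- foldOf(pos, "pos")
  fn <- foldOf(neg, "neg")
  rows <- lapply(seq_len(nFolds), function(k) {
    xtr <- rbind(pos[fp != k, , drop = FALSE], neg[fn != k, , drop = FALSE])
    ytr <- factor(rep(c("pos", "neg"), c(sum(fp != k), sum(fn != k))),
                  levels = c("neg", "pos"))
    xte <- rbind(pos[fp == k, , drop = FALSE], neg[fn == k, , drop = FALSE])
    yte <- rep(c("pos", "neg"), c(sum(fp == k), sum(fn == k)))
    m <- trainFun(xtr, ytr)
    pred <- predictFun(m, xte)
    tp <- sum(pred == "pos" & yte == "pos")
    fnn <- sum(pred == "neg" & yte == "pos")
    tn <- sum(pred == "neg" & yte == "neg")
    fpp <- sum(pred == "pos" & yte == "neg")
    data.frame(fold = k, tp = tp, fn = fnn, tn = tn, fp = fpp,
               sensitivity = tp / (tp + fnn),
               specificity = tn / (tn + fpp),
               precision = if (tp + fpp > 0) tp / (tp + fpp) else NA_real_,
               accuracy = (tp + tn) / (tp + fnn + tn + fpp))
  })
  perFold <- do.call(rbind, rows)
  summ <- colMeans(perFold[, c("sensitivity", "specificity", "precision",
                               "accuracy")], na.rm = TRUE)
  new("CvMetrics", perFold = perFold, summary = summ,
      nFolds = as.integer(nFolds))
}

#' Feature-combination selection by cross-validation
#'
#' Evaluates each candidate feature combination by stratified k-fold CV and
#' returns the combination maximizing mean accuracy; ties are broken by fewer
#' features, then lexicographically. The full per-combination table is
#' returned alongside.
#'
#' @param trainingSet a [TssTrainingSet-class] holding all features.
#' @param candidateFeatureSets list of character vectors (feature names).
#' @param nFolds,seed,hyper passed to [crossValidate()].
#' @return list with `best` (character vector), `metrics` (the
#'   [CvMetrics-class] of the best set) and `table` (`data.frame` with one
#'   row per candidate; failed candidates carry `NA` metrics and the error
#'   message).
#' @export
selectFeatures <- function(trainingSet, candidateFeatureSets, nFolds = 5L,
                           seed = 1L, hyper = list()) {
  if (length(candidateFeatureSets) == 0L)
    stop("need at least one candidate feature set")
  rows <- list()
  metricsBySet <- list()
  for (i in seq_along(candidateFeatureSets)) {
    fs <- canonicalFeatureOrder(candidateFeatureSets[[i]])
    key <- paste(fs, collapse = "+")
    res <- tryCatch({
      cv <- crossValidate(subsetTrainingSet(trainingSet, fs),
                          nFolds = nFolds, seed = seed, hyper = hyper)
      metricsBySet[[key]] <- cv
      s <- cvSummary(cv)
      data.frame(features = key, nFeatures = length(fs),
                 sensitivity = s["sensitivity"], specificity = s["specificity"],
                 precision = s["precision"], accuracy = s["accuracy"],
                 error = NA_character_, row.names = NULL)
    }, error = function(e)
      data.frame(features = key, nFeatures = length(fs),
                 sensitivity = NA_real_, specificity = NA_real_,
                 precision = NA_real_, accuracy = NA_real_,
                 error = conditionMessage(e), row.names = NULL))
    rows[[i]] <- res
  }
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$accuracy))
  if (length(ok) == 0L) stop("all candidate feature sets failed")
  ord <- ok[order(-tab$accuracy[ok], tab$nFeatures[ok], tab$features[ok])]
  best <- strsplit(tab$features[ord[1]], "\\+")[[1]]
  list(best = best, metrics = metricsBySet[[tab$features[ord[1]]]],
       table = tab)
}

#' Train the TSS classifier
#'
#' Fits a soft-margin SVM (RBF kernel, cost 1, gamma 1/n_features by
#' default) on z-scaled feature vectors; the scaling parameters, feature
#' layout and seed are stored in the model so that prediction is exactly
#' reproducible. Decision values are oriented so that larger means more
#' TSS-like.
#'
#' @param trainingSet a [TssTrainingSet-class].
#' @param featureSet optional feature subset (default: all features in the
#'   layout).
#' @param hyper list of hyperparameters (`kernel`, `cost`, `gamma`).
#' @param seed RNG seed.
#' @param span,binSize window geometry the feature vectors were built with;
#'   stored in the model and reused by [scanUpstreamTss()].
#' @param cv optional [CvMetrics-class] to record in the model metadata.
#' @return a [TssModel-class].
#' @export
trainTssModel <- function(trainingSet, featureSet = NULL, hyper = list(),
                          seed = 1L, span = 1000L, binSize = 200L,
                          cv = NULL) {
  hyper <- .defaultHyper(hyper)
  if (!is.null(featureSet))
    trainingSet <- subsetTrainingSet(trainingSet, featureSet)
  x <- rbind(trainingSet@positives, trainingSet@negatives)
  y <- factor(rep(c("pos", "neg"),
                  c(nrow(trainingSet@positives), nrow(trainingSet@negatives))),
              levels = c("neg", "pos"))
  if (length(unique(y)) < 2L) stop("training set must contain both classes")
  m <- .fitSvm(x, y, hyper, seed)
  new("TssModel", fit = m$fit, layout = trainingSet@layout,
      scaling = list(center = m$center, scale = m$scale),
      featureSet = trainingSet@layout$feature, hyper = m$hyper,
      flip = m$flip,
      metadata = list(seed = seed, span = as.integer(span),
                      binSize = as.integer(binSize),
                      trained = format(Sys.time(), "%Y-%m-%d"),
                      cv = if (is.null(cv)) NULL else cvSummary(cv)))
}

#' Decision values of a TSS model on a feature matrix
#'
#' @param model a [TssModel-class].
#' @param x numeric matrix whose columns follow the model's stored layout.
#' @param layout optional layout `data.frame` of `x`; when given it must be
#'   identical to the model's layout (feature names and bin counts), else a
#'   layout-mismatch error is raised.
#' @return numeric decision values, larger = more TSS-like.
#' @export
tssDecisionValues <- function(model, x, layout = NULL) {
  if (!is.null(layout)) {
    ml <- modelLayout(model)
    if (!identical(ml$feature, layout$feature) ||
        !identical(as.integer(ml$nBins), as.integer(layout$nBins)))
      stop("feature layout mismatch: model expects (",
           paste(ml$feature, ml$nBins, sep = ":", collapse = ", "),
           "), got (",
           paste(layout$feature, layout$nBins, sep = ":", collapse = ", "), ")")
  }
  if (ncol(x) != sum(modelLayout(model)$nBins))
    stop("feature layout mismatch: model expects ",
         sum(modelLayout(model)$nBins), " inputs, got ", ncol(x))
  .svmDecision(list(fit = model@fit, center = model@scaling$center,
                    scale = model@scaling$scale, flip = model@flip), x)
}

#' Scan the upstream window of a pre-miRNA for TSS candidates
#'
#' Scores every `step`-th position of the 10-kb (by default) upstream window
#' with the trained classifier, applies local non-maximum suppression within
#' `nmsRadius`, and returns at most `topK` candidates ranked by decreasing
#' decision value (ties broken by smaller distance to the precursor 5' end).
#' Rank 1 is the representative TSS.
#'
#' @param model a [TssModel-class].
#' @param preMirna `GRanges` of length 1 (the precursor locus) with metadata
#'   column `id`.
#' @param tracks,motifs named lists of [SignalTrack-class] objects and motif
#'   site `GRanges`, as in [featureMatrix()].
#' @param seqLengths named vector of sequence lengths.
#' @param window upstream window length (default 10000).
#' @param step scan resolution in bases (default 20).
#' @param topK maximum number of candidates (default 10).
#' @param nmsRadius non-maximum-suppression radius in bases (default 200).
#' @param est,conservation optional `GRanges` of EST 5' starts and
#'   conservation blocks; candidates overlapping them within +/-100 bp are
#'   flagged (`est_support`, `conservation_support`) as report-only evidence.
#' @return `GRanges` of 1-bp candidates with metadata columns `mirna`,
#'   `score`, `rank`, `distance` and per-feature evidence sums
#'   (`evidence_<feature>`); empty (with a warning) when the upstream window
#'   is empty.
#' @export
scanUpstreamTss <- function(model, preMirna, tracks, motifs = list(),
                            seqLengths = NULL, window = 10000L, step = 20L,
                            topK = 10L, nmsRadius = 200L, est = NULL,
                            conservation = NULL) {
  win <- tryCatch(upstreamWindow(preMirna, window, seqLengths),
                  error = function(e) NULL)
  if (is.null(win)) {
    warning("empty upstream window for ", mcols(preMirna)$id)
    return(GRanges())
  }
  strandChr <- as.character(strand(preMirna))
  pos <- seq(start(win), end(win), by = step)
  anchors <- GRanges(seqnames(win), IRanges(pos, width = 1L),
                     strand = strandChr)
  span <- model@metadata$span %||% 1000L
  binSize <- model@metadata$binSize %||% 200L
  fm <- featureMatrix(anchors, tracks, motifs,
                      featureSet = modelFeatureSet(model),
                      span = span, binSize = binSize)
  scores <- tssDecisionValues(model, fm$x, fm$layout)
  dist5 <- if (strandChr == "+") start(preMirna) - pos else pos - end(preMirna)
  ord <- order(-scores, dist5)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) >= topK) break
    if (all(abs(pos[i] - pos[keep]) > nmsRadius)) keep <- c(keep, i)
  }
  out <- anchors[keep]
  ev <- do.call(cbind, lapply(seq_len(nrow(fm$layout)), function(b) {
    cols <- sum(fm$layout$nBins[seq_len(b - 1)]) + seq_len(fm$layout$nBins[b])
    rowSums(fm$x[keep, cols, drop = FALSE])
  }))
  colnames(ev) <- paste0("evidence_", fm$layout$feature)
  mcols(out) <- DataFrame(mirna = mcols(preMirna)$id, score = scores[keep],
                          rank = seq_along(keep), distance = dist5[keep], ev)
  if (!is.null(est))
    mcols(out)$est_support <- countOverlaps(out + 100L, est) > 0L
  if (!is.null(conservation))
    mcols(out)$conservation_support <-
      countOverlaps(out + 100L, conservation) > 0L
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Represent an intragenic miRNA's TSS by its host gene TSS
#'
#' Intragenic miRNAs (precursor embedded in the same strand of an annotated
#' gene) are transcribed with their host; the host gene's TSS is reported as
#' the rank-1 candidate with evidence tag `"host_gene"`.
#'
#' @param preMirna `GRanges` of length 1 with metadata columns `id`,
#'   `intragenic` (`TRUE`) and `host_gene`.
#' @param hostGeneTss `GRanges` of 1-bp gene TSS records with metadata column
#'   `gene` (or `name`).
#' @return `GRanges` candidate of length 1 (rank 1, strand of the host TSS).
#' @export
resolveIntragenic <- function(preMirna, hostGeneTss) {
  if (!isTRUE(mcols(preMirna)$intragenic))
    stop("precursor ", mcols(preMirna)$id, " is not intragenic")
  host <- mcols(preMirna)$host_gene
  genes <- mcols(hostGeneTss)$gene
  if (is.null(genes)) genes <- mcols(hostGeneTss)$name
  hit <- which(genes == host)
  if (length(hit) == 0L)
    stop("no recorded TSS for host gene ", host)
  out <- granges(hostGeneTss[hit[1]])
  mcols(out) <- DataFrame(mirna = mcols(preMirna)$id, score = NA_real_,
                          rank = 1L, distance = NA_integer_,
                          evidence = "host_gene")
  out
}

#' Fraction of verified TSSs recovered by candidates
#'
#' @param candidates `GRanges` of TSS candidates with metadata column
#'   `mirna`.
#' @param verified `GRanges` of verified TSS positions; when it carries a
#'   `mirna` metadata column, candidates are matched per miRNA.
#' @param toleranceBp maximum distance (bases) for a verified TSS to count as
#'   recovered.
#' @return fraction in `[0, 1]`.
#' @export
evaluateOnVerified <- function(candidates, verified, toleranceBp = 0L) {
  if (length(verified) == 0L) stop("empty verified TSS list")
  if (toleranceBp < 0) stop("'toleranceBp' must be >= 0")
  vm <- mcols(verified)$mirna
  cm <- if (length(candidates)) mcols(candidates)$mirna else NULL
  hit <- vapply(seq_along(verified), function(i) {
    cand <- candidates
    if (!is.null(vm) && !is.null(cm)) cand <- cand[cm == vm[i]]
    if (length(cand) == 0L) return(FALSE)
    same <- as.character(seqnames(cand)) == as.character(seqnames(verified[i]))
    any(same & abs(start(cand) - start(verified[i])) <= toleranceBp)
  }, logical(1))
  mean(hit)
}

#' Save / load a trained TSS model
#'
#' The model file is a single self-contained archive holding the classifier,
#' feature layout, scaling parameters, hyperparameters and seed.
#'
#' @param model a [TssModel-class].
#' @param path file path.
#' @return `saveTssModel` the path invisibly; `readTssModel` the model.
#' @export
saveTssModel <- function(model, path) {
  stopifnot(is(model, "TssModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveTssModel
#' @export
readTssModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "TssModel")) stop("'", path, "' does not hold a TssModel")
  model
}
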