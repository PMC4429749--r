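# Binned feature extraction around anchors: per-position feature vectors for
# the classifier and aggregate meta-profiles around verified TSSs.

# Canonical feature order: signal tracks first, then core promoter motif
# classes; unknown (custom) features follow alphabetically. Fixed so that a
# feature-set given in any order always yields the same vector.
.KNOWN_FEATURES <- c("tss_tags", "h3k4me3", "h3k9ac", "h3",
                     "Y_patch", "Inr", "CA", "GA", "REG")

#' Canonical ordering of feature names
#' @param features character vector of feature names.
#' @return `features` reordered canonically (tracks, motif classes, then
#'   custom features alphabetically).
#' @export
canonicalFeatureOrder <- function(features) {
  c(intersect(.KNOWN_FEATURES, features),
    sort(setdiff(features, .KNOWN_FEATURES)))
}

# Bin coordinates for anchors on one sequence. Bins are ordered 5'->3' with
# respect to the anchor strand; the anchor base is the first base of bin
# nb/2 + 1. Returns per-anchor bin start positions (matrix n x nb).
.binStarts <- function(pos, strand, span, binSize) {
  nb <- 2L * span %/% binSize
  i <- seq_len(nb)
  plus <- outer(pos, (i - 1L) * binSize - span, "+")
  minus <- outer(pos, span - i * binSize + 1L, "+")
  out <- plus
  out[strand == "-", ] <- minus[strand == "-", , drop = FALSE]
  out
}

# Sum of per-base signal (or count of motif starts) per bin for many anchors
# on one sequence. `source` is an Rle (track) or an integer vector of motif
# start positions. Out-of-bounds bins contribute zero.
.binValuesOneSeq <- function(source, type, seqLen, pos, strand, span, binSize) {
  nb <- 2L * span %/% binSize
  st <- .binStarts(as.integer(pos), strand, as.integer(span),
                   as.integer(binSize))
  en <- st + as.integer(binSize) - 1L
  s2 <- pmax(as.vector(st), 1L)
  e2 <- pmin(as.vector(en), seqLen)
  vals <- numeric(length(s2))
  ok <- s2 <= e2
  if (any(ok)) {
    if (type == "track") {
      vals[ok] <- viewSums(Views(source, start = s2[ok], end = e2[ok]))
    } else {
      # counts of site start positions falling in each bin
      srt <- sort(as.integer(source))
      vals[ok] <- findInterval(e2[ok], srt) - findInterval(s2[ok] - 1L, srt)
    }
  }
  matrix(vals, ncol = nb)
}

# Per-anchor binned values for one feature over a whole anchor set.
# `tracks` entry: SignalTrack; `motif` entry: GRanges of sites.
.anchorBinMatrix <- function(feature, source, anchors, span, binSize,
                             genomeLengths) {
  if (2L * span %% binSize != 0L || span %% binSize != 0L)
    stop("'binSize' must divide 'span'")
  if (span <= 0L) stop("'span' must be positive")
  nb <- 2L * span %/% binSize
  out <- matrix(0, nrow = length(anchors), ncol = nb)
  sid <- as.character(seqnames(anchors))
  str <- as.character(strand(anchors))
  if (any(!str %in% c("+", "-")))
    stop("anchors must be stranded ('+' or '-')")
  isTrack <- is(source, "SignalTrack")
  for (s in unique(sid)) {
    idx <- which(sid == s)
    if (isTrack) {
      rl <- trackValues(source)
      if (!s %in% names(rl)) stop("no signal for sequence ", s,
                                  " in track '", featureName(source), "'")
      out[idx, ] <- .binValuesOneSeq(rl[[s]], "track", length(rl[[s]]),
                                     start(anchors)[idx], str[idx],
                                     span, binSize)
    } else {
      sites <- source[as.character(seqnames(source)) == s]
      sl <- if (!is.null(genomeLengths) && s %in% names(genomeLengths))
        as.integer(genomeLengths[s]) else .Machine$integer.max
      out[idx, ] <- .binValuesOneSeq(start(sites), "motif", sl,
                                     start(anchors)[idx], str[idx],
                                     span, binSize)
    }
  }
  out
}

#' Binned signal profile around one anchor
#'
#' Sums the per-base signal of a track in consecutive bins spanning `span`
#' bases on each side of the anchor, ordered 5'->3' with respect to the
#' anchor strand (minus-strand anchors mirror the bin order). Bins falling
#' outside the sequence are zero.
#'
#' @param track a [SignalTrack-class].
#' @param anchor a stranded 1-bp `GRanges` of length 1 (the anchor base is
#'   the first base of the first downstream bin).
#' @param span bases on each side of the anchor.
#' @param binSize bin width; must divide `span`.
#' @return a [FeatureProfile-class] with `2 * span / binSize` bins.
#' @export
windowSignal <- function(track, anchor, span = 1000L, binSize = 200L) {
  stopifnot(is(anchor, "GRanges"), length(anchor) == 1L)
  m <- .anchorBinMatrix(featureName(track), track, anchor,
                        as.integer(span), as.integer(binSize), NULL)
  FeatureProfile(featureName(track), m[1, ], binSize, span)
}

#' Binned motif-start density around one anchor
#'
#' Counts motif sites whose start position falls in each bin around the
#' anchor (same windowing as [windowSignal()]).
#'
#' @param sites `GRanges` of motif sites (one motif class).
#' @param anchor a stranded 1-bp `GRanges` of length 1.
#' @param span,binSize as in [windowSignal()].
#' @param motifClass label for the resulting profile (defaults to the
#'   `motif_class` metadata column when present).
#' @return a [FeatureProfile-class].
#' @export
motifDensity <- function(sites, anchor, span = 1000L, binSize = 200L,
                         motifClass = NULL) {
  stopifnot(is(anchor, "GRanges"), length(anchor) == 1L)
  if (is.null(motifClass))
    motifClass <- if (!is.null(mcols(sites)$motif_class) && length(sites))
      as.character(mcols(sites)$motif_class[1]) else "motif"
  m <- .anchorBinMatrix(motifClass, sites, anchor,
                        as.integer(span), as.integer(binSize), NULL)
  FeatureProfile(motifClass, m[1, ], binSize, span)
}

#' Cumulative meta-profile over many anchors
#'
#' Element-wise sum of the per-anchor binned profiles (the accumulative
#' feature count around experimentally verified TSSs: TSS tags, H3K9ac and
#' H3K4me3 peak at the TSS while nucleosome H3 dips).
#'
#' @param anchors stranded 1-bp `GRanges` of anchor positions (>= 1).
#' @param source a [SignalTrack-class] or a `GRanges` of motif sites.
#' @param span,binSize window geometry (defaults 5000/200, the meta-profile
#'   convention).
#' @return a [FeatureProfile-class] with `nAnchors = length(anchors)`.
#' @export
metaProfile <- function(anchors, source, span = 5000L, binSize = 200L) {
  if (length(anchors) == 0L) stop("need at least one anchor")
  feat <- if (is(source, "SignalTrack")) featureName(source) else {
    mc <- mcols(source)$motif_class
    if (!is.null(mc) && length(mc)) as.character(mc[1]) else "motif"
  }
  m <- .anchorBinMatrix(feat, source, anchors,
                        as.integer(span), as.integer(binSize), NULL)
  FeatureProfile(feat, colSums(m), binSize, span, nAnchors = length(anchors))
}

#' Feature matrix for many anchors
#'
#' Concatenates the binned profiles of the selected features in canonical
#' order (see [canonicalFeatureOrder()]) into one row per anchor. This is the
#' classifier input; the layout is identical for every anchor.
#'
#' @param anchors stranded 1-bp `GRanges`.
#' @param tracks named list of [SignalTrack-class] objects.
#' @param motifs named list of `GRanges` motif-site sets, one per motif
#'   class.
#' @param featureSet feature names to use (subset of
#'   `c(names(tracks), names(motifs))`); default all.
#' @param span,binSize window geometry (defaults 1000/200: 10 bins per
#'   feature).
#' @return list with `x` (numeric matrix) and `layout`
#'   (`data.frame(feature, nBins)`).
#' @export
featureMatrix <- function(anchors, tracks, motifs = list(),
                          featureSet = NULL, span = 1000L, binSize = 200L) {
  avail <- c(names(tracks), names(motifs))
  if (is.null(featureSet)) featureSet <- avail
  unknown <- setdiff(featureSet, avail)
  if (length(unknown))
    stop("unknown feature(s): ", paste(unknown, collapse = ", "),
         "; valid names: ", paste(avail, collapse = ", "))
  featureSet <- canonicalFeatureOrder(featureSet)
  nb <- 2L * as.integer(span) %/% as.integer(binSize)
  blocks <- lapply(featureSet, function(f) {
    src <- if (f %in% names(tracks)) tracks[[f]] else motifs[[f]]
    .anchorBinMatrix(f, src, anchors, as.integer(span),
                     as.integer(binSize), NULL)
  })
  x <- do.call(cbind, blocks)
  colnames(x) <- unlist(lapply(featureSet, function(f)
    paste0(f, "_bin", seq_len(nb))))
  if (!is.null(names(anchors))) rownames(x) <- names(anchors)
  else if (!is.null(mcols(anchors)$id)) rownames(x) <- mcols(anchors)$id
  list(x = x, layout = data.frame(feature = featureSet, nBins = nb,
                                  stringsAsFactors = FALSE))
}

#' Feature vector for a single anchor
#'
#' Single-anchor convenience wrapper around [featureMatrix()]; deterministic
#' for fixed inputs and independent of the order in which `featureSet` is
#' given.
#'
#' @inheritParams featureMatrix
#' @param anchor stranded 1-bp `GRanges` of length 1.
#' @return numeric vector with attribute `layout`.
#' @export
buildFeatureVector <- function(anchor, tracks, motifs = list(),
                               featureSet = NULL, span = 1000L,
                               binSize = 200L) {
  fm <- featureMatrix(anchor, tracks, motifs, featureSet, span, binSize)
  v <- fm$x[1, ]
  attr(v, "layout") <- fm$layout
  v
}

#' Plot a feature profile
#'
#' Simple line plot of a binned profile against the distance from the anchor
#' (the meta-profile figure style).
#'
#' @param profile a [FeatureProfile-class].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the x positions plotted.
#' @export
plotFeatureProfile <- function(profile, ...) {
  nb <- length(profileValues(profile))
  x <- (seq_len(nb) - nb / 2 - 1) * profileBinSize(profile) +
    profileBinSize(profile) / 2
  graphics::plot(x, profileValues(profile), type = "l",
                 xlab = "distance from anchor (bp)",
                 ylab = paste0("accumulated ", featureName(profile)), ...)
  invisible(x)
}
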