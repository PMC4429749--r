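#' @import methods
#' @importFrom S4Vectors Rle runValue mcols mcols<- DataFrame metadata
#' @importFrom IRanges IRanges RleList Views viewSums
#' @importFrom GenomicRanges GRanges granges coverage countOverlaps findOverlaps
#'   seqnames start end strand width strand<-
#' @importFrom GenomeInfoDb seqlengths seqlevels seqinfo Seqinfo seqlengths<-
#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet DNAString
#'   reverseComplement subseq
#' @importFrom stats cor sd rnorm runif rpois rbinom dhyper phyper p.adjust
#'   predict quantile
#' @importFrom utils read.delim write.table head
#' @importFrom tools md5sum
NULL

#' SignalTrack: per-base coverage for one chromatin or tag feature
#'
#' Holds one genome-wide per-base, non-negative signal (TSS tags, H3K4me3,
#' H3K9ac or nucleosome H3 coverage, or any custom track) as a run-length
#' encoded list with one element per sequence.
#'
#' @slot feature single feature label, e.g. `"h3k4me3"`.
#' @slot values an [IRanges::RleList] of per-base numeric values, one element
#'   per sequence; all values are >= 0.
#' @seealso [readSignalBedGraph()], [windowSignal()], [metaProfile()]
#' @exportClass SignalTrack
setClass("SignalTrack",
  representation(feature = "character", values = "RleList"))

setValidity("SignalTrack", function(object) {
  msg <- character()
  if (length(object@feature) != 1L || !nzchar(object@feature))
    msg <- c(msg, "'feature' must be a single non-empty string")
  if (is.null(names(object@values)) || any(!nzchar(names(object@values))))
    msg <- c(msg, "'values' must be named by sequence")
  mins <- vapply(object@values, function(r) {
    v <- runValue(r); if (length(v)) min(v) else 0
  }, numeric(1))
  if (any(mins < 0)) msg <- c(msg, "signal values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' SignalTrack constructor
#'
#' @param feature feature label.
#' @param values named `RleList` (or plain named list of numeric vectors) of
#'   per-base values.
#' @return a [SignalTrack-class] object.
#' @export
SignalTrack <- function(feature, values) {
  if (!is(values, "RleList")) values <- as(lapply(values, Rle), "RleList")
  new("SignalTrack", feature = feature, values = values)
}

#' FeatureProfile: binned signal or motif-density profile around anchors
#'
#' An ordered vector of bin values covering `span` bases on either side of an
#' anchor position, oriented 5'->3' with respect to the anchor strand; the
#' anchor base is the first base of bin `span / binSize + 1`.
#'
#' @slot feature feature label.
#' @slot values numeric bin values (length `2 * span / binSize`).
#' @slot binSize bin width in bases.
#' @slot span bases covered on each side of the anchor.
#' @slot nAnchors number of anchors aggregated into the profile.
#' @seealso [windowSignal()], [motifDensity()], [metaProfile()]
#' @exportClass FeatureProfile
setClass("FeatureProfile",
  representation(feature = "character", values = "numeric",
                 binSize = "integer", span = "integer", nAnchors = "integer"))

setValidity("FeatureProfile", function(object) {
  msg <- character()
  if (object@binSize <= 0L || object@span <= 0L)
    msg <- c(msg, "'binSize' and 'span' must be positive")
  else {
    if (object@span %% object@binSize != 0L)
      msg <- c(msg, "'binSize' must divide 'span'")
    if (length(object@values) != 2L * object@span %/% object@binSize)
      msg <- c(msg, "length(values) must equal 2 * span / binSize")
  }
  if (length(msg)) msg else TRUE
})

FeatureProfile <- function(feature, values, binSize, span, nAnchors = 1L) {
  new("FeatureProfile", feature = feature, values = as.numeric(values),
      binSize = as.integer(binSize), span = as.integer(span),
      nAnchors = as.integer(nAnchors))
}

#' TssTrainingSet: labelled feature vectors for the TSS classifier
#'
#' @slot positives numeric matrix, one row per verified-TSS anchor.
#' @slot negatives numeric matrix, one row per background anchor.
#' @slot layout `data.frame` with columns `feature`, `nBins` describing the
#'   column blocks of both matrices; identical for all vectors.
#' @slot provenance free-text description of the anchors used.
#' @exportClass TssTrainingSet
setClass("TssTrainingSet",
  representation(positives = "matrix", negatives = "matrix",
                 layout = "data.frame", provenance = "character"))

setValidity("TssTrainingSet", function(object) {
  msg <- character()
  if (nrow(object@positives) == 0L || nrow(object@negatives) == 0L)
    msg <- c(msg, "both classes must be non-empty")
  if (ncol(object@positives) != ncol(object@negatives))
    msg <- c(msg, "positives and negatives must share one feature layout")
  if (!all(c("feature", "nBins") %in% names(object@layout)))
    msg <- c(msg, "layout needs columns 'feature' and 'nBins'")
  else if (sum(object@layout$nBins) != ncol(object@positives))
    msg <- c(msg, "layout bin counts must sum to the vector length")
  if (length(msg)) msg else TRUE
})

#' TssTrainingSet constructor
#' @param positives,negatives feature matrices with a shared layout.
#' @param layout feature layout `data.frame` (`feature`, `nBins`).
#' @param provenance free-text provenance.
#' @return a [TssTrainingSet-class] object.
#' @export
TssTrainingSet <- function(positives, negatives, layout, provenance = "") {
  new("TssTrainingSet", positives = positives, negatives = negatives,
      layout = layout, provenance = provenance)
}

#' TssModel: a trained TSS classifier
#'
#' Wraps the fitted support vector machine together with everything needed to
#' apply it reproducibly: the feature layout, the per-column training
#' mean/standard deviation used for scaling, the feature set, hyperparameters
#' and training metadata (seed, date, cross-validation metrics).
#'
#' @slot fit the fitted classifier (an [e1071::svm] object).
#' @slot layout feature layout `data.frame` (`feature`, `nBins`).
#' @slot scaling list with numeric vectors `center` and `scale`.
#' @slot featureSet character vector of feature names used.
#' @slot hyper list of hyperparameters (kernel, cost, gamma).
#' @slot flip logical; `TRUE` if raw decision values must be negated so that
#'   larger values mean more TSS-like.
#' @slot metadata list (seed, trained date, optional CV metrics).
#' @exportClass TssModel
setClass("TssModel",
  representation(fit = "ANY", layout = "data.frame", scaling = "list",
                 featureSet = "character", hyper = "list", flip = "logical",
                 metadata = "list"))

setValidity("TssModel", function(object) {
  msg <- character()
  if (!all(c("center", "scale") %in% names(object@scaling)))
    msg <- c(msg, "scaling must hold 'center' and 'scale'")
  else if (length(object@scaling$center) != sum(object@layout$nBins))
    msg <- c(msg, "scaling length must match the layout")
  if (length(msg)) msg else TRUE
})

#' CvMetrics: cross-validation performance of a TSS classifier
#'
#' @slot perFold `data.frame` with one row per fold: confusion counts and
#'   sensitivity, specificity, precision, accuracy.
#' @slot summary named numeric vector of fold-mean metrics.
#' @slot nFolds number of folds.
#' @exportClass CvMetrics
setClass("CvMetrics",
  representation(perFold = "data.frame", summary = "numeric",
                 nFolds = "integer"))

setValidity("CvMetrics", function(object) {
  m <- object@summary
  need <- c("sensitivity", "specificity", "precision", "accuracy")
  if (!all(need %in% names(m)))
    return("summary must name sensitivity, specificity, precision, accuracy")
  if (any(m[need] < 0 | m[need] > 1, na.rm = TRUE))
    return("metrics must lie in [0, 1]")
  TRUE
})

#' RegulatoryNetwork: typed miRNA-centric regulatory graph
#'
#' Nodes are typed (`TF`, `miRNA`, `direct_target`, `indirect_target`) and
#' directed edges carry their provenance: TF->miRNA edges the coTFBS
#' statistic, miRNA->target edges the interaction evidence and expression
#' correlation, gene->gene edges the interaction source.
#'
#' @slot nodes `data.frame` with columns `id`, `type`.
#' @slot edges `data.frame` with columns `from`, `to`, `type` plus attribute
#'   columns.
#' @seealso [buildNetwork()], [exportNetwork()]
#' @exportClass RegulatoryNetwork
setClass("RegulatoryNetwork",
  representation(nodes = "data.frame", edges = "data.frame"))

setValidity("RegulatoryNetwork", function(object) {
  msg <- character()
  if (!all(c("id", "type") %in% names(object@nodes)))
    msg <- c(msg, "nodes need columns 'id' and 'type'")
  if (!all(c("from", "to", "type") %in% names(object@edges)))
    msg <- c(msg, "edges need columns 'from', 'to' and 'type'")
  if (anyDuplicated(object@nodes$id))
    msg <- c(msg, "duplicate node ids")
  bad <- setdiff(c(object@edges$from, object@edges$to), object@nodes$id)
  if (length(bad))
    msg <- c(msg, paste0("edge endpoint(s) missing from nodes: ",
                         paste(head(bad, 5), collapse = ", ")))
  okTypes <- c("TF", "miRNA", "direct_target", "indirect_target", "gene")
  if (!all(object@nodes$type %in% okTypes))
    msg <- c(msg, "unknown node type")
  if (length(msg)) msg else TRUE
})
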