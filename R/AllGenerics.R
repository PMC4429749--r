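#' Accessors for mirRegNet classes
#'
#' Small accessor generics so that slots are never reached into directly:
#' `featureName()` returns the feature label of a track or profile,
#' `trackValues()` the per-base `RleList` of a [SignalTrack-class],
#' `profileValues()`/`profileBinSize()`/`profileSpan()` the bins of a
#' [FeatureProfile-class], `cvSummary()`/`cvFolds()` the aggregated and
#' per-fold metrics of a [CvMetrics-class], `modelLayout()`/`modelFeatureSet()`
#' the stored layout of a [TssModel-class], and `netNodes()`/`netEdges()` the
#' typed tables of a [RegulatoryNetwork-class].
#'
#' @param x an object of the documented class.
#' @return the slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureName", function(x) standardGeneric("featureName"))
#' @rdname accessors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("profileBinSize", function(x) standardGeneric("profileBinSize"))
#' @rdname accessors
#' @export
setGeneric("profileSpan", function(x) standardGeneric("profileSpan"))
#' @rdname accessors
#' @export
setGeneric("cvSummary", function(x) standardGeneric("cvSummary"))
#' @rdname accessors
#' @export
setGeneric("cvFolds", function(x) standardGeneric("cvFolds"))
#' @rdname accessors
#' @export
setGeneric("modelLayout", function(x) standardGeneric("modelLayout"))
#' @rdname accessors
#' @export
setGeneric("modelFeatureSet", function(x) standardGeneric("modelFeatureSet"))
#' @rdname accessors
#' @export
setGeneric("modelMetadata", function(x) standardGeneric("modelMetadata"))
#' @rdname accessors
#' @export
setGeneric("netNodes", function(x) standardGeneric("netNodes"))
#' @rdname accessors
#' @export
setGeneric("netEdges", function(x) standardGeneric("netEdges"))

#' @rdname accessors
setMethod("featureName", "SignalTrack", function(x) x@feature)
#' @rdname accessors
setMethod("featureName", "FeatureProfile", function(x) x@feature)
#' @rdname accessors
setMethod("trackValues", "SignalTrack", function(x) x@values)
#' @rdname accessors
setMethod("profileValues", "FeatureProfile", function(x) x@values)
#' @rdname accessors
setMethod("profileBinSize", "FeatureProfile", function(x) x@binSize)
#' @rdname accessors
setMethod("profileSpan", "FeatureProfile", function(x) x@span)
#' @rdname accessors
setMethod("cvSummary", "CvMetrics", function(x) x@summary)
#' @rdname accessors
setMethod("cvFolds", "CvMetrics", function(x) x@perFold)
#' @rdname accessors
setMethod("modelLayout", "TssModel", function(x) x@layout)
#' @rdname accessors
setMethod("modelFeatureSet", "TssModel", function(x) x@featureSet)
#' @rdname accessors
setMethod("modelMetadata", "TssModel", function(x) x@metadata)
#' @rdname accessors
setMethod("netNodes", "RegulatoryNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("netEdges", "RegulatoryNetwork", function(x) x@edges)

setMethod("show", "SignalTrack", function(object) {
  lens <- vapply(object@values, length, integer(1))
  cat("SignalTrack '", object@feature, "' over ", length(lens),
      " sequence(s), ", sum(as.numeric(lens)), " bases\n", sep = "")
})

setMethod("show", "FeatureProfile", function(object) {
  cat("FeatureProfile '", object@feature, "': ", length(object@values),
      " bins of ", object@binSize, " bp (+/-", object@span, " bp, ",
      object@nAnchors, " anchor(s))\n", sep = "")
})

setMethod("show", "TssTrainingSet", function(object) {
  cat("TssTrainingSet: ", nrow(object@positives), " positives, ",
      nrow(object@negatives), " negatives, ",
      ncol(object@positives), " features (",
      paste(object@layout$feature, collapse = ", "), ")\n", sep = "")
})

setMethod("show", "TssModel", function(object) {
  cat("TssModel (", object@hyper$kernel, " SVM, cost=", object@hyper$cost,
      "): ", sum(object@layout$nBins), " inputs from features ",
      paste(object@featureSet, collapse = ", "), "\n", sep = "")
})

setMethod("show", "CvMetrics", function(object) {
  cat(object@nFolds, "-fold cross-validation (fold means):\n", sep = "")
  print(round(object@summary, 4))
})

setMethod("show", "RegulatoryNetwork", function(object) {
  cat("RegulatoryNetwork: ", nrow(object@nodes), " nodes (",
      paste(names(table(object@nodes$type)), table(object@nodes$type),
            sep = ":", collapse = ", "), "), ",
      nrow(object@edges), " edges\n", sep = "")
})
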