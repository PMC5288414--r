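#' Accessors for the core classes
#'
#' Small read-only accessors mirroring the slots of the package's S4
#' containers.
#'
#' @param x an object of the documented class.
#' @param object an object, for \code{show} methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("pixels", "DocumentImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("dim", "DocumentImage", function(x) dim(x@pixels))

#' @rdname accessors
#' @export
setMethod("docIds", "Corpus", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("docTokens", "Corpus", function(x) {
  out <- x@tokens
  names(out) <- x@ids
  out
})

#' @rdname accessors
#' @export
setMethod("docLabels", "Corpus", function(x) stats::setNames(x@labels, x@ids))

#' @rdname accessors
#' @export
setMethod("nDocs", "Corpus", function(x) length(x@ids))

#' @rdname accessors
#' @export
setMethod("length", "Corpus", function(x) length(x@ids))

#' @rdname accessors
#' @export
setMethod("[", "Corpus", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("Corpus", ids = x@ids[i], tokens = x@tokens[i], labels = x@labels[i])
})

#' @rdname accessors
#' @export
setMethod("vocabTerms", "Vocabulary", function(x) x@terms)

#' @rdname accessors
#' @export
setMethod("length", "Vocabulary", function(x) length(x@terms))

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("featureNames", "FeatureMatrix", function(x) x@featureNames)

#' @rdname accessors
#' @export
setMethod("docIds", "FeatureMatrix", function(x) x@docIds)

#' @rdname accessors
#' @export
setMethod("penaltyHint", "FeatureMatrix", function(x) x@penaltyHint)

#' @rdname accessors
#' @export
setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

#' @rdname accessors
#' @export
setMethod("topicWordMatrix", "TopicModel", function(x) x@topicWord)

#' @rdname accessors
#' @export
setMethod("wordTopicMatrix", "TopicModel", function(x) x@wordTopic)

#' @rdname accessors
#' @export
setMethod("nTopics", "TopicModel", function(x) x@nTopics)

#' @rdname accessors
#' @export
setMethod("vocabTerms", "TopicModel", function(x) x@vocabulary)

#' @rdname accessors
#' @export
setMethod("trainingTrace", "TopicModel", function(x) x@trace)

#' @rdname accessors
#' @export
setMethod("wordVectors", "EmbeddingModel", function(x) {
  out <- x@wordIn
  rownames(out) <- x@vocabulary
  out
})

#' @rdname accessors
#' @export
setMethod("paragraphVectors", "EmbeddingModel", function(x) {
  out <- x@para
  if (nrow(out)) rownames(out) <- x@docIds
  out
})

#' @rdname accessors
#' @export
setMethod("vocabTerms", "EmbeddingModel", function(x) x@vocabulary)

#' @rdname accessors
#' @export
setMethod("trainingTrace", "EmbeddingModel", function(x) x@trace)

#' @rdname accessors
#' @export
setMethod("modelWeights", "LinearSVM", function(x) {
  stats::setNames(x@weights, c(x@featureNames, "(bias)"))
})

#' @rdname accessors
#' @export
setMethod("pooledMetrics", "EvalReport", function(x) x@pooled)

#' @rdname accessors
#' @export
setMethod("foldMetrics", "EvalReport", function(x) x@perFold)

#' @rdname accessors
#' @export
setMethod("foldAssignments", "EvalReport", function(x) x@folds)

#' @rdname accessors
#' @export
setMethod("show", "DocumentImage", function(object) {
  d <- dim(object@pixels)
  bin <- all(object@pixels %in% c(0, 1))
  cat(sprintf("DocumentImage: %d x %d pixels (%s), %.1f%% black\n",
              d[1], d[2], if (bin) "binary" else "grayscale",
              100 * mean(object@pixels < 0.5)))
})

#' @rdname accessors
#' @export
setMethod("show", "Corpus", function(object) {
  lab <- object@labels
  cat(sprintf("Corpus: %d documents (%d positive, %d negative, %d unlabelled)\n",
              length(object@ids), sum(lab == 1L, na.rm = TRUE),
              sum(lab == 0L, na.rm = TRUE), sum(is.na(lab))))
  lens <- lengths(object@tokens)
  if (length(lens))
    cat(sprintf("  token counts: min %d / median %.0f / max %d\n",
                min(lens), stats::median(lens), max(lens)))
})

#' @rdname accessors
#' @export
setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d documents x %d features (penalty hint %s)\n",
              nrow(object@values), ncol(object@values), object@penaltyHint))
})

#' @rdname accessors
#' @export
setMethod("show", "TopicModel", function(object) {
  cat(sprintf("TopicModel: %d topics over %d terms (alpha=%.3g, beta=%.3g, %d sweeps)\n",
              object@nTopics, length(object@vocabulary), object@alpha,
              object@beta, object@nIterations))
})

#' @rdname accessors
#' @export
setMethod("show", "EmbeddingModel", function(object) {
  cat(sprintf("EmbeddingModel (%s): dim %d, window %d, |V|=%d, %d paragraph vectors\n",
              object@mode, object@dim, object@windowC,
              length(object@vocabulary), nrow(object@para)))
})

#' @rdname accessors
#' @export
setMethod("show", "LinearSVM", function(object) {
  nz <- sum(object@weights != 0)
  cat(sprintf("LinearSVM: %s penalty, C=%.4g, %d/%d non-zero weights\n",
              object@penalty, object@cost, nz, length(object@weights)))
})

#' @rdname accessors
#' @export
setMethod("show", "EvalReport", function(object) {
  p <- object@pooled
  cat(sprintf("EvalReport: %d folds, pooled accuracy %.3f, precision %.3f, recall %.3f, F2 %.3f\n",
              nrow(object@perFold), p["accuracy"], p["precision"],
              p["recall"], p["f2"]))
})
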