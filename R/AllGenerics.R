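# Generics for the package's accessor surface. Slot access from user code
# goes through these, never through @.

#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @export
setGeneric("docIds", function(x) standardGeneric("docIds"))

#' @export
setGeneric("docTokens", function(x) standardGeneric("docTokens"))

#' @export
setGeneric("docLabels", function(x) standardGeneric("docLabels"))

#' @export
setGeneric("nDocs", function(x) standardGeneric("nDocs"))

#' @export
setGeneric("vocabTerms", function(x) standardGeneric("vocabTerms"))

#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @export
setGeneric("penaltyHint", function(x) standardGeneric("penaltyHint"))

#' @export
setGeneric("topicWordMatrix", function(x) standardGeneric("topicWordMatrix"))

#' @export
setGeneric("wordTopicMatrix", function(x) standardGeneric("wordTopicMatrix"))

#' @export
setGeneric("nTopics", function(x) standardGeneric("nTopics"))

#' @export
setGeneric("wordVectors", function(x) standardGeneric("wordVectors"))

#' @export
setGeneric("paragraphVectors", function(x) standardGeneric("paragraphVectors"))

#' @export
setGeneric("trainingTrace", function(x) standardGeneric("trainingTrace"))

#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))

#' @export
setGeneric("pooledMetrics", function(x) standardGeneric("pooledMetrics"))

#' @export
setGeneric("foldMetrics", function(x) standardGeneric("foldMetrics"))

#' @export
setGeneric("foldAssignments", function(x) standardGeneric("foldAssignments"))
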