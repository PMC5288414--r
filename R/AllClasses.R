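#' @import methods
NULL

#' DocumentImage: a scanned page as a grayscale or binary raster
#'
#' Pixel intensities live in \[0, 1\] with 0 = black ink and 1 = white
#' background; the raster is stored row-major with the origin at the
#' top-left, so row 1 is the top pixel line of the page.
#'
#' @slot pixels numeric matrix of intensities in \[0, 1\].
#' @export
setClass("DocumentImage", representation(pixels = "matrix"))

setValidity("DocumentImage", function(object) {
  px <- object@pixels
  if (!is.numeric(px)) return("pixels must be a numeric matrix")
  if (length(px) == 0L) return("image must contain at least one pixel")
  if (anyNA(px) || any(!is.finite(px))) return("pixels must be finite")
  if (any(px < 0 | px > 1)) return("intensities must lie in [0, 1]")
  TRUE
})

#' SkewEstimate: result of entropy-minimising skew search
#'
#' @slot angleDeg corrective rotation angle in degrees (the grid angle
#'   minimising the row-profile entropy).
#' @slot entropy the entropy value at that angle (non-negative).
#' @slot profile the per-row black-pixel fraction profile at that angle.
#' @export
setClass("SkewEstimate",
         representation(angleDeg = "numeric", entropy = "numeric",
                        profile = "numeric"))

setValidity("SkewEstimate", function(object) {
  if (length(object@angleDeg) != 1L) return("angleDeg must be scalar")
  if (length(object@entropy) != 1L || object@entropy < -1e-12)
    return("entropy must be a non-negative scalar")
  if (any(object@profile < -1e-12 | object@profile > 1 + 1e-12))
    return("profile fractions must lie in [0, 1]")
  TRUE
})

#' RedactionRegion: a half-open rectangular region of a page
#'
#' Rows \code{rowStart:(rowEnd - 1)} and columns
#' \code{colStart:(colEnd - 1)} (1-based, half-open \code{[start, end)})
#' are covered by the region.
#'
#' @slot rowStart,rowEnd,colStart,colEnd integer bounds, half-open.
#' @export
setClass("RedactionRegion",
         representation(rowStart = "integer", rowEnd = "integer",
                        colStart = "integer", colEnd = "integer"))

setValidity("RedactionRegion", function(object) {
  b <- c(object@rowStart, object@rowEnd, object@colStart, object@colEnd)
  if (length(b) != 4L || anyNA(b)) return("all four bounds are required")
  if (object@rowStart < 1L || object@colStart < 1L)
    return("start bounds must be >= 1")
  if (object@rowEnd <= object@rowStart || object@colEnd <= object@colStart)
    return("end bounds must exceed start bounds (half-open region)")
  TRUE
})

#' Corpus: a set of tokenised, optionally labelled documents
#'
#' @slot ids unique document identifiers.
#' @slot tokens list of character vectors, one per document, already
#'   lower-cased and stop-word filtered.
#' @slot labels integer vector in \{0, 1\} (NA when unlabelled).
#' @export
setClass("Corpus",
         representation(ids = "character", tokens = "list",
                        labels = "integer"))

setValidity("Corpus", function(object) {
  n <- length(object@ids)
  if (length(object@tokens) != n) return("one token vector per id required")
  if (length(object@labels) != n) return("one label per id required")
  if (anyDuplicated(object@ids)) return("document ids must be unique")
  if (!all(vapply(object@tokens, is.character, logical(1))))
    return("tokens must be character vectors")
  lab <- object@labels[!is.na(object@labels)]
  if (length(lab) && !all(lab %in% c(0L, 1L)))
    return("labels must be 0/1 or NA")
  TRUE
})

#' Vocabulary: an ordered term dictionary
#'
#' Terms are unique and kept in deterministic (C-locale lexicographic)
#' order; the column index of a term is its position in \code{terms}.
#'
#' @slot terms character vector of unique terms.
#' @export
setClass("Vocabulary", representation(terms = "character"))

setValidity("Vocabulary", function(object) {
  if (anyDuplicated(object@terms)) return("terms must be unique")
  if (any(!nzchar(object@terms))) return("terms must be non-empty strings")
  TRUE
})

#' FeatureMatrix: documents-by-features matrix with a penalty hint
#'
#' @slot values numeric matrix or sparse \code{Matrix}, one row per
#'   document.
#' @slot featureNames column names.
#' @slot docIds row identifiers.
#' @slot penaltyHint "L1" for high-dimensional lexical families, "L2"
#'   for dense low-dimensional topic/embedding features.
#' @export
setClass("FeatureMatrix",
         representation(values = "ANY", featureNames = "character",
                        docIds = "character", penaltyHint = "character"))

setValidity("FeatureMatrix", function(object) {
  v <- object@values
  if (!(is.matrix(v) || is(v, "Matrix"))) return("values must be a matrix")
  if (ncol(v) != length(object@featureNames))
    return("featureNames length must match column count")
  if (nrow(v) != length(object@docIds))
    return("docIds length must match row count")
  if (!object@penaltyHint %in% c("L1", "L2"))
    return("penaltyHint must be 'L1' or 'L2'")
  TRUE
})

#' TopicModel: an LDA model fitted by collapsed Gibbs sampling
#'
#' @slot nTopics number of topics.
#' @slot topicWord topics-by-vocabulary row-stochastic matrix, row t =
#'   P(word | topic t).
#' @slot wordTopic vocabulary-by-topics row-stochastic matrix, row w =
#'   P(topic | word w).
#' @slot vocabulary the term dictionary the model indexes.
#' @slot alpha,beta symmetric Dirichlet concentrations.
#' @slot seed RNG seed used by the sampler.
#' @slot nIterations number of Gibbs sweeps.
#' @slot trace list with per-sweep diagnostics (complete-data
#'   log-likelihood and per-token predictive log-likelihood).
#' @export
setClass("TopicModel",
         representation(nTopics = "integer", topicWord = "matrix",
                        wordTopic = "matrix", vocabulary = "character",
                        alpha = "numeric", beta = "numeric",
                        seed = "integer", nIterations = "integer",
                        trace = "list"))

setValidity("TopicModel", function(object) {
  K <- object@nTopics; V <- length(object@vocabulary)
  if (!identical(dim(object@topicWord), c(K, V)))
    return("topicWord must be nTopics x vocabulary")
  if (!identical(dim(object@wordTopic), c(V, K)))
    return("wordTopic must be vocabulary x nTopics")
  bad <- function(m) any(m < -1e-12) ||
    any(abs(rowSums(m) - 1) > 1e-9)
  if (bad(object@topicWord)) return("topicWord rows must be stochastic")
  if (V > 0 && bad(object@wordTopic))
    return("wordTopic rows must be stochastic")
  TRUE
})

#' EmbeddingModel: CBoW word vectors and PV-DM paragraph vectors
#'
#' Trained with the full-softmax objective: context word vectors (and in
#' PV-DM mode the paragraph vector) are concatenated into a single
#' representation of width K, scored against every vocabulary word by the
#' output matrix, and softmax-normalised.
#'
#' @slot dim embedding dimensionality.
#' @slot windowC context half-window c (2c context slots).
#' @slot wordIn vocabulary-by-dim input word vectors.
#' @slot para nDocs-by-dim paragraph vectors (0-row in CBoW mode).
#' @slot wordOut vocabulary-by-K output score matrix, K = 2c*dim (+dim
#'   in PV-DM mode).
#' @slot vocabulary term dictionary.
#' @slot docIds training document ids (PV-DM).
#' @slot mode "cbow" or "pvdm".
#' @slot seed,learningRate,nEpochs training configuration.
#' @slot trace per-epoch average log-probability of the objective.
#' @export
setClass("EmbeddingModel",
         representation(dim = "integer", windowC = "integer",
                        wordIn = "matrix", para = "matrix",
                        wordOut = "matrix", vocabulary = "character",
                        docIds = "character", mode = "character",
                        seed = "integer", learningRate = "numeric",
                        nEpochs = "integer", trace = "numeric"))

setValidity("EmbeddingModel", function(object) {
  if (!object@mode %in% c("cbow", "pvdm")) return("mode must be cbow/pvdm")
  V <- length(object@vocabulary); d <- object@dim; c <- object@windowC
  K <- (2L * c + as.integer(object@mode == "pvdm")) * d
  if (!identical(dim(object@wordIn), c(V, d)))
    return("wordIn must be V x dim")
  if (!identical(dim(object@wordOut), c(V, K)))
    return("wordOut must be V x K with K matching the concatenation width")
  if (object@mode == "pvdm" && ncol(object@para) != d)
    return("para must have dim columns")
  if (any(!is.finite(object@wordIn)) || any(!is.finite(object@wordOut)) ||
      any(!is.finite(object@para)))
    return("embedding matrices must be finite")
  TRUE
})

#' LabeledMatrix: features, binary labels and row provenance
#'
#' @slot X n-by-d numeric matrix.
#' @slot y labels in \{0, 1\}.
#' @slot provenance "real" or "artificial" per row; artificial rows are
#'   always positives created by interpolation upsampling.
#' @export
setClass("LabeledMatrix",
         representation(X = "ANY", y = "integer", provenance = "character"))

setValidity("LabeledMatrix", function(object) {
  n <- nrow(object@X)
  if (length(object@y) != n || length(object@provenance) != n)
    return("y and provenance must match the row count")
  if (!all(object@y %in% c(0L, 1L))) return("labels must be 0/1")
  if (!all(object@provenance %in% c("real", "artificial")))
    return("provenance must be 'real' or 'artificial'")
  if (any(object@provenance == "artificial" & object@y != 1L))
    return("artificial rows must be labelled positive")
  TRUE
})

#' LinearSVM: a squared-hinge linear model
#'
#' The decision rule is sign(w'x) with the bias carried as a trailing
#' constant-one feature, regularised together with the rest of w.
#'
#' @slot weights numeric weight vector (last entry = bias weight).
#' @slot penalty "L1" or "L2".
#' @slot cost regularisation trade-off C (> 0).
#' @slot featureNames names of the non-bias features.
#' @slot objective final objective value reached by the solver.
#' @export
setClass("LinearSVM",
         representation(weights = "numeric", penalty = "character",
                        cost = "numeric", featureNames = "character",
                        objective = "numeric"))

setValidity("LinearSVM", function(object) {
  if (any(!is.finite(object@weights))) return("weights must be finite")
  if (!object@penalty %in% c("L1", "L2")) return("penalty must be L1/L2")
  if (object@cost <= 0) return("C must be positive")
  if (length(object@weights) != length(object@featureNames) + 1L)
    return("weights must be featureNames plus one bias entry")
  TRUE
})

#' EvalReport: per-fold and pooled classification metrics
#'
#' @slot perFold data.frame with one row per outer fold (confusion
#'   counts, accuracy, precision, recall, F2, selected C).
#' @slot pooled named numeric metrics from confusion counts summed over
#'   folds (the headline numbers).
#' @slot confusion named numeric TP/FP/TN/FN totals.
#' @slot folds named integer vector: document id -> outer fold.
#' @slot info free-form list of audit details (upsampling counts per
#'   fold, penalty, C grid).
#' @export
setClass("EvalReport",
         representation(perFold = "data.frame", pooled = "numeric",
                        confusion = "numeric", folds = "integer",
                        info = "list"))

setValidity("EvalReport", function(object) {
  need <- c("TP", "FP", "TN", "FN")
  if (!all(need %in% names(object@confusion)))
    return("confusion must contain TP, FP, TN, FN")
  TRUE
})
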