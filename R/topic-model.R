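corpusToIds <- function(corpus, terms) {
  lapply(docTokens(corpus), function(tk) match(tk, terms) - 1L)
}

#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Latent Dirichlet allocation with symmetric Dirichlet priors: alpha on
#' per-document topic proportions, beta on per-topic word distributions.
#' Inference is collapsed Gibbs sampling for \code{nIterations} full
#' sweeps; the sampler is deterministic given \code{seed}. From the
#' final count tables the model exposes the topic-word distributions
#' P(word | topic) and the word-topic posteriors P(topic | word), both
#' beta-smoothed.
#'
#' @param corpus a training \linkS4class{Corpus} (fit on training folds
#'   only).
#' @param nTopicsFit number of topics (>= 2).
#' @param alpha document-topic concentration; defaults to
#'   \code{50 / nTopicsFit}.
#' @param beta topic-word concentration (default 0.01).
#' @param nIterations Gibbs sweeps.
#' @param seed RNG seed.
#' @param heldout optional \linkS4class{Corpus} scored each sweep for
#'   the predictive-likelihood trace (otherwise the training corpus is
#'   scored).
#' @return a \linkS4class{TopicModel}.
#' @export
fitLDA <- function(corpus, nTopicsFit, alpha = 50 / nTopicsFit,
                   beta = 0.01, nIterations = 500L, seed = 1L,
                   heldout = NULL) {
  stopifnot(nTopicsFit >= 2L, nDocs(corpus) >= 1L)
  vocab <- buildVocabulary(corpus, ngrams = 1L)
  terms <- vocabTerms(vocab)
  if (length(terms) < 2L) stop("vocabulary must contain at least 2 terms")
  docs <- corpusToIds(corpus, terms)
  ho <- if (is.null(heldout)) list() else corpusToIds(heldout, terms)
  ho <- lapply(ho, function(v) v[!is.na(v)])
  fit <- lda_gibbs_fit(docs, length(terms), as.integer(nTopicsFit),
                       alpha, beta, as.integer(nIterations),
                       as.integer(seed), ho)
  nkw <- fit$nkw
  topicWord <- (nkw + beta) / (fit$nk + length(terms) * beta)
  wordTopic <- t(nkw) + beta
  wordTopic <- wordTopic / rowSums(wordTopic)
  colnames(topicWord) <- terms
  rownames(wordTopic) <- terms
  new("TopicModel", nTopics = as.integer(nTopicsFit),
      topicWord = topicWord, wordTopic = wordTopic,
      vocabulary = terms, alpha = alpha, beta = beta,
      seed = as.integer(seed), nIterations = as.integer(nIterations),
      trace = list(logLik = fit$traceJoint, predictive = fit$tracePred))
}

#' Topic-distribution vector of one document
#'
#' The document embedding is the arithmetic mean of the word-topic
#' posterior rows P(topic | word) over the document's in-vocabulary
#' tokens, L1-normalised ("word-avg", the default). The alternative
#' "doc-posterior" reading folds the document in by its smoothed
#' topic-assignment expectations: each token contributes its posterior
#' P(topic | word) reweighted by the topic-word likelihood; both give a
#' probability vector over topics. Empty or fully out-of-vocabulary
#' documents map to the uniform vector.
#'
#' @param model a fitted \linkS4class{TopicModel}.
#' @param tokens character vector of document tokens.
#' @param method "word-avg" (mean word-topic posterior) or
#'   "doc-posterior".
#' @return numeric simplex vector of length \code{nTopics(model)}.
#' @export
docTopicVector <- function(model, tokens, method = c("word-avg",
                                                     "doc-posterior")) {
  method <- match.arg(method)
  K <- nTopics(model)
  idx <- match(tokens, model@vocabulary)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) return(rep(1 / K, K))
  if (method == "word-avg") {
    v <- colMeans(model@wordTopic[idx, , drop = FALSE])
  } else {
    # expected topic counts under P(t | w) weighted by term frequency
    v <- colSums(model@wordTopic[idx, , drop = FALSE]) + model@alpha
  }
  v / sum(v)
}

#' Stack document topic vectors into a FeatureMatrix
#'
#' @param model a fitted \linkS4class{TopicModel} (trained on the
#'   training folds).
#' @param corpus documents to embed.
#' @param method embedding reading, see \code{\link{docTopicVector}}.
#' @return a dense \linkS4class{FeatureMatrix} of width
#'   \code{nTopics(model)} with penalty hint L2.
#' @export
topicFeatureMatrix <- function(model, corpus, method = "word-avg") {
  toks <- docTokens(corpus)
  m <- t(vapply(toks, function(tk) docTopicVector(model, tk, method),
                numeric(nTopics(model))))
  if (!length(toks)) m <- matrix(0, 0L, nTopics(model))
  new("FeatureMatrix", values = m,
      featureNames = sprintf("topic%03d", seq_len(nTopics(model))),
      docIds = docIds(corpus), penaltyHint = "L2")
}

#' Serialize a TopicModel to JSON
#'
#' @param model a \linkS4class{TopicModel}.
#' @param path output file ending in .json.
#' @return \code{writeTopicModel} returns \code{path} invisibly;
#'   \code{readTopicModel} the reconstructed model.
#' @export
writeTopicModel <- function(model, path) {
  jsonlite::write_json(
    list(nTopics = model@nTopics, vocabulary = model@vocabulary,
         topicWord = model@topicWord, wordTopic = model@wordTopic,
         alpha = model@alpha, beta = model@beta, seed = model@seed,
         nIterations = model@nIterations, trace = model@trace),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTopicModel
#' @export
readTopicModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tw <- as.matrix(x$topicWord); colnames(tw) <- x$vocabulary
  wt <- as.matrix(x$wordTopic); rownames(wt) <- x$vocabulary
  new("TopicModel", nTopics = as.integer(x$nTopics), topicWord = tw,
      wordTopic = wt, vocabulary = x$vocabulary, alpha = x$alpha,
      beta = x$beta, seed = as.integer(x$seed),
      nIterations = as.integer(x$nIterations),
      trace = lapply(x$trace, as.numeric))
}
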