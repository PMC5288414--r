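#' Numerically stable softmax probability
#'
#' Probability of the target index under the softmax of a score vector,
#' computed with the max-shift trick; probabilities over the whole
#' vector sum to one.
#'
#' @param scores finite numeric vector.
#' @param targetIndex 1-based index of the target entry.
#' @return scalar in (0, 1).
#' @export
softmaxProb <- function(scores, targetIndex) {
  stopifnot(all(is.finite(scores)), targetIndex >= 1,
            targetIndex <= length(scores))
  s <- scores - max(scores)
  exp(s[targetIndex]) / sum(exp(s))
}

embModes <- c(cbow = FALSE, pvdm = TRUE)

#' Concatenated context representation at a document position
#'
#' Builds the K-length vector scored by the output matrix: the 2c
#' context word input vectors (offsets -c..-1, +1..+c in document
#' order), each a dim-wide block, with out-of-window slots filled by a
#' zero pad block; in PV-DM mode the document's paragraph vector is
#' appended as the final block.
#'
#' @param model an \linkS4class{EmbeddingModel}.
#' @param tokens token vector of the document (for PV-DM training
#'   documents, pass the document's tokens and its \code{docIndex}).
#' @param position 1-based target position within \code{tokens}.
#' @param docIndex 1-based training-document index (PV-DM mode).
#' @return numeric vector of length K.
#' @export
contextRepresentation <- function(model, tokens, position, docIndex = 1L) {
  c <- model@windowC; d <- model@dim
  ids <- match(tokens, model@vocabulary)
  K <- (2L * c + (model@mode == "pvdm")) * d
  h <- numeric(K)
  slot <- 0L
  for (off in setdiff(-c:c, 0L)) {
    j <- position + off
    if (j >= 1L && j <= length(tokens) && !is.na(ids[j]))
      h[(slot * d + 1L):((slot + 1L) * d)] <- model@wordIn[ids[j], ]
    slot <- slot + 1L
  }
  if (model@mode == "pvdm")
    h[(2L * c * d + 1L):K] <- model@para[docIndex, ]
  h
}

embCorpusIds <- function(corpus, terms) {
  lapply(docTokens(corpus), function(tk) {
    id <- match(tk, terms)
    id[is.na(id)] <- 0L
    as.integer(id - 1L)   # 0-based; OOV -> -1
  })
}

buildEmbeddingModel <- function(fit, corpus, terms, dim, windowC, mode,
                                seed, lr, nEpochs) {
  new("EmbeddingModel", dim = as.integer(dim),
      windowC = as.integer(windowC), wordIn = fit$wordIn,
      para = fit$para, wordOut = fit$wordOut, vocabulary = terms,
      docIds = if (mode == "pvdm") docIds(corpus) else character(0),
      mode = mode, seed = as.integer(seed), learningRate = lr,
      nEpochs = as.integer(nEpochs), trace = as.numeric(fit$trace))
}

#' Train CBoW word vectors with the full-softmax objective
#'
#' Stochastic gradient ascent on the mean log-probability of each word
#' given its concatenated context window, scored by a full softmax over
#' the vocabulary (no hierarchical softmax or negative sampling: the
#' vocabularies this package targets are small enough for the exact
#' objective). Deterministic given \code{seed}; the learning rate
#' decays linearly over the run.
#'
#' @param corpus a \linkS4class{Corpus}.
#' @param dim embedding dimensionality (>= 2).
#' @param windowC context half-window c.
#' @param lr initial learning rate.
#' @param nEpochs training epochs.
#' @param seed RNG seed (initialisation).
#' @return an \linkS4class{EmbeddingModel} (mode "cbow") whose
#'   \code{trainingTrace} holds the per-epoch average log-probability.
#' @export
trainCBOW <- function(corpus, dim = 50L, windowC = 5L, lr = 0.025,
                      nEpochs = 50L, seed = 1L) {
  stopifnot(nDocs(corpus) >= 1L, dim >= 2L, windowC >= 1L)
  terms <- vocabTerms(buildVocabulary(corpus, 1L))
  docs <- embCorpusIds(corpus, terms)
  fit <- emb_train(docs, length(terms), as.integer(dim),
                   as.integer(windowC), lr, as.integer(nEpochs),
                   as.integer(seed), FALSE)
  buildEmbeddingModel(fit, corpus, terms, dim, windowC, "cbow",
                      seed, lr, nEpochs)
}

#' Train PV-DM paragraph vectors (doc2vec)
#'
#' Same objective and optimisation as \code{\link{trainCBOW}}, with the
#' document's paragraph vector concatenated into every context of that
#' document and updated alongside the word vectors.
#'
#' @inheritParams trainCBOW
#' @return an \linkS4class{EmbeddingModel} (mode "pvdm") whose
#'   \code{paragraphVectors} rows are the trained document embeddings.
#' @export
trainDoc2Vec <- function(corpus, dim = 150L, windowC = 5L, lr = 0.025,
                         nEpochs = 50L, seed = 1L) {
  stopifnot(nDocs(corpus) >= 1L, dim >= 2L, windowC >= 1L)
  terms <- vocabTerms(buildVocabulary(corpus, 1L))
  docs <- embCorpusIds(corpus, terms)
  fit <- emb_train(docs, length(terms), as.integer(dim),
                   as.integer(windowC), lr, as.integer(nEpochs),
                   as.integer(seed), TRUE)
  buildEmbeddingModel(fit, corpus, terms, dim, windowC, "pvdm",
                      seed, lr, nEpochs)
}

#' Infer a paragraph vector for an unseen document
#'
#' Gradient ascent on the training objective with respect to a fresh
#' paragraph vector only; the word input and output matrices stay
#' frozen, so held-out documents can be embedded without training
#' leakage. Documents with no in-vocabulary tokens return the zero
#' vector with a warning.
#'
#' @param model a trained PV-DM \linkS4class{EmbeddingModel}.
#' @param tokens token vector of the new document.
#' @param nSteps inference epochs over the document.
#' @param lr inference learning rate.
#' @return numeric vector of length \code{model@dim}.
#' @export
inferDocVector <- function(model, tokens, nSteps = 50L, lr = 0.05) {
  stopifnot(model@mode == "pvdm")
  ids <- match(tokens, model@vocabulary)
  ids[is.na(ids)] <- 0L
  ids <- as.integer(ids - 1L)
  if (!length(ids) || all(ids < 0L)) {
    warning("document has no in-vocabulary tokens: returning zero vector")
    return(numeric(model@dim))
  }
  as.numeric(emb_infer(model@wordIn, model@wordOut, ids,
                       model@windowC, as.integer(nSteps), lr))
}

#' Paragraph-vector FeatureMatrix for a corpus
#'
#' Training documents (matched by id) reuse their trained paragraph
#' vectors; any other document is embedded by
#' \code{\link{inferDocVector}} with frozen word matrices.
#'
#' @param model a trained PV-DM \linkS4class{EmbeddingModel}.
#' @param corpus documents to embed.
#' @param nSteps,lr inference settings for unseen documents.
#' @return a dense \linkS4class{FeatureMatrix} (penalty hint L2).
#' @export
embeddingFeatureMatrix <- function(model, corpus, nSteps = 50L, lr = 0.05) {
  ids <- docIds(corpus)
  toks <- docTokens(corpus)
  m <- matrix(0, length(ids), model@dim)
  trained <- match(ids, model@docIds)
  for (i in seq_along(ids)) {
    m[i, ] <- if (!is.na(trained[i])) model@para[trained[i], ]
              else inferDocVector(model, toks[[i]], nSteps, lr)
  }
  new("FeatureMatrix", values = m,
      featureNames = sprintf("dv%03d", seq_len(model@dim)),
      docIds = ids, penaltyHint = "L2")
}

#' Serialize an EmbeddingModel to JSON
#'
#' @param model an \linkS4class{EmbeddingModel}.
#' @param path output file ending in .json.
#' @return \code{writeEmbeddingModel} returns \code{path} invisibly;
#'   \code{readEmbeddingModel} the reconstructed model.
#' @export
writeEmbeddingModel <- function(model, path) {
  jsonlite::write_json(
    list(dim = model@dim, windowC = model@windowC, mode = model@mode,
         vocabulary = model@vocabulary, docIds = model@docIds,
         wordIn = model@wordIn, para = model@para,
         wordOut = model@wordOut, seed = model@seed,
         learningRate = model@learningRate, nEpochs = model@nEpochs,
         trace = model@trace),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeEmbeddingModel
#' @export
readEmbeddingModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  asMat <- function(m, nc) {
    m <- as.matrix(m)
    if (!length(m)) m <- matrix(0, 0L, nc)
    m
  }
  new("EmbeddingModel", dim = as.integer(x$dim),
      windowC = as.integer(x$windowC), wordIn = asMat(x$wordIn, x$dim),
      para = asMat(x$para, x$dim), wordOut = as.matrix(x$wordOut),
      vocabulary = x$vocabulary,
      docIds = as.character(x$docIds %||% character(0)), mode = x$mode,
      seed = as.integer(x$seed), learningRate = x$learningRate,
      nEpochs = as.integer(x$nEpochs), trace = as.numeric(x$trace))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
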