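.stopwordCache <- new.env(parent = emptyenv())

#' The shipped English stop-word list
#'
#' A standard 174-entry English stop list (articles, pronouns,
#' auxiliaries, prepositions, conjunctions) shipped under
#' \code{inst/extdata/stopwords_en.txt}; pass a different character
#' vector to \code{\link{tokenizeText}} to substitute a custom list.
#'
#' @return character vector of lower-case stop words.
#' @export
defaultStopwords <- function() {
  if (is.null(.stopwordCache$words)) {
    path <- system.file("extdata", "stopwords_en.txt",
                        package = "asdscreen", mustWork = TRUE)
    .stopwordCache$words <- readLines(path, encoding = "UTF-8")
  }
  .stopwordCache$words
}

#' Tokenize transcribed form text
#'
#' Lower-cases the text, splits on any non-alphabetic character, drops
#' empty fragments and removes stop words, preserving the original token
#' order. No stemming or spelling correction is applied.
#'
#' @param text a UTF-8 character scalar.
#' @param stopwords character vector of words to remove; defaults to the
#'   shipped list.
#' @return character vector of tokens (possibly empty).
#' @export
tokenizeText <- function(text, stopwords = defaultStopwords()) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- strsplit(tolower(text), "[^a-z]+")[[1]]
  toks <- toks[nzchar(toks)]
  toks[!toks %in% stopwords]
}

#' Extract joined n-grams from a token sequence
#'
#' @param tokens character vector of tokens.
#' @param n gram order, 2 (bigram) or 3 (trigram).
#' @return character vector of \code{max(0, length(tokens) - n + 1)}
#'   grams, tokens joined with "_", in order.
#' @export
extractNgrams <- function(tokens, n) {
  stopifnot(n %in% c(2L, 3L))
  L <- length(tokens)
  if (L < n) return(character(0))
  idx <- seq_len(L - n + 1L)
  parts <- lapply(seq_len(n) - 1L, function(o) tokens[idx + o])
  do.call(paste, c(parts, sep = "_"))
}

# per-document terms under a given set of gram orders (1 = unigrams)
docTerms <- function(tokens, ngrams) {
  unlist(lapply(ngrams, function(n) {
    if (n == 1L) tokens else extractNgrams(tokens, n)
  }), use.names = FALSE)
}

#' Build a Vocabulary from a training corpus
#'
#' Collects every distinct term (unigrams and/or joined n-grams) seen in
#' the corpus, in deterministic C-locale lexicographic order. Every
#' training term is kept: no minimum-frequency cutoff. Build the
#' vocabulary on training folds only and project held-out documents onto
#' it to avoid leakage.
#'
#' @param corpus a \linkS4class{Corpus}.
#' @param ngrams integer vector of gram orders drawn from \{1, 2, 3\};
#'   e.g. \code{c(2, 3)} for the combined bigram+trigram family.
#' @return a \linkS4class{Vocabulary}.
#' @export
buildVocabulary <- function(corpus, ngrams = 1L) {
  stopifnot(all(ngrams %in% 1:3))
  terms <- unique(unlist(lapply(docTokens(corpus), docTerms,
                                ngrams = as.integer(ngrams)),
                         use.names = FALSE))
  if (!length(terms)) stop("corpus yields an empty vocabulary")
  new("Vocabulary", terms = sort(terms, method = "radix"))
}

termCountMatrix <- function(corpus, vocab, ngrams) {
  terms <- vocabTerms(vocab)
  toks <- docTokens(corpus)
  n <- length(toks)
  triplets <- lapply(seq_len(n), function(d) {
    tt <- docTerms(toks[[d]], ngrams)
    j <- match(tt, terms)
    j <- j[!is.na(j)]
    if (!length(j)) return(NULL)
    tab <- table(j)
    cbind(d, as.integer(names(tab)), as.integer(tab))
  })
  trip <- do.call(rbind, triplets)
  if (is.null(trip))
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = double(0),
                                dims = c(n, length(terms))))
  Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                       dims = c(n, length(terms)))
}

#' Bag-of-words count matrix
#'
#' Entry (d, w) is the raw count of vocabulary term w in document d;
#' terms absent from the vocabulary are ignored (held-out documents
#' project onto the training vocabulary). Penalty hint is L1, the
#' regulariser paired with high-dimensional lexical families.
#'
#' @param corpus a \linkS4class{Corpus}.
#' @param vocab a \linkS4class{Vocabulary} built from the training
#'   corpus.
#' @param ngrams gram orders matching how \code{vocab} was built.
#' @return a sparse \linkS4class{FeatureMatrix}.
#' @export
bowMatrix <- function(corpus, vocab, ngrams = 1L) {
  if (!length(vocabTerms(vocab))) stop("empty vocabulary")
  m <- termCountMatrix(corpus, vocab, as.integer(ngrams))
  new("FeatureMatrix", values = m, featureNames = vocabTerms(vocab),
      docIds = docIds(corpus), penaltyHint = "L1")
}

#' Tf-idf weighted matrix
#'
#' Term frequency is the raw in-document count; the inverse document
#' frequency is \code{log(N / (1 + df(w)))} with natural logarithm,
#' where df(w) counts the documents of the corpus containing w. The
#' +1 smoothing in the denominator is kept exactly, so a term present
#' in every document gets a negative idf.
#'
#' @inheritParams bowMatrix
#' @return a sparse \linkS4class{FeatureMatrix} (penalty hint L1).
#' @export
tfIdfMatrix <- function(corpus, vocab, ngrams = 1L) {
  if (nDocs(corpus) == 0L) stop("empty corpus: N = 0")
  counts <- termCountMatrix(corpus, vocab, as.integer(ngrams))
  N <- nrow(counts)
  df <- Matrix::colSums(counts > 0)
  idf <- log(N / (1 + df))
  m <- counts %*% Matrix::Diagonal(x = idf)
  new("FeatureMatrix", values = m, featureNames = vocabTerms(vocab),
      docIds = docIds(corpus), penaltyHint = "L1")
}

#' Column-wise combination of feature families
#'
#' Concatenates the matrices of a named list column-wise; feature names
#' are prefixed with the family name ("bow:", "tfidf:", ...). All
#' matrices must describe the same documents in the same order. The
#' combined penalty hint is the shared hint when all families agree,
#' otherwise L1 (combinations in practice join lexical families).
#'
#' @param matrices named list of \linkS4class{FeatureMatrix} objects.
#' @return a \linkS4class{FeatureMatrix}.
#' @export
combineFeatures <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  if (is.null(names(matrices)) || any(!nzchar(names(matrices))))
    names(matrices) <- paste0("m", seq_along(matrices))
  ns <- vapply(matrices, nrow, integer(1))
  if (length(unique(ns)) != 1L)
    stop("feature matrices have mismatched row counts")
  ids <- docIds(matrices[[1]])
  for (m in matrices[-1])
    if (!identical(docIds(m), ids)) stop("document ids differ across matrices")
  vals <- do.call(cbind, lapply(matrices, featureValues))
  nms <- unlist(lapply(names(matrices), function(nm)
    paste0(nm, ":", featureNames(matrices[[nm]]))), use.names = FALSE)
  hints <- unique(vapply(matrices, penaltyHint, character(1)))
  new("FeatureMatrix", values = vals, featureNames = nms, docIds = ids,
      penaltyHint = if (length(hints) == 1L) hints else "L1")
}

#' FeatureMatrix constructor from a plain matrix
#'
#' @param values matrix or Matrix, documents in rows.
#' @param featureNames,docIds optional names (defaults generated).
#' @param penaltyHint "L1" or "L2".
#' @return a \linkS4class{FeatureMatrix}.
#' @export
FeatureMatrix <- function(values, featureNames = NULL, docIds = NULL,
                          penaltyHint = "L2") {
  if (is.null(featureNames))
    featureNames <- colnames(values)
  if (is.null(featureNames))
    featureNames <- sprintf("f%04d", seq_len(ncol(values)))
  if (is.null(docIds)) docIds <- rownames(values)
  if (is.null(docIds)) docIds <- sprintf("doc%04d", seq_len(nrow(values)))
  new("FeatureMatrix", values = values, featureNames = featureNames,
      docIds = docIds, penaltyHint = penaltyHint)
}

#' Write and read feature matrices as MatrixMarket plus sidecar JSON
#'
#' The values go to \code{<path>.mtx} (MatrixMarket) and the metadata
#' (feature names, document ids, penalty hint) to \code{<path>.json}.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param path base path without extension.
#' @return \code{writeFeatureMatrix} returns \code{path} invisibly;
#'   \code{readFeatureMatrix} returns the \linkS4class{FeatureMatrix}.
#' @export
writeFeatureMatrix <- function(fm, path) {
  v <- featureValues(fm)
  if (!is(v, "sparseMatrix")) v <- Matrix::Matrix(as.matrix(v), sparse = TRUE)
  Matrix::writeMM(as(v, "generalMatrix"), paste0(path, ".mtx"))
  jsonlite::write_json(
    list(featureNames = featureNames(fm), docIds = docIds(fm),
         penaltyHint = penaltyHint(fm)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  v <- Matrix::readMM(paste0(path, ".mtx"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("FeatureMatrix", values = methods::as(v, "CsparseMatrix"),
      featureNames = meta$featureNames,
      docIds = meta$docIds, penaltyHint = meta$penaltyHint)
}
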