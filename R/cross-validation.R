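# stratified fold assignment: positives and negatives are spread
# separately over k folds in seeded random order
stratifiedFolds <- function(y, k, seed) {
  withr::with_seed(as.integer(seed), {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Per-fold featurizers for nested cross-validation
#'
#' A featurizer is a function \code{(trainCorpus, testCorpus, seed)}
#' returning \code{list(train=, test=)} of \linkS4class{FeatureMatrix}
#' objects whose models (vocabulary, topic model, embedding) are fitted
#' on the training documents only; test documents are projected onto
#' the training vocabulary, embedded with the training topic model, or
#' inferred with frozen word matrices.
#'
#' \code{lexicalFeaturizer} builds BoW ("bow"), tf-idf ("tfidf"), the
#' bigram+trigram family ("ngram") or the column-wise combination of
#' all three ("lexical"). \code{ldaFeaturizer} and
#' \code{doc2vecFeaturizer} wrap \code{\link{fitLDA}} and
#' \code{\link{trainDoc2Vec}}.
#'
#' @param method lexical family name.
#' @return a featurizer function.
#' @export
lexicalFeaturizer <- function(method = c("bow", "tfidf", "ngram",
                                         "lexical")) {
  method <- match.arg(method)
  function(trainCorpus, testCorpus, seed) {
    one <- function(m) {
      ngrams <- if (m == "ngram") c(2L, 3L) else 1L
      vocab <- buildVocabulary(trainCorpus, ngrams)
      fun <- if (m == "tfidf") tfIdfMatrix else bowMatrix
      list(train = fun(trainCorpus, vocab, ngrams),
           test = fun(testCorpus, vocab, ngrams))
    }
    if (method != "lexical") return(one(method))
    parts <- lapply(c(bow = "bow", tfidf = "tfidf", ngram = "ngram"), one)
    list(train = combineFeatures(lapply(parts, `[[`, "train")),
         test = combineFeatures(lapply(parts, `[[`, "test")))
  }
}

#' @rdname lexicalFeaturizer
#' @param nTopicsFit,nIterations,alpha,beta LDA settings (see
#'   \code{\link{fitLDA}}).
#' @export
ldaFeaturizer <- function(nTopicsFit = 200L, nIterations = 500L,
                          alpha = 50 / nTopicsFit, beta = 0.01) {
  function(trainCorpus, testCorpus, seed) {
    model <- fitLDA(trainCorpus, nTopicsFit, alpha, beta, nIterations,
                    seed = seed)
    list(train = topicFeatureMatrix(model, trainCorpus),
         test = topicFeatureMatrix(model, testCorpus))
  }
}

#' @rdname lexicalFeaturizer
#' @param dim,windowC,lr,nEpochs,inferSteps,inferLr doc2vec settings
#'   (see \code{\link{trainDoc2Vec}} and \code{\link{inferDocVector}});
#'   inference reuses the training learning rate by default.
#' @export
doc2vecFeaturizer <- function(dim = 150L, windowC = 5L, lr = 0.025,
                              nEpochs = 50L, inferSteps = 50L,
                              inferLr = lr) {
  function(trainCorpus, testCorpus, seed) {
    model <- trainDoc2Vec(trainCorpus, dim, windowC, lr, nEpochs,
                          seed = seed)
    list(train = embeddingFeatureMatrix(model, trainCorpus,
                                        nSteps = inferSteps,
                                        lr = inferLr),
         test = embeddingFeatureMatrix(model, testCorpus,
                                       nSteps = inferSteps,
                                       lr = inferLr))
  }
}

evalOneC <- function(Xtr, ytr, Xte, yte, penalty, C) {
  fit <- trainLinearSVM(Xtr, ytr, penalty, C)
  pred <- predict(fit, Xte)
  computeMetrics(yte, pred)$f2
}

#' Nested cross-validation with F2-oriented model selection
#'
#' Outer stratified \code{outerK}-fold evaluation with inner
#' \code{innerK}-fold selection of the regularisation trade-off C by
#' mean F2. Within each outer fold: the training split (and only it) is
#' optionally upsampled; for each candidate C, the inner folds upsample
#' their own training portions, train, and score F2 on the untouched
#' inner validation portions; the best C (smallest on ties) retrains on
#' the upsampled outer training split, and predictions are made for the
#' untouched outer test split. Test folds never contain artificial
#' rows, and every document is predicted exactly once.
#'
#' @param x a \linkS4class{FeatureMatrix} (precomputed features used
#'   as-is), or a \linkS4class{Corpus} together with \code{featurizer}
#'   for honest per-fold featurization.
#' @param labels 0/1 labels; defaults to the corpus labels when
#'   \code{x} is a \linkS4class{Corpus}.
#' @param outerK,innerK fold counts (study setting: 7 and 5).
#' @param cGrid candidate C values.
#' @param penalty "L1"/"L2"; defaults to the feature matrix's penalty
#'   hint ("L2" for featurizer-produced topic/embedding features, "L1"
#'   for lexical ones).
#' @param upsample \code{NULL} for none, or a list with
#'   \code{nPerPositive} (and optionally \code{k}) passed to
#'   \code{\link{upsamplePositives}}.
#' @param seed RNG seed controlling folds, upsampling and featurizer
#'   models; results are deterministic given the seed.
#' @param featurizer per-fold featurizer (see
#'   \code{\link{lexicalFeaturizer}}), required when \code{x} is a
#'   \linkS4class{Corpus}.
#' @return an \linkS4class{EvalReport}.
#' @export
nestedCV <- function(x, labels = NULL, outerK = 7L, innerK = 5L,
                     cGrid = 2^seq(-5, 5, by = 2), penalty = NULL,
                     upsample = list(nPerPositive = 2L), seed = 1L,
                     featurizer = NULL) {
  if (is(x, "Corpus")) {
    if (is.null(featurizer))
      stop("a featurizer is required when x is a Corpus")
    if (is.null(labels)) labels <- as.integer(docLabels(x))
    ids <- docIds(x)
  } else {
    stopifnot(is(x, "FeatureMatrix"))
    ids <- docIds(x)
    if (is.null(penalty)) penalty <- penaltyHint(x)
  }
  y <- as.integer(labels)
  stopifnot(length(y) == length(ids), all(y %in% c(0L, 1L)))
  n <- length(y)
  if (n < outerK) stop("fewer documents than outer folds")
  fold <- stratifiedFolds(y, outerK, seed)
  upN <- if (is.null(upsample)) 0L else as.integer(upsample$nPerPositive)
  upK <- if (is.null(upsample)) 0L
         else as.integer(upsample$k %||% upsample$nPerPositive)

  perFold <- vector("list", outerK)
  predAll <- integer(n)
  info <- list(penalty = penalty, cGrid = cGrid,
               upsample = upsample, artificialPerFold = integer(outerK))

  for (f in seq_len(outerK)) {
    trIdx <- which(fold != f); teIdx <- which(fold == f)
    if (length(unique(y[trIdx])) < 2L || length(teIdx) == 0L)
      stop(sprintf("outer fold %d is missing a class", f))
    foldSeed <- as.integer(seed) + 1000L * f
    if (is(x, "Corpus")) {
      fm <- featurizer(x[trIdx], x[teIdx], foldSeed)
      Xtr <- featureValues(fm$train); Xte <- featureValues(fm$test)
      if (is.null(penalty)) penalty <- penaltyHint(fm$train)
      if (is.null(info$penalty)) info$penalty <- penalty
    } else {
      Xtr <- featureValues(x)[trIdx, , drop = FALSE]
      Xte <- featureValues(x)[teIdx, , drop = FALSE]
    }
    ytr <- y[trIdx]; yte <- y[teIdx]

    # inner C selection on mean F2
    bestC <- cGrid[1]
    if (length(cGrid) > 1L) {
      innerFold <- stratifiedFolds(ytr, innerK, foldSeed + 1L)
      meanF2 <- vapply(cGrid, function(C) {
        f2s <- vapply(seq_len(innerK), function(g) {
          iTr <- which(innerFold != g); iVa <- which(innerFold == g)
          if (length(unique(ytr[iTr])) < 2L || !length(iVa)) return(NA_real_)
          Xi <- Xtr[iTr, , drop = FALSE]; yi <- ytr[iTr]
          if (upN > 0L) {
            lm <- upsamplePositives(LabeledMatrix(as.matrix(Xi), yi),
                                    upN, upK, seed = foldSeed + 10L + g)
            Xi <- lm@X; yi <- lm@y
          }
          evalOneC(Xi, yi, Xtr[iVa, , drop = FALSE], ytr[iVa], penalty, C)
        }, numeric(1))
        mean(f2s, na.rm = TRUE)
      }, numeric(1))
      bestC <- cGrid[which.max(meanF2)]
    }

    Xfit <- Xtr; yfit <- ytr
    if (upN > 0L) {
      lm <- upsamplePositives(LabeledMatrix(as.matrix(Xtr), ytr),
                              upN, upK, seed = foldSeed + 2L)
      Xfit <- lm@X; yfit <- lm@y
      info$artificialPerFold[f] <- sum(lm@provenance == "artificial")
    }
    fit <- trainLinearSVM(Xfit, yfit, penalty, bestC)
    pred <- predict(fit, Xte)
    predAll[teIdx] <- pred
    m <- computeMetrics(yte, pred)
    perFold[[f]] <- data.frame(fold = f, n = length(teIdx), C = bestC,
                               TP = m$TP, FP = m$FP, TN = m$TN, FN = m$FN,
                               accuracy = m$accuracy,
                               precision = m$precision,
                               recall = m$recall, f2 = m$f2)
  }

  pf <- do.call(rbind, perFold)
  pooled <- computeMetrics(y, predAll)
  new("EvalReport", perFold = pf,
      pooled = c(accuracy = pooled$accuracy, precision = pooled$precision,
                 recall = pooled$recall, f2 = pooled$f2),
      confusion = c(TP = pooled$TP, FP = pooled$FP, TN = pooled$TN,
                    FN = pooled$FN),
      folds = stats::setNames(fold, ids), info = info)
}

#' Write an EvalReport as JSON plus a per-fold CSV
#'
#' @param report an \linkS4class{EvalReport}.
#' @param path base path without extension; writes \code{<path>.json}
#'   and \code{<path>_folds.csv}.
#' @return \code{path}, invisibly.
#' @export
writeEvalReport <- function(report, path) {
  jsonlite::write_json(
    list(pooled = as.list(report@pooled),
         confusion = as.list(report@confusion),
         perFold = report@perFold,
         folds = as.list(report@folds),
         info = report@info[c("penalty", "cGrid", "artificialPerFold")]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report@perFold, paste0(path, "_folds.csv"),
                   row.names = FALSE)
  invisible(path)
}
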