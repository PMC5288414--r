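test_that("tokenizer lowercases, splits and removes stop words in order", {
  expect_equal(tokenizeText("He is a boy", stopwords = c("he", "is", "a")),
               "boy")
  expect_equal(tokenizeText(""), character(0))
  expect_equal(tokenizeText("Night-time SLEEP, 3 naps!",
                            stopwords = character(0)),
               c("night", "time", "sleep", "naps"))
  # shipped list: documented size, and filtering equals a manual scan
  expect_length(defaultStopwords(), 174)
  para <- paste("The child does not respond to his name and he avoids",
                "eye contact with other children during play but she is",
                "very focused on spinning objects for a long time and",
                "has been flapping both hands when she gets too excited")
  got <- tokenizeText(para)
  raw <- strsplit(tolower(para), "[^a-z]+")[[1]]
  raw <- raw[nzchar(raw)]
  manual <- raw[!raw %in% defaultStopwords()]
  expect_identical(got, manual)
})

test_that("n-gram extraction yields L - n + 1 ordered joined grams", {
  expect_equal(extractNgrams(c("a", "b", "c"), 2), c("a_b", "b_c"))
  expect_equal(extractNgrams("a", 2), character(0))
  toks <- sprintf("t%02d", 1:50)
  expect_length(extractNgrams(toks, 3), 48)
  expect_equal(extractNgrams(toks, 3)[1], "t01_t02_t03")
  expect_error(extractNgrams(toks, 4), "n")
})

test_that("bag-of-words counts match a brute-force recount", {
  corp <- Corpus(c("d1", "d2"),
                 list(c("x", "x", "y"), c("zz", "qq")),
                 c(1L, 0L))
  vocab <- buildVocabulary(corp[1])          # trained on d1 only
  fm <- bowMatrix(corp, vocab)
  expect_equal(featureNames(fm), c("x", "y"))
  expect_equal(as.numeric(featureValues(fm)[1, ]), c(2, 1))
  expect_equal(as.numeric(featureValues(fm)[2, ]), c(0, 0))  # OOV row
  sim <- simulateCorpus(nPos = 5, nNeg = 5, vocabSize = 30,
                        docLengthMean = 25, seed = 6)
  v <- buildVocabulary(sim$corpus)
  m <- featureValues(bowMatrix(sim$corpus, v))
  inVocab <- vapply(docTokens(sim$corpus),
                    function(tk) sum(tk %in% vocabTerms(v)), numeric(1))
  expect_equal(as.numeric(Matrix::rowSums(m)), unname(inVocab))
})

test_that("tf-idf keeps the printed +1 smoothing including negative idf", {
  # N = 2, term in exactly one document: idf = ln(2/2) = 0
  corp2 <- Corpus(c("a", "b"), list(c("w"), c("v")))
  v2 <- buildVocabulary(corp2)
  expect_equal(as.numeric(featureValues(tfIdfMatrix(corp2, v2))),
               rep(0, 4))
  # N = 4, df = 1, tf = 3 -> 3 ln 2
  corp4 <- Corpus(letters[1:4],
                  list(c("w", "w", "w"), "x", "x", "x"))
  v4 <- buildVocabulary(corp4)
  m4 <- featureValues(tfIdfMatrix(corp4, v4))
  expect_equal(m4[1, match("w", vocabTerms(v4))], 3 * log(2),
               tolerance = 1e-12)
  expect_equal(3 * log(2), 2.0794, tolerance = 1e-4)
  # a term in all N documents is forced negative: ln(N/(N+1)) < 0
  corpAll <- Corpus(letters[1:3], list(c("u", "a"), c("u", "b"), c("u", "c")))
  vAll <- buildVocabulary(corpAll)
  mAll <- featureValues(tfIdfMatrix(corpAll, vAll))
  uCol <- match("u", vocabTerms(vAll))
  expect_true(all(mAll[, uCol] < 0))
  expect_equal(mAll[1, uCol], log(3 / 4), tolerance = 1e-12)
  # one-document corpus: every present term has df = 1, idf = ln(1/2),
  # so all non-zero entries share that negative sign
  corp1 <- Corpus("only", list(c("p", "q", "q")))
  m1 <- featureValues(tfIdfMatrix(corp1, buildVocabulary(corp1)))
  expect_true(all(m1[m1 != 0] < 0))
})

test_that("n-gram vocabulary counts distinct joined grams", {
  corp <- Corpus(c("d1", "d2"),
                 list(c("a", "b", "a", "b"), c("b", "c", "d")))
  v <- buildVocabulary(corp, ngrams = c(2L, 3L))
  grams2 <- unique(unlist(lapply(docTokens(corp), extractNgrams, n = 2)))
  grams3 <- unique(unlist(lapply(docTokens(corp), extractNgrams, n = 3)))
  expect_length(vocabTerms(v), length(grams2) + length(grams3))
  fm <- bowMatrix(corp, v, ngrams = c(2L, 3L))
  expect_equal(ncol(featureValues(fm)), length(grams2) + length(grams3))
})

test_that("feature combination concatenates columns with source prefixes", {
  mk <- function(nc, hint) {
    FeatureMatrix(Matrix::rsparsematrix(5, nc, density = 0.1,
                                        rand.x = function(n) rep(1, n)),
                  featureNames = sprintf("c%d", seq_len(nc)),
                  docIds = sprintf("doc%d", 1:5), penaltyHint = hint)
  }
  # the study's lexical families: 4839 + 4839 + 9284 = 18962 columns
  comb <- combineFeatures(list(bow = mk(4839, "L1"),
                               tfidf = mk(4839, "L1"),
                               ngram = mk(9284, "L1")))
  expect_equal(ncol(featureValues(comb)), 18962)
  expect_equal(penaltyHint(comb), "L1")
  single <- combineFeatures(list(only = mk(3, "L2")))
  expect_equal(dim(featureValues(single)), c(5L, 3L))
  # every column is retrievable from its source by prefix
  a <- mk(4, "L1"); b <- mk(2, "L1")
  ab <- combineFeatures(list(alpha = a, beta = b))
  expect_equal(featureNames(ab),
               c(paste0("alpha:", featureNames(a)),
                 paste0("beta:", featureNames(b))))
  expect_equal(as.matrix(featureValues(ab)[, startsWith(featureNames(ab),
                                                        "beta:")]),
               as.matrix(featureValues(b)), ignore_attr = TRUE)
  bad <- FeatureMatrix(matrix(0, 4, 2), penaltyHint = "L1")
  expect_error(combineFeatures(list(a, bad)), "row counts")
})

test_that("feature matrices round-trip through MatrixMarket plus JSON", {
  sim <- simulateCorpus(nPos = 4, nNeg = 4, vocabSize = 25,
                        docLengthMean = 20, seed = 3)
  fm <- bowMatrix(sim$corpus, buildVocabulary(sim$corpus))
  base <- file.path(withr::local_tempdir(), "feat")
  writeFeatureMatrix(fm, base)
  back <- readFeatureMatrix(base)
  expect_equal(as.matrix(featureValues(back)), as.matrix(featureValues(fm)),
               ignore_attr = TRUE)
  expect_identical(featureNames(back), featureNames(fm))
  expect_identical(docIds(back), docIds(fm))
  expect_identical(penaltyHint(back), penaltyHint(fm))
})
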