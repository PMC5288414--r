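test_that("softmax probabilities are stable, normalised and exact", {
  expect_equal(softmaxProb(rep(3.2, 7), 4), 1 / 7)
  expect_equal(softmaxProb(c(0, log(3)), 2), 0.75)
  withr::with_seed(2, s <- stats::rnorm(10) * 5)
  naive <- exp(s) / sum(exp(s))
  for (i in c(1, 5, 10))
    expect_equal(softmaxProb(s, i), naive[i], tolerance = 1e-12)
  expect_equal(sum(vapply(1:10, function(i) softmaxProb(s, i),
                          numeric(1))), 1, tolerance = 1e-9)
  # max-shift survives scores that overflow the naive formula
  expect_equal(softmaxProb(c(1000, 1000), 1), 0.5)
})

test_that("context representation concatenates blocks with zero padding", {
  corp <- Corpus("d1", list(c("w", "v", "w", "u")))
  model <- trainCBOW(corp, dim = 3, windowC = 2, nEpochs = 1, seed = 1)
  # CBoW width 2c*dim; both neighbours the same word give equal blocks
  h <- contextRepresentation(model, c("w", "v", "w"), 2)
  expect_length(h, 2 * 2 * 3)
  expect_equal(h[4:6], h[7:9])     # offsets -1 and +1 are both "w"
  # position 1 with c = 2: the two left slots are zero pads
  h1 <- contextRepresentation(model, c("w", "v", "w"), 1)
  expect_equal(h1[1:6], rep(0, 6))
  pv <- trainDoc2Vec(corp, dim = 3, windowC = 2, nEpochs = 1, seed = 1)
  expect_length(contextRepresentation(pv, c("w", "v"), 1, docIndex = 1),
                (2 * 2 + 1) * 3)
})

test_that("CBoW learns the deterministic alternation of a toy corpus", {
  corp <- Corpus("d1", list(rep(c("a", "b"), 12)))
  model <- trainCBOW(corp, dim = 4, windowC = 1, lr = 0.1,
                     nEpochs = 60, seed = 3)
  # context (a, a) must predict b over a
  h <- contextRepresentation(model, c("a", "b", "a"), 2)
  scores <- as.numeric(model@wordOut %*% h)
  ia <- match("a", vocabTerms(model)); ib <- match("b", vocabTerms(model))
  expect_gt(softmaxProb(scores, ib), softmaxProb(scores, ia))
  tr <- trainingTrace(model)
  expect_length(tr, 60)
  expect_true(all(is.finite(tr)))
  expect_lte(tr[1], tr[60])
  again <- trainCBOW(corp, dim = 4, windowC = 1, lr = 0.1,
                     nEpochs = 60, seed = 3)
  expect_identical(wordVectors(model), wordVectors(again))
})

test_that("analytic gradients match central finite differences", {
  withr::with_seed(11, {
    docs <- list(c(0L, 1L, 2L, 3L, 1L), c(2L, 4L, 0L, -1L))
    V <- 5L; d <- 3L; c <- 1L
    for (pvdm in c(FALSE, TRUE)) {
      K <- (2L * c + pvdm) * d
      Win <- matrix(stats::rnorm(V * d, sd = 0.4), V)
      P <- matrix(stats::rnorm(2 * d, sd = 0.4), 2)
      Wout <- matrix(stats::rnorm(V * K, sd = 0.4), V)
      obj <- function(a, b, cc)
        asdscreen:::emb_objective(a, b, cc, docs, c, pvdm)
      g <- asdscreen:::emb_gradient(Win, P, Wout, docs, c, pvdm)
      h <- 1e-5
      checkSome <- function(M, G, wrap) {
        idx <- sample(length(M), min(15, length(M)))
        for (i in idx) {
          Mp <- M; Mp[i] <- Mp[i] + h
          Mm <- M; Mm[i] <- Mm[i] - h
          fd <- (wrap(Mp) - wrap(Mm)) / (2 * h)
          expect_lt(abs(fd - G[i]) / max(1e-6, abs(fd)), 1e-4)
        }
      }
      checkSome(Win, g$wordIn, function(M) obj(M, P, Wout))
      if (pvdm) checkSome(P, g$para, function(M) obj(Win, M, Wout))
      checkSome(Wout, g$wordOut, function(M) obj(Win, P, M))
    }
  })
})

test_that("paragraph vectors separate disjoint documents", {
  vocabA <- sprintf("a%02d", 1:8); vocabB <- sprintf("b%02d", 1:8)
  withr::with_seed(7, {
    mk <- function(v) sample(v, 40, replace = TRUE)
    corp <- Corpus(c("d1", "d2", "d3"),
                   list(mk(vocabA), mk(vocabB), mk(vocabA)))
  })
  model <- trainDoc2Vec(corp, dim = 8, windowC = 2, nEpochs = 40,
                        lr = 0.05, seed = 5)
  expect_equal(ncol(paragraphVectors(model)), 8)
  p <- paragraphVectors(model)
  # documents from the same vocabulary are closer than disjoint ones
  expect_gt(cosineSim(p["d1", ], p["d3", ]),
            cosineSim(p["d1", ], p["d2", ]))
  again <- trainDoc2Vec(corp, dim = 8, windowC = 2, nEpochs = 40,
                        lr = 0.05, seed = 5)
  expect_identical(paragraphVectors(model), paragraphVectors(again))
  wide <- trainDoc2Vec(corp, dim = 150, windowC = 2, nEpochs = 1, seed = 1)
  expect_equal(ncol(paragraphVectors(wide)), 150)
})

test_that("inference freezes word matrices and recovers training vectors", {
  sim <- smallDisjointCorpus(nPos = 6, nNeg = 6, seed = 19)
  model <- trainDoc2Vec(sim$corpus, dim = 12, windowC = 2, nEpochs = 40,
                        lr = 0.05, seed = 2)
  wordsBefore <- model@wordIn; outBefore <- model@wordOut
  toks <- docTokens(sim$corpus)
  v <- inferDocVector(model, toks[[1]], nSteps = 60, lr = 0.05)
  expect_gte(cosineSim(v, paragraphVectors(model)[1, ]), 0.8)
  expect_identical(model@wordIn, wordsBefore)
  expect_identical(model@wordOut, outBefore)
  expect_warning(z <- inferDocVector(model, c("zz", "qq")), "zero vector")
  expect_equal(z, numeric(12))
  expect_warning(ze <- inferDocVector(model, character(0)), "zero vector")
  expect_equal(ze, numeric(12))
})

test_that("embedding feature matrices reuse trained vectors and infer new ones", {
  sim <- smallDisjointCorpus(nPos = 5, nNeg = 5, seed = 3)
  train <- sim$corpus[1:8]; test <- sim$corpus[9:10]
  model <- trainDoc2Vec(train, dim = 6, windowC = 2, nEpochs = 20, seed = 4)
  fmTrain <- embeddingFeatureMatrix(model, train)
  expect_equal(unname(as.matrix(featureValues(fmTrain))),
               unname(paragraphVectors(model)))
  fmTest <- embeddingFeatureMatrix(model, test, nSteps = 20)
  expect_equal(dim(featureValues(fmTest)), c(2L, 6L))
  expect_equal(penaltyHint(fmTest), "L2")
})

test_that("embedding models serialise to JSON and back", {
  corp <- Corpus(c("a", "b"), list(c("x", "y", "x"), c("y", "z")))
  model <- trainDoc2Vec(corp, dim = 3, windowC = 1, nEpochs = 5, seed = 8)
  f <- withr::local_tempfile(fileext = ".json")
  writeEmbeddingModel(model, f)
  back <- readEmbeddingModel(f)
  expect_equal(back@wordIn, model@wordIn)
  expect_equal(back@para, model@para)
  expect_equal(back@wordOut, model@wordOut)
  expect_identical(back@mode, model@mode)
})
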