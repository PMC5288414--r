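#' Simulate a scanned medical-form page with known ground truth
#'
#' Builds a white page carrying (top to bottom) a personal-information
#' text band, a fully black horizontal marker line (the separator below
#' which no identifying information appears), and \code{nLines}
#' word-patterned text bands. The page is then rotated by
#' \code{skewDeg} about its centre with the same rotation primitive used
#' by \code{\link{deskewImage}}, and symmetric salt-and-pepper noise
#' flips each pixel independently with probability \code{noiseRate}.
#'
#' @param widthPx,heightPx page dimensions in pixels.
#' @param nLines number of body text lines below the marker.
#' @param lineHeightPx thickness of each text band.
#' @param lineGapPx white gap between consecutive bands.
#' @param skewDeg true rotation applied, |skewDeg| <= 20.
#' @param noiseRate per-pixel flip probability, < 0.05.
#' @param markerRow 1-based row of the separator line.
#' @param seed RNG seed; identical seeds give bit-identical pages.
#' @return list with \code{image} (binary \linkS4class{DocumentImage})
#'   and \code{truth}: \code{skewDeg}, \code{markerRow} and
#'   \code{redactionRegion} (the personal-information band above the
#'   marker, as a \linkS4class{RedactionRegion}).
#' @export
simulateFormImage <- function(widthPx = 360L, heightPx = 480L,
                              nLines = 14L, lineHeightPx = 6L,
                              lineGapPx = 8L, skewDeg = 0,
                              noiseRate = 0.01, markerRow = 60L,
                              seed = 1L) {
  stopifnot(abs(skewDeg) <= 20, noiseRate >= 0, noiseRate < 0.05,
            markerRow >= 1L, markerRow <= heightPx, nLines >= 1L)
  bodyTop <- markerRow + 4L * lineGapPx
  bodyBottom <- bodyTop + nLines * (lineHeightPx + lineGapPx) - lineGapPx
  if (bodyBottom > heightPx - lineGapPx)
    stop("text lines do not fit on the page: reduce nLines or line sizes")
  withr::with_seed(as.integer(seed), {
    px <- matrix(1, heightPx, widthPx)
    colL <- max(1L, round(0.075 * widthPx))
    colR <- min(widthPx, round(0.925 * widthPx))
    # word-patterned band: black runs (words) separated by short gaps
    paintBand <- function(px, rowTop, thick) {
      cols <- integer(0)
      pos <- colL
      while (pos <= colR) {
        wordLen <- sample(8:20, 1)
        gapLen <- sample(4:8, 1)
        cols <- c(cols, seq(pos, min(pos + wordLen - 1L, colR)))
        pos <- pos + wordLen + gapLen
      }
      px[rowTop:(rowTop + thick - 1L), cols] <- 0
      px
    }
    # personal-information band above the marker
    piTop <- max(2L, markerRow - 4L * lineGapPx)
    px <- paintBand(px, piTop, lineHeightPx)
    # marker separator: solid black line, two rows thick
    px[markerRow:min(heightPx, markerRow + 1L), colL:colR] <- 0
    for (i in seq_len(nLines)) {
      top <- bodyTop + (i - 1L) * (lineHeightPx + lineGapPx)
      px <- paintBand(px, top, lineHeightPx)
    }
    px <- rotatePixels(px, skewDeg, "nearest", fill = 1)
    if (noiseRate > 0) {
      flip <- matrix(stats::runif(length(px)) < noiseRate,
                     nrow(px), ncol(px))
      px[flip] <- 1 - px[flip]
    }
    list(image = DocumentImage(px),
         truth = list(
           skewDeg = skewDeg,
           markerRow = as.integer(markerRow),
           redactionRegion = RedactionRegion(1L, as.integer(markerRow),
                                             1L, widthPx + 1L)))
  })
}

#' Construct a Corpus from token lists
#'
#' @param ids unique document identifiers.
#' @param tokens list of character token vectors.
#' @param labels 0/1 integer labels, or NA when unlabelled.
#' @return a \linkS4class{Corpus}.
#' @export
Corpus <- function(ids, tokens, labels = rep(NA_integer_, length(ids))) {
  new("Corpus", ids = as.character(ids), tokens = tokens,
      labels = as.integer(labels))
}

# symmetric per-class topic weights: class 0 tilts toward the first half
# of topics, class 1 toward the second half, with strength `divergence`
classTopicWeights <- function(nTopics, divergence) {
  s <- rep(0, nTopics)
  half <- nTopics %/% 2
  if (half > 0) {
    s[seq_len(half)] <- -1
    s[(nTopics - half + 1L):nTopics] <- 1
  }
  w0 <- exp(-divergence * s); w1 <- exp(divergence * s)
  rbind(`0` = w0 / sum(w0), `1` = w1 / sum(w1))
}

#' Simulate a labelled two-class corpus with known structure
#'
#' Documents are generated from a topic mixture: \code{nTopicsTrue}
#' topic-word distributions with disjoint vocabulary blocks, and a
#' per-document topic proportion drawn from a Dirichlet whose
#' concentration is a symmetric baseline tilted by the document's class.
#' \code{classDivergence = 0} makes both classes draw from the identical
#' symmetric process (documents carry no label signal); large values
#' confine each class to its own topics, giving effectively disjoint
#' class vocabularies. Defaults reproduce the study conditions of 56
#' positive and 143 negative patients (199 documents).
#'
#' @param nPos,nNeg number of positive (label 1) and negative documents.
#' @param vocabSize vocabulary size (>= nTopicsTrue).
#' @param docLengthMean mean document length in tokens (Poisson,
#'   truncated at 1).
#' @param classDivergence non-negative separation between the
#'   class-conditional topic weights; 0 = identical classes.
#' @param nTopicsTrue number of generating topics.
#' @param alpha0 symmetric Dirichlet baseline concentration for
#'   per-document topic proportions.
#' @param seed RNG seed; identical seeds give identical corpora.
#' @return list with \code{corpus} (a \linkS4class{Corpus}; positives
#'   first) and \code{truth}: \code{topicWord} (nTopicsTrue x vocabSize
#'   row-stochastic matrix), \code{classWordDist} (2 x vocabSize
#'   expected word distribution per class, rows "0" and "1"),
#'   \code{classTopicWeights} (2 x nTopicsTrue) and the spec parameters.
#' @export
simulateCorpus <- function(nPos = 56L, nNeg = 143L, vocabSize = 200L,
                           docLengthMean = 120L, classDivergence = 2,
                           nTopicsTrue = 4L, alpha0 = 1, seed = 1L) {
  stopifnot(nPos + nNeg >= 2L, vocabSize >= 10L, classDivergence >= 0,
            nTopicsTrue >= 1L)
  if (vocabSize < nTopicsTrue)
    stop("vocabSize must be at least nTopicsTrue")
  withr::with_seed(as.integer(seed), {
    V <- as.integer(vocabSize); K <- as.integer(nTopicsTrue)
    # purely alphabetic terms (waa, wab, ...) so corpora survive the
    # alphabetic tokenizer; lexicographic order matches index order
    width <- max(2L, ceiling(log(V + 1) / log(26)))
    terms <- vapply(seq_len(V) - 1L, function(i) {
      s <- character(width)
      for (p in width:1) { s[p] <- letters[i %% 26L + 1L]; i <- i %/% 26L }
      paste0("w", paste(s, collapse = ""))
    }, character(1))
    # disjoint vocabulary blocks, one per topic, non-uniform within block
    block <- sort(rep_len(seq_len(K), V))
    topicWord <- matrix(0, K, V, dimnames = list(NULL, terms))
    for (t in seq_len(K)) {
      idx <- which(block == t)
      w <- stats::rgamma(length(idx), shape = 2, rate = 1)
      topicWord[t, idx] <- w / sum(w)
    }
    ctw <- classTopicWeights(K, classDivergence)
    labels <- c(rep(1L, nPos), rep(0L, nNeg))
    n <- length(labels)
    ids <- sprintf("doc%04d", seq_len(n))
    lens <- pmax(1L, stats::rpois(n, docLengthMean))
    tokens <- vector("list", n)
    for (d in seq_len(n)) {
      conc <- alpha0 * K * ctw[as.character(labels[d]), ]
      g <- stats::rgamma(K, shape = conc, rate = 1)
      # guard against all-zero gamma draws at tiny concentrations
      if (sum(g) == 0) g[which.max(conc)] <- 1
      theta <- g / sum(g)
      z <- sample.int(K, lens[d], replace = TRUE, prob = theta)
      toks <- character(lens[d])
      for (t in unique(z)) {
        at <- which(z == t)
        toks[at] <- terms[sample.int(V, length(at), replace = TRUE,
                                     prob = topicWord[t, ])]
      }
      tokens[[d]] <- toks
    }
    classWordDist <- ctw %*% topicWord
    rownames(classWordDist) <- rownames(ctw)
    list(corpus = Corpus(ids, tokens, labels),
         truth = list(topicWord = topicWord,
                      classWordDist = classWordDist,
                      classTopicWeights = ctw,
                      nTopicsTrue = K, vocabSize = V,
                      classDivergence = classDivergence, seed = seed))
  })
}

#' Write and read a corpus as plain text plus a labels CSV
#'
#' One UTF-8 text file per document (tokens separated by spaces) named
#' \code{<doc_id>.txt}, plus \code{labels.csv} with columns
#' \code{doc_id,label}.
#'
#' @param corpus a \linkS4class{Corpus}.
#' @param dir output directory (created if missing).
#' @return \code{writeCorpus} returns \code{dir} invisibly;
#'   \code{readCorpus} returns a \linkS4class{Corpus}. Documents are
#'   re-tokenised on read with \code{\link{tokenizeText}} using
#'   \code{stopwords} (set \code{stopwords = character(0)} to keep all
#'   tokens).
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- docIds(corpus)
  toks <- docTokens(corpus)
  for (i in seq_along(ids)) {
    writeLines(paste(toks[[i]], collapse = " "),
               file.path(dir, paste0(ids[i], ".txt")), useBytes = TRUE)
  }
  utils::write.csv(data.frame(doc_id = ids,
                              label = as.integer(docLabels(corpus))),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCorpus
#' @param stopwords stop-word list applied when re-tokenising.
#' @export
readCorpus <- function(dir, stopwords = character(0)) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"),
                         colClasses = c("character", "integer"))
  tokens <- lapply(lab$doc_id, function(id) {
    txt <- readLines(file.path(dir, paste0(id, ".txt")), warn = FALSE)
    tokenizeText(paste(txt, collapse = " "), stopwords = stopwords)
  })
  Corpus(lab$doc_id, tokens, lab$label)
}
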