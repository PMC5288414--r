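#' Read a pipeline run configuration
#'
#' Configurations are YAML or JSON and round-trip losslessly through
#' \code{yaml::write_yaml}. Recognised top-level fields: \code{seed}
#' (global seed, fanned out to per-stage seeds by fixed offsets),
#' \code{out_dir}, and the stage blocks \code{simulate},
#' \code{preprocess}, \code{featurize}, \code{evaluate}; a stage runs
#' iff its block is present.
#'
#' @param path YAML (.yml/.yaml) or JSON (.json) file.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: ", ext))
  validateRunConfig(cfg)
  cfg
}

validateRunConfig <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config requires a global seed")
  if (is.null(config$out_dir)) stop("config requires out_dir")
  known <- c("seed", "out_dir", "simulate", "preprocess", "featurize",
             "evaluate")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  if (!is.null(config$featurize)) {
    m <- config$featurize$method %||% "bow"
    if (!m %in% c("bow", "tfidf", "ngram", "lexical", "lda", "doc2vec"))
      stop("featurize.method must be one of bow/tfidf/ngram/lexical/lda/doc2vec")
  }
  invisible(TRUE)
}

stageSeed <- function(seed, stage) {
  as.integer(seed) + c(simulate = 11L, preprocess = 23L,
                       featurize = 37L, evaluate = 53L)[[stage]]
}

logStage <- function(stage, seed, t0) {
  message(sprintf("[%s] stage=%s seed=%d elapsed=%.2fs",
                  format(Sys.time(), "%H:%M:%S"), stage, seed,
                  as.numeric(Sys.time()) - t0))
}

featurizeCorpus <- function(corpus, method, params, seed) {
  params <- params %||% list()
  switch(method,
    bow = ,
    tfidf = ,
    ngram = ,
    lexical = lexicalFeaturizer(method)(corpus, corpus[integer(0)],
                                        seed)$train,
    lda = {
      model <- fitLDA(corpus,
                      nTopicsFit = params$topics %||% 200L,
                      nIterations = params$iters %||% 500L,
                      seed = seed)
      topicFeatureMatrix(model, corpus)
    },
    doc2vec = {
      model <- trainDoc2Vec(corpus, dim = params$dim %||% 150L,
                            windowC = params$window %||% 5L,
                            nEpochs = params$epochs %||% 50L,
                            seed = seed)
      embeddingFeatureMatrix(model, corpus)
    })
}

#' Run the screening pipeline from a configuration
#'
#' Executes the enabled stages in order: \code{simulate} (synthetic
#' form images, corpus and ground truth), \code{preprocess} (binarize,
#' de-skew and de-identify every image of a directory), \code{featurize}
#' (one or more feature matrices from the corpus; \code{lda} and
#' \code{doc2vec} accept a vector of dimensions to sweep) and
#' \code{evaluate} (nested cross-validation). A manifest recording the
#' configuration, per-stage seeds, package version and the MD5 of every
#' artifact is written last; re-running the same configuration
#' reproduces identical artifacts.
#'
#' @param config list (see \code{\link{readRunConfig}}) or path to a
#'   config file.
#' @return the run directory path, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  validateRunConfig(config)
  t0 <- as.numeric(Sys.time())
  outDir <- config$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  note <- function(...) artifacts <<- c(artifacts, file.path(outDir, ...))

  if (!is.null(config$simulate)) {
    s <- config$simulate
    seed <- stageSeed(config$seed, "simulate")
    imgDir <- file.path(outDir, "images")
    dir.create(imgDir, showWarnings = FALSE)
    nImages <- s$n_images %||% 0L
    truths <- list()
    for (i in seq_len(nImages)) {
      withr::with_seed(seed + i, {
        ang <- stats::runif(1, -(s$max_skew %||% 15), s$max_skew %||% 15)
      })
      sim <- simulateFormImage(skewDeg = ang,
                               noiseRate = s$noise_rate %||% 0.01,
                               seed = seed + i)
      f <- sprintf("form%03d.png", i)
      writeFormImage(sim$image, file.path(imgDir, f))
      truths[[f]] <- list(skewDeg = sim$truth$skewDeg,
                          markerRow = sim$truth$markerRow)
      note("images", f)
    }
    if (nImages > 0) {
      jsonlite::write_json(truths, file.path(imgDir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      note("images", "ground_truth.json")
    }
    if (!is.null(s$corpus)) {
      cs <- s$corpus
      sim <- simulateCorpus(nPos = cs$n_pos %||% 56L,
                            nNeg = cs$n_neg %||% 143L,
                            vocabSize = cs$vocab_size %||% 200L,
                            docLengthMean = cs$doc_length_mean %||% 120L,
                            classDivergence = cs$class_divergence %||% 2,
                            nTopicsTrue = cs$n_topics_true %||% 4L,
                            seed = seed)
      writeCorpus(sim$corpus, file.path(outDir, "corpus"))
      jsonlite::write_json(
        list(classTopicWeights = sim$truth$classTopicWeights,
             topicWord = sim$truth$topicWord),
        file.path(outDir, "corpus", "ground_truth.json"), digits = NA)
      note("corpus", "labels.csv")
      note("corpus", "ground_truth.json")
    }
    logStage("simulate", seed, t0)
  }

  if (!is.null(config$preprocess)) {
    p <- config$preprocess
    seed <- stageSeed(config$seed, "preprocess")
    inDir <- p$in_dir %||% file.path(outDir, "images")
    if (!dir.exists(inDir))
      stop("preprocess: missing upstream artifact directory ", inDir)
    cleanDir <- file.path(outDir, "preprocessed")
    dir.create(cleanDir, showWarnings = FALSE)
    masks <- if (!is.null(p$mask_file))
      jsonlite::read_json(p$mask_file, simplifyVector = TRUE) else list()
    results <- list()
    for (f in list.files(inDir, pattern = "\\.(png|tif|tiff)$")) {
      img <- readFormImage(file.path(inDir, f))
      thr <- p$threshold %||% "otsu"
      bin <- binarizeImage(img, if (identical(thr, "otsu")) NULL else thr)
      est <- estimateSkew(bin, rangeDeg = p$range %||% 20,
                          stepDeg = p$step %||% 0.1)
      fixed <- deskewImage(bin, est@angleDeg)
      if (!is.null(masks[[f]])) {
        for (r in masks[[f]])
          fixed <- blankRegion(fixed, RedactionRegion(r[1], r[2], r[3], r[4]))
        marker <- NA_integer_
      } else {
        de <- deidentifyForm(fixed)
        fixed <- de$image
        marker <- de$markerRow
      }
      writeFormImage(fixed, file.path(cleanDir, f))
      results[[f]] <- list(angle = est@angleDeg, entropy = est@entropy,
                           markerRow = marker)
      note("preprocessed", f)
    }
    jsonlite::write_json(results, file.path(cleanDir, "preprocess.json"),
                         auto_unbox = TRUE, digits = NA)
    note("preprocessed", "preprocess.json")
    logStage("preprocess", seed, t0)
  }

  if (!is.null(config$featurize)) {
    fz <- config$featurize
    seed <- stageSeed(config$seed, "featurize")
    corpusDir <- fz$corpus_dir %||% file.path(outDir, "corpus")
    if (!dir.exists(corpusDir))
      stop("featurize: missing upstream corpus at ", corpusDir)
    corpus <- readCorpus(corpusDir)
    method <- fz$method %||% "bow"
    dims <- fz$dims %||% fz$topics %||% NA
    if (method %in% c("lda", "doc2vec") && !all(is.na(dims))) {
      for (d in dims) {
        prm <- if (method == "lda") list(topics = d, iters = fz$iters %||% 500L)
               else list(dim = d, window = fz$window %||% 5L,
                         epochs = fz$epochs %||% 50L)
        fm <- featurizeCorpus(corpus, method, prm, seed)
        writeFeatureMatrix(fm, file.path(outDir,
                                         sprintf("features_%s_%d", method, d)))
        note(sprintf("features_%s_%d.mtx", method, d))
        note(sprintf("features_%s_%d.json", method, d))
      }
    } else {
      fm <- featurizeCorpus(corpus, method, fz, seed)
      writeFeatureMatrix(fm, file.path(outDir, paste0("features_", method)))
      note(paste0("features_", method, ".mtx"))
      note(paste0("features_", method, ".json"))
    }
    logStage("featurize", seed, t0)
  }

  if (!is.null(config$evaluate)) {
    ev <- config$evaluate
    seed <- stageSeed(config$seed, "evaluate")
    fmPath <- ev$features %||% file.path(outDir, "features_bow")
    if (!file.exists(paste0(fmPath, ".mtx")))
      stop("evaluate: missing upstream feature matrix ", fmPath)
    fm <- readFeatureMatrix(fmPath)
    labPath <- ev$labels %||% file.path(outDir, "corpus", "labels.csv")
    lab <- utils::read.csv(labPath, colClasses = c("character", "integer"))
    y <- lab$label[match(docIds(fm), lab$doc_id)]
    up <- if (isFALSE(ev$upsample) || identical(ev$upsample, 0L)) NULL
          else list(nPerPositive = ev$upsample %||% 2L,
                    k = ev$upsample_k %||% ev$upsample %||% 2L)
    report <- nestedCV(fm, y, outerK = ev$outer %||% 7L,
                       innerK = ev$inner %||% 5L,
                       upsample = up, seed = seed)
    writeEvalReport(report, file.path(outDir, "eval"))
    note("eval.json"); note("eval_folds.csv")
    logStage("evaluate", seed, t0)
  }

  manifest <- list(
    config = config,
    package = as.character(utils::packageVersion("asdscreen")),
    rVersion = R.version.string,
    stageSeeds = lapply(stats::setNames(nm = intersect(
      c("simulate", "preprocess", "featurize", "evaluate"),
      names(config))), function(s) stageSeed(config$seed, s)),
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(artifacts[file.exists(artifacts)])),
      sub(paste0("^", outDir, "/?"), "", artifacts[file.exists(artifacts)]))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outDir)
}
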