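#' Squared-hinge SVM objective
#'
#' L1 form: \code{||w||_1 + C * sum(max(0, 1 - y * Xw)^2)}; L2 form:
#' \code{0.5 * w'w + C * sum(max(0, 1 - y * Xw)^2)}. Labels must be in
#' \{-1, +1\}.
#'
#' @param w weight vector (including any bias feature the caller
#'   appended).
#' @param X n-by-d matrix.
#' @param y labels in \{-1, +1\}.
#' @param C positive regularisation trade-off.
#' @param penalty "L1" or "L2".
#' @return scalar objective value.
#' @export
svmObjective <- function(w, X, y, C, penalty = c("L1", "L2")) {
  penalty <- match.arg(penalty)
  if (!all(y %in% c(-1, 1))) stop("labels must be in {-1, +1}")
  stopifnot(C > 0, ncol(X) == length(w), nrow(X) == length(y))
  margin <- pmax(0, 1 - y * as.numeric(X %*% w))
  loss <- C * sum(margin^2)
  pen <- if (penalty == "L1") sum(abs(w)) else 0.5 * sum(w^2)
  pen + loss
}

addBias <- function(X) {
  if (is(X, "Matrix")) Matrix::cbind2(X, 1) else cbind(X, 1)
}

# gradient of the smooth part C * sum(max(0, 1 - y Xw)^2)
hingeGrad <- function(w, X, y, C) {
  h <- pmax(0, 1 - y * as.numeric(X %*% w))
  as.numeric(-2 * C * Matrix::crossprod(X, y * h))
}

softThreshold <- function(z, t) sign(z) * pmax(0, abs(z) - t)

#' Train a squared-hinge linear SVM
#'
#' Proximal gradient descent on the squared-hinge loss with an L1
#' (soft-thresholding) or L2 proximal step, with backtracking line
#' search, so the objective is non-increasing across iterations. A bias
#' is handled by appending a constant-one feature, regularised together
#' with the weights.
#'
#' @param X n-by-d matrix (or Matrix) of features, without bias column.
#' @param y labels in \{0, 1\}; both classes must be present.
#' @param penalty "L1" or "L2".
#' @param C positive regularisation trade-off.
#' @param tol relative objective-change stopping tolerance.
#' @param maxIter iteration cap.
#' @param featureNames optional column names for reporting.
#' @return a \linkS4class{LinearSVM}.
#' @export
trainLinearSVM <- function(X, y, penalty = c("L1", "L2"), C = 1,
                           tol = 1e-9, maxIter = 5000L,
                           featureNames = NULL) {
  penalty <- match.arg(penalty)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (is.null(featureNames)) {
    featureNames <- colnames(X)
    if (is.null(featureNames)) featureNames <- sprintf("f%04d", seq_len(ncol(X)))
  }
  Xb <- addBias(X)
  ys <- ifelse(y == 1L, 1, -1)
  d <- ncol(Xb)
  w <- numeric(d)
  obj <- svmObjective(w, Xb, ys, C, penalty)
  step <- 1 / max(1, 2 * C * sum(Xb^2) / nrow(Xb))
  prox <- function(z, s) {
    if (penalty == "L1") softThreshold(z, s) else z / (1 + s)
  }
  for (it in seq_len(maxIter)) {
    g <- hingeGrad(w, Xb, ys, C)
    repeat {
      wNew <- prox(w - step * g, step)
      objNew <- svmObjective(wNew, Xb, ys, C, penalty)
      if (objNew <= obj + 1e-12) break
      step <- step / 2
      if (step < 1e-18) { wNew <- w; objNew <- obj; break }
    }
    dObj <- obj - objNew
    w <- wNew; obj <- objNew
    step <- step * 1.2
    if (dObj <= tol * max(1, abs(obj))) break
  }
  new("LinearSVM", weights = as.numeric(w), penalty = penalty,
      cost = C, featureNames = featureNames, objective = obj)
}

#' Predict 0/1 labels from a linear model
#'
#' Label 1 iff \code{w'x >= 0}: the tie at exactly zero goes to the
#' positive class, favouring recall.
#'
#' @param object a \linkS4class{LinearSVM}.
#' @param newdata n-by-d matrix matching the training features (without
#'   bias column).
#' @param ... unused.
#' @return integer vector of 0/1 labels.
#' @export
setMethod("predict", "LinearSVM", function(object, newdata, ...) {
  if (ncol(newdata) != length(object@weights) - 1L)
    stop("feature dimension mismatch")
  scores <- as.numeric(addBias(newdata) %*% object@weights)
  as.integer(scores >= 0)
})

#' F2 score from precision and recall
#'
#' \code{F2 = 5 * P * R / (4 * P + R)}, the recall-weighted F-measure;
#' defined as 0 when the denominator vanishes.
#'
#' @param precision,recall scalars in \[0, 1\].
#' @return scalar F2 in \[0, 1\].
#' @export
f2Score <- function(precision, recall) {
  den <- 4 * precision + recall
  ifelse(den == 0, 0, 5 * precision * recall / den)
}

#' Classification metrics from 0/1 labels
#'
#' @param yTrue,yPred equal-length 0/1 vectors.
#' @return named list: confusion counts TP/FP/TN/FN, accuracy,
#'   precision (0 when no positive prediction), recall, F2.
#' @export
computeMetrics <- function(yTrue, yPred) {
  stopifnot(length(yTrue) == length(yPred), length(yTrue) > 0,
            all(yTrue %in% c(0, 1)), all(yPred %in% c(0, 1)))
  TP <- sum(yTrue == 1 & yPred == 1)
  FP <- sum(yTrue == 0 & yPred == 1)
  TN <- sum(yTrue == 0 & yPred == 0)
  FN <- sum(yTrue == 1 & yPred == 0)
  precision <- if (TP + FP == 0) 0 else TP / (TP + FP)
  recall <- if (TP + FN == 0) 0 else TP / (TP + FN)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       accuracy = (TP + TN) / length(yTrue),
       precision = precision, recall = recall,
       f2 = f2Score(precision, recall))
}

#' Top-weight feature report
#'
#' The k features with the largest absolute weights of a fitted linear
#' model, split by sign (positive weights push toward the positive
#' class). Zero weights are dropped; ties in magnitude resolve by
#' feature name.
#'
#' @param model a \linkS4class{LinearSVM}.
#' @param k number of features to report (all non-zero ones if fewer).
#' @return data.frame with columns \code{feature}, \code{weight},
#'   \code{signClass} ("positive"/"negative"), sorted by |weight|
#'   descending.
#' @export
topFeatures <- function(model, k = 10L) {
  w <- model@weights[seq_along(model@featureNames)]
  nz <- which(w != 0)
  if (!length(nz))
    return(data.frame(feature = character(0), weight = numeric(0),
                      signClass = character(0)))
  o <- nz[order(-abs(w[nz]), model@featureNames[nz])]
  o <- o[seq_len(min(k, length(o)))]
  data.frame(feature = model@featureNames[o], weight = w[o],
             signClass = ifelse(w[o] > 0, "positive", "negative"))
}

#' Serialize a LinearSVM as JSON weights
#'
#' @param model a \linkS4class{LinearSVM}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeLinearSVM <- function(model, path) {
  jsonlite::write_json(
    list(weights = model@weights, penalty = model@penalty, C = model@cost,
         featureNames = model@featureNames, objective = model@objective),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
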