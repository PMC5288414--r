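#' Pairwise Euclidean distances among positive samples
#'
#' @param Xpos m-by-d numeric matrix, m >= 2.
#' @return symmetric m-by-m matrix with zero diagonal.
#' @export
pairwiseEuclidean <- function(Xpos) {
  Xpos <- as.matrix(Xpos)
  if (nrow(Xpos) < 2L) stop("need at least 2 positive samples")
  d <- as.matrix(stats::dist(Xpos, method = "euclidean"))
  dimnames(d) <- NULL
  d
}

#' Indices of the k nearest positive neighbours
#'
#' For each positive row, the indices of its k smallest-distance
#' positive rows, self excluded; distance ties resolve toward the
#' smaller index.
#'
#' @param Xpos m-by-d numeric matrix of positive samples.
#' @param k number of neighbours, k < m.
#' @return m-by-k integer matrix of row indices.
#' @export
nearestPositiveNeighbors <- function(Xpos, k) {
  Xpos <- as.matrix(Xpos)
  m <- nrow(Xpos)
  if (k >= m) stop("k must be smaller than the number of positives")
  D <- pairwiseEuclidean(Xpos)
  out <- matrix(0L, m, k)
  for (i in seq_len(m)) {
    cand <- setdiff(seq_len(m), i)
    o <- cand[order(D[i, cand], cand)]
    out[i, ] <- o[seq_len(k)]
  }
  out
}

#' Interpolate between a sample and a neighbour
#'
#' Returns \code{x + u * (neighbor - x)}, a point on the closed segment
#' between the two samples.
#'
#' @param x,neighbor d-vectors.
#' @param u interpolation fraction in \[0, 1\].
#' @return d-vector.
#' @export
synthesizeBetween <- function(x, neighbor, u) {
  stopifnot(u >= 0, u <= 1, length(x) == length(neighbor))
  x + u * (neighbor - x)
}

#' LabeledMatrix constructor
#'
#' @param X n-by-d matrix.
#' @param y 0/1 labels.
#' @param provenance per-row "real"/"artificial" flags.
#' @return a \linkS4class{LabeledMatrix}.
#' @export
LabeledMatrix <- function(X, y, provenance = rep("real", length(y))) {
  new("LabeledMatrix", X = X, y = as.integer(y), provenance = provenance)
}

#' Upsample the positive class by segment interpolation
#'
#' For every real positive sample, \code{nPerPositive} artificial
#' positives are appended, each drawn on the segment between the sample
#' and one of its \code{k} nearest positive neighbours at an
#' independent Uniform(0, 1) fraction (neighbours are cycled through in
#' nearest-first order). Real rows, and in particular all negatives,
#' are untouched bit-exactly; the operation is deterministic given
#' \code{seed}.
#'
#' @param data a \linkS4class{LabeledMatrix} with at least 2 positives.
#' @param nPerPositive artificial samples generated per real positive
#'   (the study setting is 2).
#' @param k neighbour pool size; defaults to \code{nPerPositive}.
#' @param seed RNG seed.
#' @return the augmented \linkS4class{LabeledMatrix}; artificial rows
#'   carry provenance "artificial" and label 1.
#' @export
upsamplePositives <- function(data, nPerPositive = 2L, k = nPerPositive,
                              seed = 1L) {
  stopifnot(is(data, "LabeledMatrix"), nPerPositive >= 1L, k >= 1L)
  X <- as.matrix(data@X)
  posIdx <- which(data@y == 1L & data@provenance == "real")
  if (length(posIdx) < 2L) stop("need at least 2 real positive samples")
  k <- min(k, length(posIdx) - 1L)
  Xpos <- X[posIdx, , drop = FALSE]
  nbr <- nearestPositiveNeighbors(Xpos, k)
  m <- length(posIdx)
  withr::with_seed(as.integer(seed), {
    art <- matrix(0, m * nPerPositive, ncol(X))
    r <- 0L
    for (i in seq_len(m)) {
      for (j in seq_len(nPerPositive)) {
        r <- r + 1L
        u <- stats::runif(1)
        nb <- nbr[i, ((j - 1L) %% k) + 1L]
        art[r, ] <- synthesizeBetween(Xpos[i, ], Xpos[nb, ], u)
      }
    }
    new("LabeledMatrix", X = rbind(X, art),
        y = c(data@y, rep(1L, nrow(art))),
        provenance = c(data@provenance, rep("artificial", nrow(art))))
  })
}
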