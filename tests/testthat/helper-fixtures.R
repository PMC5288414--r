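# shared fixtures and independent oracles

cosineSim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# brute-force Sobel oracle: double loop, replicated borders, kernel
# entries visited in row-major order
naiveSobel <- function(px) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  ky <- matrix(c(1, 0, -1, 2, 0, -2, 1, 0, -1), 3, 3)
  h <- nrow(px); w <- ncol(px)
  clampAt <- function(i, n) min(max(i, 1L), n)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    gx <- 0; gy <- 0
    for (di in -1:1) for (dj in -1:1) {
      v <- px[clampAt(i + di, h), clampAt(j + dj, w)]
      gx <- gx + kx[di + 2, dj + 2] * v
      gy <- gy + ky[di + 2, dj + 2] * v
    }
    out[i, j] <- sqrt(gx^2 + gy^2)
  }
  out
}

# tiny deterministic two-class corpus with disjoint class vocabularies
smallDisjointCorpus <- function(nPos = 12, nNeg = 24, seed = 42) {
  simulateCorpus(nPos = nPos, nNeg = nNeg, vocabSize = 40,
                 docLengthMean = 40, classDivergence = 8,
                 nTopicsTrue = 2, seed = seed)
}

# toy labelled point cloud for classifier tests
separableCloud <- function(n = 30, d = 2, gap = 3, seed = 7) {
  withr::with_seed(seed, {
    X <- rbind(matrix(stats::rnorm(n * d / 2, mean = gap), n / 2, d),
               matrix(stats::rnorm(n * d / 2, mean = -gap), n / 2, d))
    list(X = X, y = rep(c(1L, 0L), each = n / 2))
  })
}

# Nelder-Mead reference optimum for the squared-hinge objective
referenceSVMObjective <- function(X, y01, C, penalty, nRestarts = 2) {
  Xb <- cbind(X, 1)
  ys <- ifelse(y01 == 1, 1, -1)
  obj <- function(w) svmObjective(w, Xb, ys, C, penalty)
  best <- Inf
  par <- rep(0, ncol(Xb))
  for (r in seq_len(nRestarts + 1)) {
    fit <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = 20000, reltol = 1e-14))
    if (fit$value < best) best <- fit$value
    par <- fit$par
  }
  best
}
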