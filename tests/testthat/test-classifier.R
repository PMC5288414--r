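test_that("the squared-hinge objective evaluates both penalties exactly", {
  # w = 0: every margin is 1, so the objective is C * l
  X <- matrix(stats::rnorm(12), 6, 2)
  y <- c(1, -1, 1, -1, 1, -1)
  expect_equal(svmObjective(c(0, 0), X, y, 2, "L1"), 12)
  expect_equal(svmObjective(c(0, 0), X, y, 2, "L2"), 12)
  # 1-D worked case: margin 2 > 1, loss 0
  expect_equal(svmObjective(2, matrix(1), 1, 1, "L2"), 2)
  expect_equal(svmObjective(2, matrix(1), 1, 1, "L1"), 2)
  # random instance vs term-by-term recompute
  withr::with_seed(21, {
    Xr <- matrix(stats::rnorm(15), 5, 3)
    yr <- sample(c(-1, 1), 5, replace = TRUE)
    w <- stats::rnorm(3)
  })
  byHand <- 0
  for (i in 1:5)
    byHand <- byHand + 1.5 * max(0, 1 - yr[i] * sum(w * Xr[i, ]))^2
  expect_equal(svmObjective(w, Xr, yr, 1.5, "L1"), sum(abs(w)) + byHand,
               tolerance = 1e-12)
  expect_equal(svmObjective(w, Xr, yr, 1.5, "L2"),
               0.5 * sum(w^2) + byHand, tolerance = 1e-12)
  expect_error(svmObjective(w, Xr, c(0, 1, 1, 0, 1), 1, "L1"), "-1")
})

test_that("training separates separable data and improves on zero weights", {
  cloud <- separableCloud(n = 40, seed = 17)
  for (pen in c("L1", "L2")) {
    fit <- trainLinearSVM(cloud$X, cloud$y, pen, C = 10)
    expect_equal(mean(predict(fit, cloud$X) == cloud$y), 1)
    Xb <- cbind(cloud$X, 1)
    ys <- ifelse(cloud$y == 1, 1, -1)
    expect_lte(fit@objective, svmObjective(numeric(3), Xb, ys, 10, pen))
  }
  expect_error(trainLinearSVM(cloud$X, rep(1L, 40), "L2"), "both classes")
})

test_that("L1 regularisation zeroes noise features", {
  withr::with_seed(25, {
    n <- 60
    informative <- c(stats::rnorm(n / 2, 2), stats::rnorm(n / 2, -2))
    noise <- matrix(stats::rnorm(n * 6, sd = 0.3), n, 6)
    X <- cbind(informative, noise)
    y <- rep(c(1L, 0L), each = n / 2)
  })
  fit <- trainLinearSVM(X, y, "L1", C = 0.1)
  w <- modelWeights(fit)
  expect_true(abs(w[1]) > 0)
  expect_true(all(w[2:7] == 0))
  # the reference optimiser agrees this is (near) optimal
  ref <- referenceSVMObjective(X, y, 0.1, "L1")
  expect_lte(fit@objective, ref * (1 + 1e-3))
})

test_that("solver reaches the reference optimum on small instances", {
  withr::with_seed(29, {
    for (pen in c("L1", "L2")) {
      for (r in 1:5) {
        n <- sample(10:30, 1); d <- sample(2:4, 1)
        X <- matrix(stats::rnorm(n * d), n, d)
        y <- rbinom(n, 1, 0.5)
        if (length(unique(y)) < 2) y[1] <- 1L - y[1]
        C <- sample(c(0.1, 1, 10), 1)
        fit <- trainLinearSVM(X, y, pen, C)
        ref <- referenceSVMObjective(X, y, C, pen)
        expect_lte(fit@objective, ref * (1 + 1e-3))
      }
    }
  })
})

test_that("prediction uses the recall-favouring tie rule", {
  model <- new("LinearSVM", weights = c(1, 0, 0), penalty = "L2",
               cost = 1, featureNames = c("f1", "f2"), objective = 0)
  # w'x = 0 predicts positive; e1 weight vector reads feature 1
  expect_equal(predict(model, rbind(c(0, 5))), 1L)
  expect_equal(predict(model, rbind(c(-3, 2))), 0L)
  withr::with_seed(31, {
    Xr <- matrix(stats::rnorm(20), 10, 2)
    w <- c(stats::rnorm(2), 0.2)
  })
  m2 <- new("LinearSVM", weights = w, penalty = "L2", cost = 1,
            featureNames = c("a", "b"), objective = 0)
  expect_equal(predict(m2, Xr),
               as.integer(as.numeric(cbind(Xr, 1) %*% w) >= 0))
  expect_error(predict(m2, matrix(0, 2, 5)), "mismatch")
})

test_that("metrics reproduce the published F2 arithmetic", {
  expect_equal(round(f2Score(0.646, 0.911), 3), 0.842)
  expect_equal(round(f2Score(0.472, 0.644), 3), 0.600)
  for (p in c(0.2, 0.5, 0.9)) expect_equal(f2Score(p, p), p)
  expect_equal(f2Score(0, 0), 0)
  # F2 lies between min and max of precision and recall; equals R at P=R
  withr::with_seed(35, {
    for (r in 1:20) {
      P <- stats::runif(1); R <- stats::runif(1)
      f2 <- f2Score(P, R)
      expect_gte(f2, min(P, R) - 1e-12)
      expect_lte(f2, max(P, R) + 1e-12)
    }
  })
  m <- computeMetrics(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
  expect_equal(m$TP, 2); expect_equal(m$FP, 1)
  expect_equal(m$TN, 1); expect_equal(m$FN, 1)
  expect_equal(m$accuracy, 3 / 5)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f2, 2 / 3)
  none <- computeMetrics(c(1, 0), c(0, 0))
  expect_equal(none$precision, 0)
  expect_equal(none$f2, 0)
})

test_that("top-feature report ranks by absolute weight with sign classes", {
  model <- new("LinearSVM", weights = c(3, -5, 1, 0.5), penalty = "L1",
               cost = 1, featureNames = c("fa", "fb", "fc"),
               objective = 0)
  top2 <- topFeatures(model, 2)
  expect_equal(top2$feature, c("fb", "fa"))
  expect_equal(top2$signClass, c("negative", "positive"))
  zero <- new("LinearSVM", weights = c(0, 0, 0), penalty = "L1",
              cost = 1, featureNames = c("fa", "fb"), objective = 0)
  expect_equal(nrow(topFeatures(zero)), 0)
  withr::with_seed(41, w <- stats::rnorm(12))
  m <- new("LinearSVM", weights = c(w, 0.1), penalty = "L1", cost = 1,
           featureNames = sprintf("f%02d", 1:12), objective = 0)
  all12 <- topFeatures(m, 50)       # k > d returns all non-zero
  expect_equal(nrow(all12), 12)
  expect_equal(all12$feature,
               sprintf("f%02d", order(-abs(w), sprintf("f%02d", 1:12))))
})
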