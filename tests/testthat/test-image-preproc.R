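test_that("binarization thresholds pixels exactly and handles edge cases", {
  white <- DocumentImage(matrix(1, 4, 4))
  expect_equal(pixels(binarizeImage(white, 0.5)), matrix(1, 4, 4))
  img <- DocumentImage(matrix(c(0.2, 0.8), 2, 2))
  expect_equal(sort(unique(as.numeric(pixels(binarizeImage(img, 0.5))))),
               c(0, 1))
  withr::with_seed(1, px <- matrix(stats::runif(30 * 20), 30))
  bin <- binarizeImage(DocumentImage(px), 0.37)
  expect_equal(sum(pixels(bin) == 0), sum(px < 0.37))
  expect_error(DocumentImage(matrix(numeric(0), 0, 0)), "at least one")
})

test_that("row profile counts black fractions on the rotated raster", {
  white <- DocumentImage(matrix(1, 10, 8))
  expect_equal(rowProfile(white, 0), rep(0, 10))
  px <- matrix(1, 10, 8); px[4, ] <- 0
  oneRow <- rowProfile(DocumentImage(px), 0)
  expect_equal(oneRow[4], 1)
  expect_equal(sum(oneRow), 1)
  # three constructed bands: profile equals a brute-force row count
  px <- matrix(1, 30, 20)
  px[c(5:6, 15:16, 25:26), 3:18] <- 0
  img <- DocumentImage(px)
  expect_equal(rowProfile(img, 0), rowSums(px == 0) / 20)
})

test_that("skew entropy applies the 10% filter and the P log P form", {
  expect_equal(skewEntropy(1.0), 0)
  expect_equal(skewEntropy(0.05), 0)
  expect_equal(skewEntropy(0.5), -0.5 * log(0.5))
  expect_equal(skewEntropy(0.5), 0.34657, tolerance = 1e-4)
  expect_equal(skewEntropy(c(0.05, 0.09, 0.0)), 0)
  expect_equal(skewEntropy(c(0.5, 0.05, 1.0)), -0.5 * log(0.5))
  expect_gte(skewEntropy(runif(50)), 0)
})

test_that("skew estimation recovers the corrective angle on synthetic forms", {
  flat <- simulateFormImage(skewDeg = 0, noiseRate = 0, seed = 4)
  est0 <- estimateSkew(flat$image, rangeDeg = 5, stepDeg = 0.2)
  expect_lte(abs(est0@angleDeg), 0.2)
  rot <- simulateFormImage(skewDeg = 3, noiseRate = 0.01, seed = 4)
  est <- estimateSkew(rot$image, rangeDeg = 10, stepDeg = 0.2)
  expect_lt(abs(est@angleDeg + 3), 2 * 0.2 + 1e-9)
  # fixed point: de-skewing by the estimate leaves ~zero residual skew
  fixed <- deskewImage(rot$image, est@angleDeg)
  re <- estimateSkew(fixed, rangeDeg = 10, stepDeg = 0.2)
  expect_lte(abs(re@angleDeg), 2 * 0.2 + 1e-9)
  # and the entropy does not increase
  expect_lte(skewEntropy(rowProfile(fixed, 0)),
             skewEntropy(rowProfile(rot$image, 0)))
})

test_that("blank page skew estimate warns and returns zero", {
  blank <- DocumentImage(matrix(1, 40, 30))
  expect_warning(est <- estimateSkew(blank), "blank")
  expect_equal(est@angleDeg, 0)
  expect_equal(est@entropy, 0)
})

test_that("deskew rotates about the centre, keeps dims and binariness", {
  sim <- simulateFormImage(skewDeg = 0, noiseRate = 0, seed = 8)
  expect_identical(pixels(deskewImage(sim$image, 0)), pixels(sim$image))
  there <- deskewImage(sim$image, 7)
  back <- deskewImage(there, -7)
  expect_identical(dim(there), dim(sim$image))
  expect_true(all(pixels(there) %in% c(0, 1)))
  # double resampling leaves only a thin band of disagreement
  expect_lt(mean(pixels(back) != pixels(sim$image)), 0.02)
})

test_that("Sobel magnitude matches the brute-force convolution oracle", {
  flat <- DocumentImage(matrix(0.6, 5, 7))
  expect_equal(sobelEdges(flat), matrix(0, 5, 7))
  # vertical step a -> b: horizontal kernel responds 4|b - a| at the
  # step columns
  a <- 0.2; b <- 0.9
  px <- cbind(matrix(a, 6, 3), matrix(b, 6, 3))
  e <- sobelEdges(DocumentImage(px))
  expect_equal(e[3, 3], 4 * abs(b - a))
  expect_equal(e[3, 4], 4 * abs(b - a))
  expect_equal(e[3, 2], 0)
  withr::with_seed(5, px <- matrix(stats::runif(12 * 9), 12))
  expect_equal(sobelEdges(DocumentImage(px)), naiveSobel(px),
               tolerance = 1e-12)
  expect_error(sobelEdges(DocumentImage(matrix(0.5, 2, 2))), "3 x 3")
})

test_that("marker line is found at the ground-truth row", {
  sim <- simulateFormImage(skewDeg = 0, noiseRate = 0.005, seed = 12)
  row <- locateMarkerLine(sobelEdges(sim$image))
  expect_lte(abs(row - sim$truth$markerRow), 6)
  white <- DocumentImage(matrix(1, 40, 30))
  expect_warning(nf <- locateMarkerLine(sobelEdges(white)), "not found")
  expect_true(is.na(nf))
  # equal-energy tie resolves to the smaller row
  edges <- matrix(0, 10, 5); edges[c(3, 7), ] <- 2
  expect_equal(locateMarkerLine(edges, searchFraction = 1), 3)
})

test_that("blankRegion paints the half-open region black and nothing else", {
  white <- DocumentImage(matrix(1, 10, 8))
  reg <- RedactionRegion(2, 5, 3, 7)
  red <- blankRegion(white, reg)
  expect_equal(sum(pixels(red) == 0), 3 * 4)
  expect_equal(pixels(red)[2:4, 3:6], matrix(0, 3, 4))
  expect_identical(pixels(blankRegion(red, reg)), pixels(red))
  expect_error(blankRegion(white, RedactionRegion(2, 20, 1, 3)),
               "exceeds")
  # pixels outside the region are untouched bit-exactly
  withr::with_seed(3, px <- matrix(stats::runif(80), 10))
  img <- DocumentImage(px)
  out <- pixels(blankRegion(img, reg))
  mask <- matrix(TRUE, 10, 8); mask[2:4, 3:6] <- FALSE
  expect_identical(out[mask], px[mask])
})

test_that("de-identification blanks the personal-information band", {
  sim <- simulateFormImage(skewDeg = 0, noiseRate = 0, seed = 14)
  de <- deidentifyForm(sim$image)
  expect_false(is.na(de$markerRow))
  reg <- sim$truth$redactionRegion
  above <- pixels(de$image)[seq_len(reg@rowEnd - 2L), ]
  # everything above the marker is black: nothing of the personal band
  # survives outside the redacted area
  expect_true(all(above == 0))
  below <- pixels(de$image)[(de$markerRow + 2):nrow(pixels(de$image)), ]
  expect_identical(below,
                   pixels(sim$image)[(de$markerRow + 2):nrow(pixels(sim$image)), ])
})

test_that("page images round-trip through PNG and TIFF", {
  sim <- simulateFormImage(skewDeg = 1, seed = 2)
  for (ext in c("png", "tiff")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    writeFormImage(sim$image, f)
    back <- readFormImage(f)
    expect_equal(pixels(back), pixels(sim$image), tolerance = 1 / 254)
  }
})
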