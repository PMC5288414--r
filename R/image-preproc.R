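#' Construct a DocumentImage from a pixel matrix
#'
#' @param pixels numeric matrix with intensities in \[0, 1\]
#'   (0 = black ink, 1 = white background), rows = pixel lines from the
#'   top of the page.
#' @return a \linkS4class{DocumentImage}.
#' @export
DocumentImage <- function(pixels) {
  storage.mode(pixels) <- "double"
  new("DocumentImage", pixels = pixels)
}

# Rotate a raster about its centre, keeping dimensions. Inverse mapping:
# each output pixel pulls from the source location obtained by rotating
# its centred coordinates by -angle. Uncovered pixels get `fill`.
# filter "nearest" preserves a binary alphabet; "bilinear" is for
# grayscale input.
rotatePixels <- function(px, angleDeg, filter = c("nearest", "bilinear"),
                         fill = 1) {
  filter <- match.arg(filter)
  if (angleDeg == 0) return(px)
  h <- nrow(px); w <- ncol(px)
  th <- angleDeg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  dy <- (seq_len(h) - cy); dx <- (seq_len(w) - cx)
  ct <- cos(th); st <- sin(th)
  # source coordinates for every output pixel (h x w outer sums)
  srcR <- outer(ct * dy, -st * dx, "+") + cy
  srcC <- outer(st * dy, ct * dx, "+") + cx
  out <- matrix(fill, h, w)
  if (filter == "nearest") {
    i <- round(srcR); j <- round(srcC)
    ok <- i >= 1 & i <= h & j >= 1 & j <= w
    out[ok] <- px[cbind(i[ok], j[ok])]
  } else {
    i0 <- floor(srcR); j0 <- floor(srcC)
    fr <- srcR - i0; fc <- srcC - j0
    ok <- i0 >= 1 & i0 + 1 <= h & j0 >= 1 & j0 + 1 <= w
    i0k <- i0[ok]; j0k <- j0[ok]; frk <- fr[ok]; fck <- fc[ok]
    v <- px[cbind(i0k, j0k)] * (1 - frk) * (1 - fck) +
      px[cbind(i0k + 1, j0k)] * frk * (1 - fck) +
      px[cbind(i0k, j0k + 1)] * (1 - frk) * fck +
      px[cbind(i0k + 1, j0k + 1)] * frk * fck
    out[ok] <- v
  }
  out
}

isBinaryImage <- function(image) all(image@pixels %in% c(0, 1))

#' Otsu's global threshold
#'
#' Computes the threshold maximising between-class variance of the
#' intensity histogram (256 bins over \[0, 1\]).
#'
#' @param image a \linkS4class{DocumentImage}.
#' @return scalar threshold in (0, 1).
#' @export
otsuThreshold <- function(image) {
  px <- pixels(image)
  breaks <- seq(0, 1, length.out = 257)
  h <- tabulate(findInterval(px, breaks, all.inside = TRUE), nbins = 256)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[256]
  sb <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Binarize a grayscale page
#'
#' A pixel becomes black (0) iff its intensity is strictly below the
#' threshold; all other pixels become white (1).
#'
#' @param image a \linkS4class{DocumentImage}.
#' @param threshold scalar in (0, 1); \code{NULL} selects Otsu's
#'   threshold.
#' @return a binary \linkS4class{DocumentImage}.
#' @export
binarizeImage <- function(image, threshold = NULL) {
  if (is.null(threshold)) threshold <- otsuThreshold(image)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  px <- pixels(image)
  DocumentImage(matrix(as.double(px >= threshold), nrow(px), ncol(px)))
}

#' Per-row black-pixel fractions at a candidate skew angle
#'
#' The binarized page is rotated by \code{angleDeg} about its centre
#' (nearest-neighbour resampling, white fill) and each row's black-pixel
#' count is divided by the row's total pixel count.
#'
#' @param image a binary \linkS4class{DocumentImage}.
#' @param angleDeg rotation angle in degrees.
#' @return numeric vector of fractions in \[0, 1\], one per row.
#' @export
rowProfile <- function(image, angleDeg = 0) {
  stopifnot(isBinaryImage(image))
  px <- rotatePixels(pixels(image), angleDeg, "nearest", fill = 1)
  rowSums(px == 0) / ncol(px)
}

#' Row-profile entropy with the 10% line filter
#'
#' H = -sum over qualifying rows of P * log(P), natural logarithm, where
#' P is the row's black-pixel fraction. Rows with fewer than
#' \code{minFraction} black pixels (noise and blank rows) are excluded;
#' a fully black row (P = 1) contributes zero. With no qualifying rows
#' the entropy is zero.
#'
#' @param profile numeric vector of per-row black fractions.
#' @param minFraction exclusion threshold, default 0.10.
#' @return non-negative scalar entropy.
#' @export
skewEntropy <- function(profile, minFraction = 0.10) {
  stopifnot(all(profile >= 0 & profile <= 1))
  p <- profile[profile >= minFraction]
  if (!length(p)) return(0)
  -sum(p * log(p))
}

#' Estimate the corrective skew angle by entropy minimisation
#'
#' Searches a coarse 1-degree grid over \code{[-rangeDeg, rangeDeg]},
#' then a fine grid at \code{stepDeg} within 1 degree of the coarse
#' optimum, for the angle minimising \code{skewEntropy(rowProfile())}.
#' Ties are broken toward the smallest absolute angle, then toward the
#' negative angle. The returned angle is the rotation that de-skews the
#' page (a page skewed by +3 degrees yields an estimate near -3).
#'
#' @param image a binary \linkS4class{DocumentImage}.
#' @param rangeDeg half-width of the search interval in degrees.
#' @param stepDeg fine grid step (> 0).
#' @param minFraction row filter passed to \code{\link{skewEntropy}}.
#' @return a \linkS4class{SkewEstimate}.
#' @export
estimateSkew <- function(image, rangeDeg = 20, stepDeg = 0.1,
                         minFraction = 0.10) {
  stopifnot(isBinaryImage(image), stepDeg > 0, rangeDeg > 0)
  px <- pixels(image)
  if (!any(px == 0)) {
    warning("blank image: no black pixels, returning angle 0")
    return(new("SkewEstimate", angleDeg = 0, entropy = 0,
               profile = rowSums(px == 0) / ncol(px)))
  }
  evalAngles <- function(angles) {
    vapply(angles, function(a)
      skewEntropy(rowProfile(image, a), minFraction), numeric(1))
  }
  pickBest <- function(angles, H) {
    o <- order(H, abs(angles), angles)
    angles[o[1]]
  }
  coarseStep <- max(min(1, rangeDeg), stepDeg)
  coarse <- seq(-rangeDeg, rangeDeg, by = coarseStep)
  Hc <- evalAngles(coarse)
  best <- pickBest(coarse, Hc)
  fine <- seq(max(-rangeDeg, best - coarseStep),
              min(rangeDeg, best + coarseStep), by = stepDeg)
  fine <- setdiff(round(fine, 10), round(coarse, 10))
  all <- coarse; H <- Hc
  if (length(fine)) {
    all <- c(coarse, fine)
    H <- c(Hc, evalAngles(fine))
  }
  aStar <- pickBest(all, H)
  prof <- rowProfile(image, aStar)
  new("SkewEstimate", angleDeg = aStar,
      entropy = skewEntropy(prof, minFraction), profile = prof)
}

#' Rotate a page to undo its skew
#'
#' Rotates about the image centre keeping the dimensions; uncovered
#' border pixels are filled white. Binary pages use nearest-neighbour
#' resampling (the output stays binary), grayscale pages bilinear.
#'
#' @param image a \linkS4class{DocumentImage}.
#' @param angleDeg rotation angle in degrees (use the
#'   \code{\link{estimateSkew}} angle to de-skew).
#' @return the rotated \linkS4class{DocumentImage}.
#' @export
deskewImage <- function(image, angleDeg) {
  filter <- if (isBinaryImage(image)) "nearest" else "bilinear"
  DocumentImage(rotatePixels(pixels(image), angleDeg, filter, fill = 1))
}

# 3x3 Sobel kernels: horizontal-gradient and vertical-gradient
sobelKx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
sobelKy <- matrix(c(1, 0, -1, 2, 0, -2, 1, 0, -1), 3, 3)

# direct 3x3 cross-correlation with replicated borders, via nine
# shifted adds over the padded raster (kernel entries visited in
# row-major order, matching a naive double loop)
conv3x3 <- function(px, k) {
  h <- nrow(px); w <- ncol(px)
  pad <- rbind(px[1, , drop = FALSE], px, px[h, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, w, drop = FALSE])
  out <- matrix(0, h, w)
  for (di in -1:1) for (dj in -1:1) {
    kv <- k[di + 2, dj + 2]
    if (kv != 0)
      out <- out + kv * pad[(2 + di):(h + 1 + di), (2 + dj):(w + 1 + dj)]
  }
  out
}

#' Sobel gradient magnitude
#'
#' Applies the pair of 3x3 Sobel kernels (horizontal and vertical
#' gradients) with replicated borders and returns
#' sqrt(Gx^2 + Gy^2).
#'
#' @param image a \linkS4class{DocumentImage} of at least 3 x 3 pixels.
#' @return numeric matrix of gradient magnitudes, same dimensions.
#' @export
sobelEdges <- function(image) {
  px <- pixels(image)
  if (nrow(px) < 3 || ncol(px) < 3)
    stop("image must be at least 3 x 3 for Sobel edges")
  gx <- conv3x3(px, sobelKx)
  gy <- conv3x3(px, sobelKy)
  sqrt(gx^2 + gy^2)
}

#' Locate the personal-information marker line
#'
#' On semi-structured forms the personal-information block sits above a
#' strong horizontal separator (a line of asterisks on the referral
#' form). The marker is taken as the row with maximal summed Sobel edge
#' energy within the top \code{searchFraction} of the page; equal-energy
#' ties resolve to the smaller row index.
#'
#' @param edges gradient-magnitude matrix from \code{\link{sobelEdges}}.
#' @param searchFraction fraction (0, 1\] of top rows searched.
#' @param energyFloor minimum summed row energy; below it the marker is
#'   declared not found (returns \code{NA} with a warning) and the
#'   caller should fall back to a manually supplied region. Defaults to
#'   an average gradient magnitude of 1 per pixel.
#' @return integer row index, or \code{NA_integer_} when not found.
#' @export
locateMarkerLine <- function(edges, searchFraction = 0.5,
                             energyFloor = ncol(edges)) {
  stopifnot(searchFraction > 0, searchFraction <= 1)
  nTop <- max(1L, floor(nrow(edges) * searchFraction))
  energy <- rowSums(edges[seq_len(nTop), , drop = FALSE])
  if (max(energy) < energyFloor) {
    warning("marker not found: no row exceeds the energy floor")
    return(NA_integer_)
  }
  which.max(energy)
}

#' Create a RedactionRegion
#'
#' Half-open bounds: rows \code{rowStart:(rowEnd-1)} and columns
#' \code{colStart:(colEnd-1)} are inside the region.
#'
#' @param rowStart,rowEnd,colStart,colEnd integer bounds (1-based,
#'   half-open).
#' @return a \linkS4class{RedactionRegion}.
#' @export
RedactionRegion <- function(rowStart, rowEnd, colStart, colEnd) {
  new("RedactionRegion", rowStart = as.integer(rowStart),
      rowEnd = as.integer(rowEnd), colStart = as.integer(colStart),
      colEnd = as.integer(colEnd))
}

#' Blank a region of a page
#'
#' Every pixel in the half-open region is painted black (0); pixels
#' outside are untouched bit-exactly. Idempotent.
#'
#' @param image a \linkS4class{DocumentImage}.
#' @param region a \linkS4class{RedactionRegion} within the page bounds.
#' @return the redacted \linkS4class{DocumentImage}.
#' @export
blankRegion <- function(image, region) {
  px <- pixels(image)
  if (region@rowEnd > nrow(px) + 1L || region@colEnd > ncol(px) + 1L)
    stop("redaction region exceeds the image bounds")
  px[region@rowStart:(region@rowEnd - 1L),
     region@colStart:(region@colEnd - 1L)] <- 0
  DocumentImage(px)
}

#' De-identify a semi-structured form
#'
#' Convenience wrapper: locate the marker line from the Sobel edges and
#' blank everything above it across the full page width. If the marker
#' is not found the image is returned unchanged (with the
#' \code{\link{locateMarkerLine}} warning) so the caller can apply a
#' manual mask instead.
#'
#' @param image a \linkS4class{DocumentImage}.
#' @param searchFraction top fraction of the page searched for the
#'   marker.
#' @return list with elements \code{image} (redacted page) and
#'   \code{markerRow} (integer or NA).
#' @export
deidentifyForm <- function(image, searchFraction = 0.5) {
  marker <- locateMarkerLine(sobelEdges(image), searchFraction)
  if (is.na(marker) || marker < 2L)
    return(list(image = image, markerRow = marker))
  region <- RedactionRegion(1L, marker, 1L, ncol(pixels(image)) + 1L)
  list(image = blankRegion(image, region), markerRow = marker)
}

#' Read and write page images
#'
#' PNG and TIFF rasters are supported; colour images are converted to
#' grayscale by channel averaging.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param image a \linkS4class{DocumentImage} (for writing).
#' @return \code{readFormImage} returns a \linkS4class{DocumentImage};
#'   \code{writeFormImage} returns \code{path} invisibly.
#' @export
readFormImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:3, drop = FALSE], c(1, 2), mean)
  DocumentImage(pmin(pmax(arr, 0), 1))
}

#' @rdname readFormImage
#' @export
writeFormImage <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  px <- pixels(image)
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
    stop("unsupported image format: ", ext))
  invisible(path)
}
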