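# Procedural digit generator (no download) and MNIST-compatible IDX I/O.

drawH <- function(m, r, c1, c2) { m[(r - 1):(r + 1), c1:c2] <- 255; m }
drawV <- function(m, c, r1, r2) { m[r1:r2, (c - 1):(c + 1)] <- 255; m }

# 3x3 binomial blur with zero padding; grades stroke edges so latency
# encoding spreads spike times instead of producing one synchronous volley.
blur3 <- function(m) {
  p <- rbind(0, m, 0)
  v <- (p[1:28, ] + 2 * p[2:29, ] + p[3:30, ]) / 4
  p <- cbind(0, v, 0)
  (p[, 1:28] + 2 * p[, 2:29] + p[, 3:30]) / 4
}

# Seven-segment stroke templates on the 28x28 canvas, stroke width 3 px,
# blurred and renormalized to peak 255.
digitTemplate <- function(digit) {
  segs <- list(
    "0" = c("A", "B", "C", "D", "E", "F"),
    "1" = c("B", "C"),
    "2" = c("A", "B", "G", "E", "D"),
    "3" = c("A", "B", "G", "C", "D"),
    "4" = c("F", "G", "B", "C"),
    "5" = c("A", "F", "G", "C", "D"),
    "6" = c("A", "F", "G", "E", "D", "C"),
    "7" = c("A", "B", "C"),
    "8" = c("A", "B", "C", "D", "E", "F", "G"),
    "9" = c("A", "B", "C", "D", "F", "G"))[[as.character(digit)]]
  m <- matrix(0, 28, 28)
  for (s in segs) {
    m <- switch(s,
      A = drawH(m, 5, 9, 19),
      G = drawH(m, 14, 9, 19),
      D = drawH(m, 23, 9, 19),
      F = drawV(m, 9, 4, 15),
      E = drawV(m, 9, 13, 24),
      B = drawV(m, 19, 4, 15),
      C = drawV(m, 19, 13, 24))
  }
  m <- blur3(m)
  if (max(m) > 0) m <- m / max(m) * 255
  round(m)
}

shiftImage <- function(m, dr, dc) {
  out <- matrix(0, 28, 28)
  srcR <- max(1, 1 - dr):min(28, 28 - dr)
  srcC <- max(1, 1 - dc):min(28, 28 - dc)
  out[srcR + dr, srcC + dc] <- m[srcR, srcC]
  out
}

#' Generate a balanced set of procedural digit images
#'
#' Renders each digit 0-9 from fixed seven-segment stroke templates onto a
#' 28x28 canvas (strokes at 255 on background 0, edges graded by a small
#' blur), then applies a seeded integer translation jitter within
#' \code{±jitterPx} pixels and salt noise (random pixels set to 255 with
#' probability \code{noiseLevel}). Labels are assigned round-robin
#' 0,1,...,9,0,... so every class count is within one of n/10. The same
#' (n, seed, jitterPx, noiseLevel) always yields the identical set.
#'
#' @param n number of images
#' @param seed integer seed
#' @param jitterPx maximum absolute translation per axis, px
#' @param noiseLevel per-pixel salt probability
#' @return a [LabeledImageSet]
#' @export
generateDigits <- function(n, seed = 0L, jitterPx = 1L, noiseLevel = 0.02) {
  stopifnot(n > 0)
  templates <- lapply(0:9, digitTemplate)
  labels <- rep(0:9, length.out = n)
  images <- array(0L, dim = c(28, 28, n))
  withr::with_seed(deriveSeed(seed, 99), {
    for (k in seq_len(n)) {
      img <- templates[[labels[k] + 1]]
      if (jitterPx > 0) {
        dr <- sample(-jitterPx:jitterPx, 1)
        dc <- sample(-jitterPx:jitterPx, 1)
        img <- shiftImage(img, dr, dc)
      }
      if (noiseLevel > 0) {
        salt <- stats::runif(784) < noiseLevel
        img[salt] <- 255
      }
      images[, , k] <- as.integer(round(img))
    }
  })
  new("LabeledImageSet", images = images, labels = as.integer(labels),
      seed = as.integer(seed))
}

IDX_IMAGE_MAGIC <- 2051L  # 0x00000803
IDX_LABEL_MAGIC <- 2049L  # 0x00000801

#' Write a labelled image set as MNIST IDX (ubyte) files
#'
#' Standard big-endian IDX layout: images with magic 0x00000803 and
#' dimensions (n, rows, cols), pixels row-major; labels with magic
#' 0x00000801.
#'
#' @param set a [LabeledImageSet]
#' @param imagesPath,labelsPath output file paths
#' @return invisibly, the two paths
#' @export
writeIdxSet <- function(set, imagesPath, labelsPath) {
  n <- length(set@labels)
  con <- file(imagesPath, "wb")
  writeBin(c(IDX_IMAGE_MAGIC, n, 28L, 28L), con, size = 4, endian = "big")
  px <- unlist(lapply(seq_len(n), function(k) as.integer(t(set@images[, , k]))),
               use.names = FALSE)
  writeBin(as.raw(px), con)
  close(con)
  con <- file(labelsPath, "wb")
  writeBin(c(IDX_LABEL_MAGIC, n), con, size = 4, endian = "big")
  writeBin(as.raw(set@labels), con)
  close(con)
  invisible(c(imagesPath, labelsPath))
}

readIdxHeader <- function(con, expectedMagic, nDims, path) {
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (length(magic) == 0 || magic != expectedMagic)
    stop(sprintf("bad IDX magic 0x%08x in '%s' at byte offset 0 (expected 0x%08x)",
                 if (length(magic)) magic else 0L, path, expectedMagic))
  dims <- readBin(con, "integer", nDims, size = 4, endian = "big")
  if (length(dims) < nDims)
    stop(sprintf("truncated IDX header in '%s' at byte offset %d",
                 path, 4 + 4 * length(dims)))
  dims
}

#' Read an MNIST IDX image/label file pair
#'
#' Bit-exact reader for the standard IDX (ubyte) container: big-endian magic
#' numbers 0x00000803 (images) / 0x00000801 (labels) and dimension headers.
#' Bad magic or a truncated payload raises a format error naming the byte
#' offset. \code{writeIdxSet()} followed by \code{readIdxSet()} is the
#' identity on images and labels.
#'
#' @param imagesPath,labelsPath input file paths
#' @return a [LabeledImageSet] (seed is NA)
#' @export
readIdxSet <- function(imagesPath, labelsPath) {
  con <- file(imagesPath, "rb")
  on.exit(close(con), add = TRUE)
  dims <- readIdxHeader(con, IDX_IMAGE_MAGIC, 3L, imagesPath)
  n <- dims[1]; rows <- dims[2]; cols <- dims[3]
  expected <- n * rows * cols
  raw <- readBin(con, "raw", expected)
  if (length(raw) < expected)
    stop(sprintf("truncated IDX payload in '%s': expected %d pixel bytes, file ends at byte offset %d",
                 imagesPath, expected, 16 + length(raw)))
  images <- aperm(array(as.integer(raw), dim = c(cols, rows, n)), c(2, 1, 3))

  con2 <- file(labelsPath, "rb")
  on.exit(close(con2), add = TRUE)
  dims2 <- readIdxHeader(con2, IDX_LABEL_MAGIC, 1L, labelsPath)
  if (dims2[1] != n)
    stop(sprintf("label count %d does not match image count %d", dims2[1], n))
  rawL <- readBin(con2, "raw", n)
  if (length(rawL) < n)
    stop(sprintf("truncated IDX payload in '%s': expected %d label bytes, file ends at byte offset %d",
                 labelsPath, n, 8 + length(rawL)))
  new("LabeledImageSet", images = images, labels = as.integer(rawL),
      seed = NA_integer_)
}
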