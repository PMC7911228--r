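#' Latency-encode pixel values into spike times
#'
#' With v = value/255 normalized to [0, 1], the spike time is
#' S = (v - 1)^2 (T_stop - T_start) + T_start: the brightest pixel (255)
#' fires at T_start, background (0) at T_stop, and the mapping is a strictly
#' decreasing bijection from [0, 255] onto the window, steepest near bright
#' pixels — the rank-order principle that earlier spikes carry more
#' information.
#'
#' @param value pixel value(s) in [0, 255]
#' @param params an [EncodingParams] object
#' @return spike time(s) in ms
#' @export
encodePixel <- function(value, params = EncodingParams()) {
  if (any(value < 0 | value > 255))
    stop("pixel values must lie in [0, 255]")
  v <- value / 255
  (v - 1)^2 * (params@tStop - params@tStart) + params@tStart
}

#' Latency-encode a whole image or channel
#'
#' Elementwise [encodePixel()]: one spike per pixel per presentation.
#'
#' @param image numeric matrix with values in [0, 255]
#' @param params an [EncodingParams] object
#' @return matrix of spike times (ms) with the input's shape
#' @export
encodeImage <- function(image, params = EncodingParams()) {
  out <- encodePixel(image, params)
  dim(out) <- dim(image)
  out
}

#' Default 4x4 convolution kernels
#'
#' The four fixed feature kernels used by the three-layer network: uniform
#' average, horizontal edge, vertical edge, and diagonal edge. Deterministic
#' and parameter-free; replaceable via the \code{filters} argument of the
#' network builders.
#'
#' @param n number of kernels (1-4)
#' @return list of 4x4 matrices
#' @export
defaultKernels <- function(n = 4) {
  stopifnot(n >= 1, n <= 4)
  avg <- matrix(1 / 16, 4, 4)
  hor <- rbind(matrix(1 / 8, 2, 4), matrix(-1 / 8, 2, 4))
  ver <- cbind(matrix(1 / 8, 4, 2), matrix(-1 / 8, 4, 2))
  dia <- outer(1:4, 1:4, function(r, c) ifelse((r <= 2) == (c <= 2), 1 / 8, -1 / 8))
  list(avg, hor, ver, dia)[seq_len(n)]
}

# Valid (no-padding) 4x4 stride-1 convolution of a 28x28 image -> 25x25.
conv4x4 <- function(image, kernel) {
  out <- matrix(0, 25, 25)
  for (a in 1:4) for (b in 1:4)
    out <- out + kernel[a, b] * image[a:(a + 24), b:(b + 24)]
  out
}

# 2x2 stride-2 pooling with floor truncation: 25x25 -> 12x12 (row/col 25
# dropped).
pool2x2 <- function(m, pooling = c("max", "mean")) {
  pooling <- match.arg(pooling)
  r <- seq(1, 23, by = 2)
  a <- m[r, r]; b <- m[r + 1, r]; cc <- m[r, r + 1]; d <- m[r + 1, r + 1]
  if (pooling == "max") pmax(a, b, cc, d) else (a + b + cc + d) / 4
}

#' Convolution/pooling preprocessing of a 28x28 image
#'
#' Applies each 4x4 kernel as a valid stride-1 convolution (25x25), then 2x2
#' stride-2 pooling with floor truncation (12x12), and rescales each channel
#' back onto [0, 255] so it can be latency-encoded like a raw image. A
#' constant channel (zero range) is left unscaled and clamped.
#'
#' @param image 28x28 numeric matrix
#' @param nFilters number of channels (default 4)
#' @param filters list of 4x4 kernels (default [defaultKernels()])
#' @param pooling "max" or "mean"
#' @return 12 x 12 x nFilters array with values in [0, 255]
#' @export
preprocessImage <- function(image, nFilters = 4, filters = defaultKernels(nFilters),
                            pooling = c("max", "mean")) {
  if (!is.matrix(image) || !identical(dim(image), c(28L, 28L)))
    stop("image must be a 28x28 matrix")
  pooling <- match.arg(pooling)
  preprocessChannels(image, nFilters, filters, pooling)$values
}

# Shared conv/pool core. `active` marks pixels with a strictly positive raw
# filter response: background and anti-preferred pixels carry no information
# and are tailored out of the memory-layer drive in the growth experiment.
preprocessChannels <- function(image, nFilters, filters, pooling) {
  stopifnot(length(filters) == nFilters)
  values <- array(0, dim = c(12, 12, nFilters))
  active <- array(FALSE, dim = c(12, 12, nFilters))
  for (f in seq_len(nFilters)) {
    ch <- pool2x2(conv4x4(image, filters[[f]]), pooling)
    active[, , f] <- ch > 1e-9
    rng <- range(ch)
    if (diff(rng) > 1e-12) {
      ch <- (ch - rng[1]) / diff(rng) * 255
    } else {
      ch <- clip(ch, 0, 255)
    }
    values[, , f] <- ch
  }
  list(values = values, active = active)
}

#' Export encoded spike times as a long-format table
#'
#' @param encoded matrix (single channel) or 3-d array of spike times
#' @return data.frame with columns pixel_row, pixel_col, channel, time_ms
#' @export
encodedToTable <- function(encoded) {
  if (is.matrix(encoded)) encoded <- array(encoded, dim = c(dim(encoded), 1))
  d <- dim(encoded)
  data.frame(
    pixel_row = rep(seq_len(d[1]), times = d[2] * d[3]),
    pixel_col = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    channel = rep(seq_len(d[3]), each = d[1] * d[2]),
    time_ms = as.vector(encoded))
}
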