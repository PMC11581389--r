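# deep_features: 227x227 bilinear resize and the pool2 activations of the
# AlexNet-architecture front end.  Weights are seeded-random by default so
# the whole pipeline runs offline; a pretrained-weight file of the same
# shapes can be supplied instead.

#' Convolution/pooling output-size arithmetic
#'
#' `floor((input + 2 pad - kernel) / stride) + 1`.
#'
#' @param input,kernel,stride,pad layer geometry (scalars).
#' @return integer output size.
#' @examples
#' ## the 227 -> 55 -> 27 -> 27 -> 13 chain down to pool2
#' convOutputSize(227, 11, 4)                    # conv1
#' convOutputSize(convOutputSize(227, 11, 4), 3, 2)
#' @export
convOutputSize <- function(input, kernel, stride = 1L, pad = 0L) {
  as.integer(floor((input + 2 * pad - kernel) / stride) + 1)
}

#' @rdname convOutputSize
#' @return `pool2Shape()`: the pool2 output shape `c(rows, cols, channels)`
#'   derived from the layer arithmetic (13, 13, 256 for a 227 input).
#' @export
pool2Shape <- function(input = 227L) {
  s <- convOutputSize(input, 11, 4)   # conv1
  s <- convOutputSize(s, 3, 2)        # pool1
  s <- convOutputSize(s, 5, 1, 2)     # conv2
  s <- convOutputSize(s, 3, 2)        # pool2
  c(s, s, 256L)
}

# Separable bilinear interpolation matrix mapping `nIn` samples to `nOut`,
# half-pixel-centre convention; rows sum to 1, so constants are preserved.
bilinearMatrix <- function(nOut, nIn) {
  s <- pmin(nIn - 1, pmax(0, ((seq_len(nOut) - 0.5) * nIn / nOut) - 0.5))
  lo <- floor(s)
  w <- s - lo
  m <- matrix(0, nOut, nIn)
  m[cbind(seq_len(nOut), lo + 1)] <- 1 - w
  hi <- pmin(lo + 1, nIn - 1)
  m[cbind(seq_len(nOut), hi + 1)] <- m[cbind(seq_len(nOut), hi + 1)] + w
  m
}

#' Resize a patient image to the extractor input
#'
#' Bilinear resize of the grayscale grid to 227 x 227 (separable
#' interpolation, half-pixel-centre convention), replicated to 3 identical
#' channels.  Values stay in \[0, 1\], the extractor's input range under
#' seeded-random weights; constants are preserved exactly.
#'
#' @param image rows x cols numeric matrix in \[0, 1\].
#' @param size target spatial size (227).
#' @return size x size x 3 array.
#' @export
resizeToInput <- function(image, size = 227L) {
  array(resizePlane(image, size), c(size, size, 3L))
}

resizePlane <- function(image, size = 227L) {
  image <- as.matrix(image)
  if (length(image) == 0) stop("empty image")
  R <- bilinearMatrix(size, nrow(image))
  C <- bilinearMatrix(size, ncol(image))
  R %*% image %*% t(C)
}

#' Seeded-random extractor weights
#'
#' Gaussian He-scaled weights (`sd = sqrt(2 / fan_in)`) for conv1 and
#' conv2, zero biases; fully reproducible under `seed`.
#'
#' @param seed integer seed.
#' @return an [ExtractorWeights-class].
#' @export
randomExtractorWeights <- function(seed = 1L) {
  withSeed(as.integer(seed), {
    c1 <- array(rnorm(11 * 11 * 3 * 96, sd = sqrt(2 / (11 * 11 * 3))),
                c(11L, 11L, 3L, 96L))
    c2 <- array(rnorm(5 * 5 * 96 * 256, sd = sqrt(2 / (5 * 5 * 96))),
                c(5L, 5L, 96L, 256L))
    new("ExtractorWeights", conv1 = c1, bias1 = numeric(96), conv2 = c2,
        bias2 = numeric(256), source = "seeded-random",
        seed = as.integer(seed),
        fingerprint = weightFingerprint("seeded-random", seed, c1, c2))
  })
}

#' Load pretrained extractor weights from an RDS file
#'
#' The file must hold a list with arrays `conv1` (11 x 11 x 3 x 96),
#' `bias1` (96), `conv2` (5 x 5 x 96 x 256) and `bias2` (256), e.g.
#' exported from a pretrained AlexNet.  A missing file is an explicit
#' error: there is no silent fallback to random weights.
#'
#' @param path RDS path.
#' @return an [ExtractorWeights-class].
#' @export
loadExtractorWeights <- function(path) {
  if (!file.exists(path))
    stop("pretrained weights unavailable: file not found: ", path,
         "\nuse randomExtractorWeights() for seeded-random weights")
  w <- readRDS(path)
  new("ExtractorWeights", conv1 = w$conv1, bias1 = as.numeric(w$bias1),
      conv2 = w$conv2, bias2 = as.numeric(w$bias2), source = "file",
      seed = NA_integer_,
      fingerprint = weightFingerprint("file", NA, w$conv1, w$conv2))
}

#' Extract pool2 deep features from patient images
#'
#' Each image is bilinearly resized to 227 x 227, replicated to 3
#' channels and passed through conv1 (96 filters 11 x 11, stride 4) +
#' ReLU, max-pool 3 x 3 stride 2, conv2 (256 filters 5 x 5, padding 2) +
#' ReLU and max-pool 3 x 3 stride 2.  The 13 x 13 x 256 pool2 output is
#' flattened to a 43,264-length vector in a fixed order (feature index =
#' row + 13 col + 169 channel, 0-based).  Extraction is pure and
#' deterministic for fixed weights.
#'
#' @param images a [PatientImageSet-class].
#' @param weights an [ExtractorWeights-class].
#' @param batchSize images per C++ call (memory knob only).
#' @return a [DeepFeatureMatrix-class] (n x 43264).
#' @export
extractDeepFeatures <- function(images, weights, batchSize = 64L) {
  n <- nPatients(images)
  if (n == 0) stop("empty image set")
  # channels are replicated grayscale, so conv1 uses the plane with the
  # channel-summed kernel (identical arithmetic, a third of the work)
  w1 <- matrix(weights@conv1, 363, 96)
  w1 <- w1[1:121, ] + w1[122:242, ] + w1[243:363, ]
  w2 <- matrix(weights@conv2, 2400, 256)
  out <- matrix(NA_real_, n, 43264L)
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    inp <- vapply(idx, function(i)
      as.numeric(resizePlane(images@pixels[, , i])),
      numeric(227 * 227))
    out[idx, ] <- cpp_extract_pool2(inp, w1, weights@bias1, w2,
                                    weights@bias2)
  }
  rownames(out) <- images@patientIds
  new("DeepFeatureMatrix", values = out, fingerprint = weights@fingerprint)
}
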