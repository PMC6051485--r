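#' Describe a resolution-preserving dilated segmentation network
#'
#' A network spec lists five feature blocks followed by a classifier block.
#' Each feature block holds `layers` convolutions with a per-axis `kernel`
#' (odd tap counts) and per-axis `dilation`, all resolution-preserving via
#' symmetric zero padding. Outputs of the five blocks are concatenated (in 3D
#' through per-block 1x1x1 compression convolutions) and fed to the
#' classifier, a 1x1(x1) convolution producing two-channel logits.
#'
#' @param blocks list of feature-block descriptors; each a list with elements
#'   `kernel` (length-3 integer, odd), `dilation` (length-3 integer, >= 1),
#'   `channels` and `layers`.
#' @param dims spatial dimensionality, 2 or 3.
#' @param compression_channels channel count of the per-block 1x1x1
#'   compression convolutions (3D only; `NULL` disables compression).
#' @param classifier_channels output channels of the classifier (always 2
#'   for binary segmentation).
#' @return an object of class `network_spec`.
#' @seealso [pnet_spec()], [pcnet_spec()], [receptive_field()]
#' @export
network_spec <- function(blocks, dims = 2L, compression_channels = NULL,
                         classifier_channels = 2L) {
  spec <- structure(
    list(blocks = blocks, dims = as.integer(dims),
         compression_channels = compression_channels,
         classifier = list(kernel = c(1L, 1L, 1L),
                           channels = as.integer(classifier_channels))),
    class = "network_spec")
  validate_network_spec(spec)
  spec
}

#' @export
print.network_spec <- function(x, ...) {
  rf <- receptive_field(x)
  cat(sprintf("<network_spec> %dD, %d feature blocks + classifier, receptive field %s\n",
              x$dims, length(x$blocks), paste(rf, collapse = "x")))
  for (i in seq_along(x$blocks)) {
    b <- x$blocks[[i]]
    cat(sprintf("  block%d: %d conv x kernel %s, dilation %s, %d channels\n",
                i, b$layers, paste(b$kernel, collapse = "x"),
                paste(b$dilation, collapse = "x"), b$channels))
  }
  if (!is.null(x$compression_channels))
    cat(sprintf("  1x1x1 compression to %d channels per block before concatenation\n",
                x$compression_channels))
  invisible(x)
}

validate_network_spec <- function(spec) {
  if (!spec$dims %in% c(2L, 3L))
    stop("network spec invalid: dims must be 2 or 3", call. = FALSE)
  if (length(spec$blocks) < 1L)
    stop("network spec invalid: at least one feature block required", call. = FALSE)
  for (i in seq_along(spec$blocks)) {
    b <- spec$blocks[[i]]
    if (length(b$kernel) != 3L || any(b$kernel %% 2L != 1L))
      stop(sprintf("network spec invalid: block %d kernel sizes must be odd on every axis (resolution preservation)", i),
           call. = FALSE)
    if (length(b$dilation) != 3L || any(b$dilation < 1L))
      stop(sprintf("network spec invalid: block %d dilations must all be >= 1", i),
           call. = FALSE)
    if (b$layers < 1L || b$channels < 1L)
      stop(sprintf("network spec invalid: block %d needs layers >= 1 and channels >= 1", i),
           call. = FALSE)
    if (spec$dims == 2L && (b$kernel[3] != 1L || b$dilation[3] != 1L))
      stop(sprintf("network spec invalid: block %d uses the third axis but dims = 2", i),
           call. = FALSE)
  }
  invisible(spec)
}

#' Default 2D bounding-box segmentation network spec
#'
#' Six blocks in total: five dilated feature blocks with in-plane dilations
#' 1, 2, 4, 8, 16 holding 2, 2, 3, 3, 3 convolutions of 3x3 taps, plus the
#' 1x1 classifier block fed by the concatenation of the five block outputs.
#' This fixed kernel/dilation structure gives a theoretical receptive field
#' of exactly 181 x 181 pixels, which the constructor verifies.
#'
#' @param channels channel width of every feature block. The default is a
#'   compact desk-scale width; `profile = "original"` selects the original
#'   64-channel width used with cluster-scale training.
#' @param profile `"compact"` (default) or `"original"`.
#' @return a `network_spec` for [build_network()].
#' @export
pnet_spec <- function(channels = 8L, profile = c("compact", "original")) {
  profile <- match.arg(profile)
  if (profile == "original") channels <- 64L
  dil <- c(1L, 2L, 4L, 8L, 16L)
  nlay <- c(2L, 2L, 3L, 3L, 3L)
  blocks <- lapply(1:5, function(i) {
    list(kernel = c(3L, 3L, 1L), dilation = c(dil[i], dil[i], 1L),
         channels = as.integer(channels), layers = nlay[i])
  })
  spec <- network_spec(blocks, dims = 2L)
  stopifnot(identical(receptive_field(spec), c(181L, 181L)))
  spec
}

#' Default 3D bounding-box segmentation network spec
#'
#' Five feature blocks with 3x3x3 kernels in blocks 1-2 and 3x3x1 kernels in
#' blocks 3-5 (in-plane dilations 1, 2, 3, 4, 5; through-plane dilation 1),
#' per-block 1x1x1 compression convolutions to save feature-cache memory, and
#' a 1x1x1 classifier on the compressed concatenation. The anisotropic
#' receptive field is exactly 85 x 85 x 9 voxels, verified at construction.
#'
#' @param channels feature-block channel width (compact default).
#' @param compression_channels output channels of the per-block compression
#'   convolutions (default 16).
#' @param profile `"compact"` (default) or `"original"` (64-channel blocks).
#' @return a `network_spec` for [build_network()].
#' @export
pcnet_spec <- function(channels = 8L, compression_channels = 16L,
                       profile = c("compact", "original")) {
  profile <- match.arg(profile)
  if (profile == "original") channels <- 64L
  dil <- c(1L, 2L, 3L, 4L, 5L)
  nlay <- c(2L, 2L, 3L, 3L, 3L)
  blocks <- lapply(1:5, function(i) {
    kz <- if (i <= 2) 3L else 1L
    list(kernel = c(3L, 3L, kz), dilation = c(dil[i], dil[i], 1L),
         channels = as.integer(channels), layers = nlay[i])
  })
  spec <- network_spec(blocks, dims = 3L,
                       compression_channels = as.integer(compression_channels))
  stopifnot(identical(receptive_field(spec), c(85L, 85L, 9L)))
  spec
}

#' Theoretical receptive field of a network spec
#'
#' Accumulates `(kernel - 1) * dilation` per convolution layer per axis over
#' all feature blocks and adds 1; the 1x1(x1) classifier and compression
#' convolutions contribute nothing.
#'
#' @param spec a `network_spec`.
#' @return integer vector of per-axis extents (length 2 for 2D, 3 for 3D).
#' @examples
#' receptive_field(pnet_spec())   # 181 181
#' receptive_field(pcnet_spec())  # 85 85 9
#' @export
receptive_field <- function(spec) {
  validate_network_spec(spec)
  ext <- c(0L, 0L, 0L)
  for (b in spec$blocks) {
    ext <- ext + b$layers * (b$kernel - 1L) * b$dilation
  }
  rf <- as.integer(ext + 1L)
  if (spec$dims == 2L) rf[1:2] else rf
}
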