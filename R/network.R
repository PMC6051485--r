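#' Build a trainable segmentation network from a spec
#'
#' Instantiates the convolution parameters described by a [network_spec()].
#' The network maps a single-channel region to a two-channel softmax output
#' of identical spatial shape. Outputs of the five feature blocks feed a
#' concatenation layer (through 1x1x1 compression convolutions in 3D) that
#' feeds the classifier block, whose parameters are separately addressable
#' for classifier-only fine-tuning.
#'
#' @param spec a `network_spec`.
#' @param dims expected spatial dimensionality; must match `spec$dims`.
#' @param seed integer seed for the (He normal) weight initialization.
#' @return an object of class `boxseg_net` with elements `spec`, `dims` and
#'   `params` (a flat named list; the classifier lives under `"cls"`).
#' @export
build_network <- function(spec, dims = spec$dims, seed = 1L) {
  validate_network_spec(spec)
  if (!identical(as.integer(dims), spec$dims))
    stop("configuration error: dims does not match the kernel dimensionality of the spec",
         call. = FALSE)
  set.seed(seed)
  params <- list()
  cin <- 1L
  for (i in seq_along(spec$blocks)) {
    b <- spec$blocks[[i]]
    for (l in seq_len(b$layers)) {
      fan_in <- cin * prod(b$kernel)
      W <- matrix(rnorm(fan_in * b$channels, sd = sqrt(2 / fan_in)),
                  nrow = fan_in, ncol = b$channels)
      params[[sprintf("b%dl%d", i, l)]] <- list(W = W, b = numeric(b$channels))
      cin <- b$channels
    }
  }
  feat_per_block <- if (is.null(spec$compression_channels)) {
    vapply(spec$blocks, function(b) b$channels, integer(1))
  } else {
    for (i in seq_along(spec$blocks)) {
      ch <- spec$blocks[[i]]$channels
      W <- matrix(rnorm(ch * spec$compression_channels, sd = sqrt(2 / ch)),
                  nrow = ch, ncol = spec$compression_channels)
      params[[sprintf("comp%d", i)]] <- list(W = W, b = numeric(spec$compression_channels))
    }
    rep(spec$compression_channels, length(spec$blocks))
  }
  nfeat <- sum(feat_per_block)
  params[["cls"]] <- list(
    W = matrix(rnorm(nfeat * spec$classifier$channels, sd = sqrt(2 / nfeat)),
               nrow = nfeat, ncol = spec$classifier$channels),
    b = numeric(spec$classifier$channels))
  structure(list(spec = spec, dims = spec$dims, params = params, nfeat = nfeat),
            class = "boxseg_net")
}

#' @export
print.boxseg_net <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), numeric(1)))
  cat(sprintf("<boxseg_net> %dD, %d parameters (%d concat features -> classifier)\n",
              x$dims, np, x$nfeat))
  invisible(x)
}

backbone_names <- function(net) setdiff(names(net$params), "cls")

backbone_checksum <- function(net) param_checksum(net$params[backbone_names(net)])

# Foreground probability from two-channel logits, numerically stable and
# identical between the full forward pass and the cached classifier path.
logits_to_prob <- function(logits) stats::plogis(logits[, 2] - logits[, 1])

region_intensities <- function(x) {
  if (inherits(x, "image_region")) x$intensities else x
}

# Full forward pass. Returns concat features, logits, probability and (with
# keep = TRUE) every layer input / pre-activation needed for backprop.
net_forward <- function(net, x, keep = FALSE) {
  x <- region_intensities(x)
  if (ndims_of(x) != net$dims)
    stop("input error: region dimensionality does not match the network", call. = FALSE)
  vol <- as_volume(x)
  sp <- dim(vol)
  npix <- prod(sp)
  spec <- net$spec
  a <- array(as.double(vol), c(sp, 1L))
  store <- if (keep) list() else NULL
  block_out <- vector("list", length(spec$blocks))
  for (i in seq_along(spec$blocks)) {
    b <- spec$blocks[[i]]
    for (l in seq_len(b$layers)) {
      key <- sprintf("b%dl%d", i, l)
      p <- net$params[[key]]
      z <- .conv_fwd(a, dim(a), p$W, p$b, b$kernel, b$dilation)
      if (keep) store[[key]] <- list(x = a, z = z)
      a <- relu(z)
    }
    block_out[[i]] <- a
  }
  feats <- vector("list", length(spec$blocks))
  for (i in seq_along(spec$blocks)) {
    if (is.null(spec$compression_channels)) {
      feats[[i]] <- matrix(block_out[[i]], nrow = npix)
    } else {
      key <- sprintf("comp%d", i)
      p <- net$params[[key]]
      z <- .conv_fwd(block_out[[i]], dim(block_out[[i]]), p$W, p$b,
                     c(1L, 1L, 1L), c(1L, 1L, 1L))
      if (keep) store[[key]] <- list(x = block_out[[i]], z = z)
      feats[[i]] <- matrix(relu(z), nrow = npix)
    }
  }
  FF <- do.call(cbind, feats)
  cls <- net$params$cls
  logits <- FF %*% cls$W
  logits <- sweep(logits, 2, cls$b, "+")
  prob <- array(logits_to_prob(logits), dim(x))
  list(prob = prob, logits = logits, features = FF, spatial_shape = dim(x),
       store = store)
}

#' Foreground probability map for a region
#'
#' Runs a forward pass of the network on a (normalized) cropped region and
#' returns the per-pixel foreground probability of the binary softmax.
#' Deterministic: identical inputs and parameters give identical maps.
#'
#' @param net a `boxseg_net`.
#' @param region an [image_region][crop_region()] or a bare numeric
#'   matrix/array matching the network's dimensionality.
#' @return numeric array of probabilities in `[0, 1]`, same spatial shape as
#'   the input.
#' @export
forward_probability <- function(net, region) {
  net_forward(net, region)$prob
}

#' Cache concatenation-layer features for classifier-only fine-tuning
#'
#' Stores the per-pixel feature vectors at the concatenation layer feeding
#' the classifier, so that repeated classifier-only forward passes (during
#' image-specific fine-tuning) avoid recomputing the feature blocks. While
#' the non-classifier parameters are unchanged, [classifier_forward()] on the
#' cache reproduces [forward_probability()] bit for bit.
#'
#' @inheritParams forward_probability
#' @return a `feature_cache` with the feature matrix, the spatial shape and
#'   a checksum of the non-classifier parameters (for staleness detection).
#' @export
cache_features <- function(net, region) {
  fwd <- net_forward(net, region)
  structure(list(features = fwd$features, spatial_shape = fwd$spatial_shape,
                 dims = net$dims, backbone = backbone_checksum(net)),
            class = "feature_cache")
}

#' Classifier-only forward pass from cached features
#'
#' @param net a `boxseg_net` (only its classifier parameters are used).
#' @param cache a `feature_cache` from [cache_features()].
#' @return foreground probability array of the cached spatial shape.
#' @export
classifier_forward <- function(net, cache) {
  stopifnot(inherits(cache, "feature_cache"))
  cls <- net$params$cls
  logits <- cache$features %*% cls$W
  logits <- sweep(logits, 2, cls$b, "+")
  array(logits_to_prob(logits), cache$spatial_shape)
}

# Backward pass through the whole network given d(loss)/d(logits)
# (npix x 2). Returns gradients as a flat list parallel to net$params.
net_backward <- function(net, fwd, dlogits) {
  spec <- net$spec
  npix <- nrow(fwd$features)
  grads <- list()
  cls <- net$params$cls
  grads$cls <- list(W = crossprod(fwd$features, dlogits), b = colSums(dlogits))
  dF <- dlogits %*% t(cls$W)

  nb <- length(spec$blocks)
  fpb <- if (is.null(spec$compression_channels)) {
    vapply(spec$blocks, function(b) b$channels, integer(1))
  } else rep(spec$compression_channels, nb)
  offs <- cumsum(c(0L, fpb))
  dblock <- vector("list", nb)  # gradient w.r.t. each block's output
  for (i in seq_len(nb)) {
    dfeat <- dF[, (offs[i] + 1L):offs[i + 1L], drop = FALSE]
    if (is.null(spec$compression_channels)) {
      st <- fwd$store[[sprintf("b%dl%d", i, spec$blocks[[i]]$layers)]]
      dblock[[i]] <- array(dfeat, dim(st$z))
    } else {
      key <- sprintf("comp%d", i)
      st <- fwd$store[[key]]
      dz <- array(dfeat, dim(st$z)) * (st$z > 0)
      res <- .conv_bwd(st$x, dim(st$x), net$params[[key]]$W, dz,
                       c(1L, 1L, 1L), c(1L, 1L, 1L))
      grads[[key]] <- list(W = res$gW, b = res$gb)
      dblock[[i]] <- res$gx
    }
  }
  g <- dblock[[nb]]
  for (i in rev(seq_len(nb))) {
    b <- spec$blocks[[i]]
    for (l in rev(seq_len(b$layers))) {
      key <- sprintf("b%dl%d", i, l)
      st <- fwd$store[[key]]
      dz <- g * (st$z > 0)
      res <- .conv_bwd(st$x, dim(st$x), net$params[[key]]$W, dz,
                       b$kernel, b$dilation)
      grads[[key]] <- list(W = res$gW, b = res$gb)
      g <- res$gx
    }
    if (i > 1L) g <- g + dblock[[i - 1L]]
  }
  grads
}
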