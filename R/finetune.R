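# Image-specific fine-tuning: alternating exact CRF label updates with
# uncertainty-weighted gradient updates of the classifier block on cached
# concatenation-layer features.

#' Fine-tuning configuration
#'
#' @param rounds number of label-update / network-update alternations
#'   (default 4). `rounds = 0` is the degenerate "initial forward + one CRF
#'   solve" baseline without any network update.
#' @param lr classifier learning rate of the network update (default 1e-2).
#' @param steps gradient steps per network update (default 20).
#' @param momentum optional momentum of the network update (default 0:
#'   plain gradient descent).
#' @param crf a [crf_params()].
#' @param unc an [uncertainty_params()].
#' @param recompute_uncertainty recompute U_p from the current softmax at
#'   every round (default `TRUE`) or freeze the sets of the first round.
#' @param seed integer seed (the update itself is deterministic; the seed
#'   covers any stochastic extension and the reproducibility contract).
#' @return object of class `finetune_config`.
#' @export
finetune_config <- function(rounds = 4L, lr = 1e-2, steps = 20L, momentum = 0,
                            crf = crf_params(), unc = uncertainty_params(),
                            recompute_uncertainty = TRUE, seed = 1L) {
  if (rounds < 0L) stop("input error: rounds must be >= 0", call. = FALSE)
  if (lr <= 0) stop("input error: lr must be > 0", call. = FALSE)
  if (steps < 1L) stop("input error: steps must be >= 1", call. = FALSE)
  structure(list(rounds = as.integer(rounds), lr = lr, steps = as.integer(steps),
                 momentum = momentum, crf = crf, unc = unc,
                 recompute_uncertainty = isTRUE(recompute_uncertainty),
                 seed = as.integer(seed)),
            class = "finetune_config")
}

#' Weighted cross-entropy loss
#'
#' The per-pixel negative log-likelihood of the current labelling under the
#' network's softmax output, weighted by the three-valued weight map and
#' summed (not averaged) over pixels.
#'
#' @param prob foreground probability array (clamped internally).
#' @param labeling binary array of the same shape.
#' @param weights numeric weight array (values in `{0, 1, omega}`).
#' @return the weighted negative log-likelihood (sum over pixels).
#' @export
weighted_loss <- function(prob, labeling, weights) {
  stopifnot(all(dim(prob) == dim(labeling)), all(dim(prob) == dim(weights)))
  p <- clamp01(prob, PROB_EPS)
  y <- as.vector(labeling)
  -sum(as.vector(weights) * (y * log(as.vector(p)) + (1 - y) * log(1 - as.vector(p))))
}

#' Classifier-only network update on cached features
#'
#' Runs `steps` gradient steps on the weighted cross-entropy between the
#' classifier output (computed from the cached concatenation features) and
#' the current labelling. Only the classifier parameters change; gradients
#' are normalized by the pixel count so the learning rate is independent of
#' the crop size. Deterministic given identical inputs.
#'
#' @param net a `boxseg_net`.
#' @param cache a [cache_features()] result built at the current
#'   non-classifier parameters (a stale cache is a state error).
#' @param labeling binary target labelling, cached spatial shape.
#' @param weights weight array from [build_weight_map()].
#' @param lr learning rate.
#' @param steps gradient step count.
#' @param momentum momentum coefficient (0 = plain gradient descent).
#' @return the network with updated classifier parameters; all other
#'   parameters are bit-identical.
#' @export
network_update <- function(net, cache, labeling, weights, lr = 1e-2,
                           steps = 20L, momentum = 0) {
  stopifnot(inherits(cache, "feature_cache"))
  if (!identical(cache$backbone, backbone_checksum(net)))
    stop("state error: feature cache is stale (non-classifier parameters changed)",
         call. = FALSE)
  stopifnot(all(cache$spatial_shape == dim(labeling)),
            all(cache$spatial_shape == dim(weights)))
  FF <- cache$features
  npix <- nrow(FF)
  y <- as.vector(labeling)
  w <- as.vector(weights)
  Y2 <- cbind(1 - y, y, deparse.level = 0)
  W <- net$params$cls$W
  b <- net$params$cls$b
  vW <- W * 0; vb <- b * 0
  for (s in seq_len(steps)) {
    logits <- sweep(FF %*% W, 2, b, "+")
    ez <- exp(logits - apply(logits, 1, max))
    P2 <- ez / rowSums(ez)
    G <- (P2 - Y2) * (w / npix)
    gW <- crossprod(FF, G)
    gb <- colSums(G)
    vW <- momentum * vW - lr * gW
    vb <- momentum * vb - lr * gb
    W <- W + vW
    b <- b + vb
  }
  net$params$cls$W <- W
  net$params$cls$b <- b
  net
}

#' Image-specific refinement of a boxed region
#'
#' Starting from the network's initial softmax segmentation of the cropped,
#' normalized and resized region, alternates for `cfg$rounds` rounds:
#' (a) exact graph-cut label update of the scribble-constrained CRF,
#' (b) uncertainty sets and weight map, (c) classifier-only network update
#' on the cached features, (d) refreshed probability from the cache. With an
#' empty scribble set this is unsupervised refinement (no `omega` pixels,
#' zeros only on the network-uncertain set).
#'
#' @param net a trained `boxseg_net`.
#' @param region a prepared [image_region][crop_region()] (normalized, and
#'   resized to the network input convention).
#' @param scribbles a [scribble_set()] in region coordinates, or `NULL`.
#' @param cfg a [finetune_config()].
#' @param reference optional binary reference mask (region shape) for Dice
#'   tracking in the history.
#' @return object of class `segmentation_state`: final `labeling`, final
#'   `prob`, the updated `net`, the feature `cache` and a per-round
#'   `history` data frame (energy before/after each label update, loss,
#'   Dice when a reference is given).
#' @export
refine <- function(net, region, scribbles = NULL, cfg = finetune_config(),
                   reference = NULL) {
  x <- region_intensities(region)
  if (!empty_scribbles(scribbles)) {
    idx <- scribble_indices(scribbles)
    if (min(idx) < 1L || max(idx) > length(x))
      stop("input error: scribbles outside the region", call. = FALSE)
  }
  set.seed(cfg$seed)
  cache <- cache_features(net, region)
  prob <- classifier_forward(net, cache)
  labeling <- array(as.integer(prob > 0.5), dim(x))
  init_labeling <- labeling
  up <- us <- NULL
  hist <- list()
  if (cfg$rounds == 0L) {
    labeling <- solve_labels(prob, x, scribbles, cfg$crf)
  } else {
    for (r in seq_len(cfg$rounds)) {
      e_before <- crf_energy(labeling, prob, x, scribbles, cfg$crf)
      labeling <- solve_labels(prob, x, scribbles, cfg$crf)
      e_after <- crf_energy(labeling, prob, x, scribbles, cfg$crf)
      if (cfg$recompute_uncertainty || is.null(up)) {
        up <- network_uncertainty(prob, cfg$unc$t0, cfg$unc$t1)
        us <- scribble_uncertainty(x, scribbles, labeling,
                                   epsilon = cfg$unc$epsilon, gamma = cfg$unc$gamma)
      }
      w <- build_weight_map(scribbles, up, us, omega = cfg$unc$omega)
      net <- network_update(net, cache, labeling, w,
                            lr = cfg$lr, steps = cfg$steps, momentum = cfg$momentum)
      prob <- classifier_forward(net, cache)
      hist[[r]] <- data.frame(
        round = r, energy_before = e_before, energy_after = e_after,
        loss = weighted_loss(prob, labeling, w),
        scribbles_satisfied = empty_scribbles(scribbles) ||
          (all(labeling[scribbles$fg] == 1L) && all(labeling[scribbles$bg] == 0L)),
        dice = if (is.null(reference)) NA_real_ else dice_score(labeling, reference))
    }
  }
  structure(list(labeling = labeling, prob = prob, net = net, cache = cache,
                 initial_labeling = init_labeling,
                 history = if (length(hist)) do.call(rbind, hist) else
                   data.frame(round = integer(0))),
            class = "segmentation_state")
}

#' @export
print.segmentation_state <- function(x, ...) {
  cat(sprintf("<segmentation_state> %s, %d foreground pixels, %d rounds\n",
              paste(dim(x$labeling), collapse = "x"), sum(x$labeling),
              nrow(x$history)))
  invisible(x)
}

#' Calibrate the pairwise weight on validation instances
#'
#' Application-specific refinement hyperparameters are fixed by a grid
#' search on training-side data (validation instances of the classes seen
#' in training; held-out classes are never consulted). This calibrates the
#' pairwise weight `lambda` — the one term whose scale depends on the
#' application's boundary statistics — by maximizing the mean Dice of
#' unsupervised refinement over a decade-spanning grid; the remaining
#' profile parameters are taken from `cfg`.
#'
#' @param net a trained `boxseg_net`.
#' @param instances prepared validation `training_instance`s with masks,
#'   drawn from the classes used in training.
#' @param grid candidate `lambda` values.
#' @param cfg base [finetune_config()].
#' @return the config with the calibrated `lambda`; the per-candidate mean
#'   Dice table is attached as attribute `"calibration"`.
#' @export
calibrate_lambda <- function(net, instances, grid = c(1, 3, 10),
                             cfg = finetune_config()) {
  stopifnot(length(instances) > 0, length(grid) > 0)
  scores <- vapply(grid, function(lam) {
    c2 <- cfg
    c2$crf$lambda <- lam
    mean(vapply(instances, function(inst) {
      dice_score(refine(net, inst$region, NULL, c2)$labeling, inst$mask)
    }, numeric(1)))
  }, numeric(1))
  cfg$crf$lambda <- grid[which.max(scores)]
  attr(cfg, "calibration") <- data.frame(lambda = grid, dice = scores)
  cfg
}

#' Segment one object from a bounding box (end-to-end)
#'
#' Crops the box, normalizes and resizes the region, maps any scribbles
#' into the resized crop, runs [refine()], and restores the final labelling
#' to source-image coordinates.
#'
#' @param net a trained `boxseg_net`.
#' @param image full 2D matrix or 3D array.
#' @param box a [bounding_box()] inside the image.
#' @param scribbles optional list with full-image logical masks `fg` and/or
#'   `bg`; every scribble pixel must lie inside the box.
#' @param cfg a [finetune_config()].
#' @param target resize target passed to [resize_for_network()].
#' @return full-image binary labelling (integer array); the final
#'   `segmentation_state` is attached as attribute `"state"`.
#' @export
segment_box <- function(net, image, box, scribbles = NULL,
                        cfg = finetune_config(), target = NULL) {
  region <- crop_region(image, box)
  region <- normalize_region(region)
  region <- resize_for_network(region, target = target)
  scr <- scribbles
  if (!is.null(scribbles) && !inherits(scribbles, "scribble_set")) {
    fg <- map_mask_to_region(scribbles$fg, region)
    bg <- map_mask_to_region(scribbles$bg, region)
    dup <- intersect(fg, bg)   # collisions from downscaling
    scr <- scribble_set(setdiff(fg, dup), setdiff(bg, dup),
                        shape = dim(region$intensities))
  }
  st <- refine(net, region, scr, cfg)
  out <- restore_to_source(st$labeling, region, "mask")
  storage.mode(out) <- "integer"
  attr(out, "state") <- st
  out
}

# Map a full-image scribble mask into (resized) region linear indices.
map_mask_to_region <- function(mask, region) {
  if (is.null(mask) || !any(mask != 0)) return(integer(0))
  box <- region$original_box
  idx <- which(mask != 0, arr.ind = TRUE)
  crop_coord <- sweep(idx, 2, box$lo, "-")        # 1-based within the crop
  if (any(crop_coord < 1) || any(sweep(crop_coord, 2, box_shape(box), ">")))
    stop("input error: scribbles outside the bounding box", call. = FALSE)
  if (!is.null(region$resize)) {
    scale <- region$resize$new_shape / region$resize$orig_shape
    crop_coord <- pmax(1L, pmin(
      matrix(rep(region$resize$new_shape, each = nrow(crop_coord)),
             nrow = nrow(crop_coord)),
      round(sweep(crop_coord - 0.5, 2, scale, "*") + 0.5)))
  }
  shape <- dim(region$intensities)
  mult <- cumprod(c(1, shape[-length(shape)]))
  unique(as.integer(1 + (crop_coord - 1) %*% mult))
}
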