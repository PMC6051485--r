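# Training of the bounding-box binary segmentation network on cropped
# instances with cross-entropy loss.

#' Training configuration
#'
#' Defaults are desk-scale (2000 iterations, compact widths); the original
#' cluster-scale settings (80k iterations, learning rate halved every 5k)
#' are available as the `"original"` profile.
#'
#' @param batch_size instances per gradient step (default 1).
#' @param momentum SGD momentum (default 0.9).
#' @param weight_decay L2 penalty coefficient (default 5e-4).
#' @param max_iterations gradient steps (desk default 2000).
#' @param initial_lr initial learning rate (default 1e-3).
#' @param lr_halving_interval iterations between learning-rate halvings
#'   (default 5000).
#' @param margin_range random bounding-box margin range used at instance
#'   extraction (recorded here; default 0 to 10).
#' @param val_interval iterations between validation-loss evaluations.
#' @param seed integer seed controlling initialization-independent
#'   stochasticity (instance order).
#' @param profile `"compact"` or `"original"`.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 1L, momentum = 0.9, weight_decay = 5e-4,
                         max_iterations = 2000L, initial_lr = 1e-3,
                         lr_halving_interval = 5000L, margin_range = c(0L, 10L),
                         val_interval = 100L, seed = 1L,
                         profile = c("compact", "original")) {
  profile <- match.arg(profile)
  if (profile == "original") max_iterations <- 80000L
  stopifnot(batch_size >= 1, momentum >= 0, weight_decay >= 0,
            max_iterations >= 1, initial_lr > 0, lr_halving_interval >= 1)
  structure(list(batch_size = as.integer(batch_size), momentum = momentum,
                 weight_decay = weight_decay,
                 max_iterations = as.integer(max_iterations),
                 initial_lr = initial_lr,
                 lr_halving_interval = as.integer(lr_halving_interval),
                 margin_range = margin_range,
                 val_interval = as.integer(val_interval),
                 seed = as.integer(seed), profile = profile),
            class = "train_config")
}

#' Learning rate at a given iteration
#'
#' The initial learning rate halved every `lr_halving_interval` iterations:
#' iterations 1..k keep the initial rate and iteration k+1 uses half of it.
#'
#' @param iter 1-based iteration number.
#' @param cfg a [train_config()].
#' @return learning rate.
#' @export
lr_at <- function(iter, cfg) {
  cfg$initial_lr * 0.5^((iter - 1) %/% cfg$lr_halving_interval)
}

# Mean cross-entropy of a forward result against a binary mask, plus the
# d(loss)/d(logits) matrix for backprop.
ce_loss_grad <- function(fwd, mask) {
  npix <- nrow(fwd$logits)
  y <- as.vector(mask)
  Y2 <- cbind(1 - y, y, deparse.level = 0)
  lg <- fwd$logits
  ez <- exp(lg - apply(lg, 1, max))
  P2 <- ez / rowSums(ez)
  P2c <- pmin(pmax(P2, PROB_EPS), 1 - PROB_EPS)
  loss <- -mean(rowSums(Y2 * log(P2c)))
  list(loss = loss, dlogits = (P2 - Y2) / npix)
}

#' Train the segmentation network on cropped binary instances
#'
#' Stochastic gradient descent with momentum, weight decay and a halving
#' learning-rate schedule on the per-pixel cross-entropy (averaged over
#' pixels). Instances must already be preprocessed with [prep_instance()]
#' (normalized and resized). Deterministic given the config seed.
#'
#' @param net a `boxseg_net` (its current parameters are the starting
#'   point).
#' @param instances nonempty list of prepared `training_instance`s.
#' @param cfg a [train_config()].
#' @param val_instances optional prepared instances for periodic
#'   validation-loss logging.
#' @return list with the trained `net`, a `loss` data frame (iteration,
#'   loss, lr) and a `val` data frame (iteration, loss).
#' @export
train_network <- function(net, instances, cfg = train_config(),
                          val_instances = NULL) {
  if (length(instances) == 0L)
    stop("input error: empty training set", call. = FALSE)
  set.seed(cfg$seed)
  vel <- lapply(net$params, function(p) list(W = p$W * 0, b = p$b * 0))
  loss_log <- numeric(cfg$max_iterations)
  lr_log <- numeric(cfg$max_iterations)
  val_log <- list()
  order_pool <- integer(0)
  for (it in seq_len(cfg$max_iterations)) {
    lr <- lr_at(it, cfg)
    grads_acc <- NULL
    loss_acc <- 0
    for (bi in seq_len(cfg$batch_size)) {
      if (length(order_pool) == 0L) order_pool <- sample(seq_along(instances))
      inst <- instances[[order_pool[1L]]]
      order_pool <- order_pool[-1L]
      fwd <- net_forward(net, inst$region, keep = TRUE)
      lg <- ce_loss_grad(fwd, inst$mask)
      loss_acc <- loss_acc + lg$loss
      g <- net_backward(net, fwd, lg$dlogits)
      grads_acc <- if (is.null(grads_acc)) g else
        mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
               grads_acc, g, SIMPLIFY = FALSE)
    }
    loss_log[it] <- loss_acc / cfg$batch_size
    lr_log[it] <- lr
    for (nm in names(net$params)) {
      gW <- grads_acc[[nm]]$W / cfg$batch_size + cfg$weight_decay * net$params[[nm]]$W
      gb <- grads_acc[[nm]]$b / cfg$batch_size
      vel[[nm]]$W <- cfg$momentum * vel[[nm]]$W - lr * gW
      vel[[nm]]$b <- cfg$momentum * vel[[nm]]$b - lr * gb
      net$params[[nm]]$W <- net$params[[nm]]$W + vel[[nm]]$W
      net$params[[nm]]$b <- net$params[[nm]]$b + vel[[nm]]$b
    }
    if (!is.null(val_instances) && it %% cfg$val_interval == 0L) {
      vl <- mean(vapply(val_instances, function(vi) {
        ce_loss_grad(net_forward(net, vi$region), vi$mask)$loss
      }, numeric(1)))
      val_log[[length(val_log) + 1L]] <- data.frame(iteration = it, loss = vl)
    }
  }
  list(net = net,
       loss = data.frame(iteration = seq_len(cfg$max_iterations),
                         loss = loss_log, lr = lr_log),
       val = if (length(val_log)) do.call(rbind, val_log) else
         data.frame(iteration = integer(0), loss = numeric(0)))
}

#' Dice overlap between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks score 1.
#'
#' @param a,b binary (or logical) arrays of equal shape.
#' @return Dice score in `[0, 1]`.
#' @export
dice_score <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

#' Evaluate a network on prepared instances
#'
#' Forward pass per instance, thresholded at 0.5, scored with
#' [dice_score()] against the instance mask.
#'
#' @param net a `boxseg_net`.
#' @param instances list of prepared `training_instance`s with reference
#'   masks.
#' @return data frame with one row per instance (`instance`, `class`,
#'   `dice`) plus a `"class_means"` attribute (mean Dice per class label).
#' @export
evaluate_instances <- function(net, instances) {
  res <- data.frame(
    instance = seq_along(instances),
    class = vapply(instances, function(i) as.integer(i$label), integer(1)),
    dice = vapply(instances, function(i) {
      p <- forward_probability(net, i$region)
      dice_score(p > 0.5, i$mask)
    }, numeric(1)))
  attr(res, "class_means") <- tapply(res$dice, res$class, mean)
  res
}
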