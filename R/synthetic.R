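# Synthetic multi-organ scenes and a robot user. The generator emulates the
# premise that different object classes share saliency, contrast and
# hyper-intensity against the background while differing in geometry and
# texture, so a subset of classes can be held out as previously unseen
# objects for zero-shot evaluation.

#' Default synthetic class catalog
#'
#' Four bright (hyper-intense) object classes sharing contrast against the
#' background but differing in geometry and texture: smooth ellipses and
#' fuzzy round blobs (the conventional "seen" pair) plus lobed multi-ellipse
#' shapes and strongly bumpy blobs (the conventional "unseen" pair).
#'
#' @param dims 2 or 3.
#' @return list of class descriptors (name, shape family, intensity offset,
#'   texture noise sd, instance count range, size range).
#' @export
default_catalog <- function(dims = 2L) {
  base <- list(
    list(name = "ellipse", family = "ellipse", offset = 0.45, texture_sd = 0.02,
         count = c(0L, 2L), size = c(10, 20)),
    list(name = "blob",    family = "blob",    offset = 0.35, texture_sd = 0.04,
         count = c(0L, 2L), size = c(11, 22)),
    list(name = "lobed",   family = "lobed",   offset = 0.40, texture_sd = 0.03,
         count = c(0L, 2L), size = c(9, 16)),
    list(name = "bumpy",   family = "bumpy",   offset = 0.50, texture_sd = 0.05,
         count = c(0L, 2L), size = c(10, 18)))
  if (dims == 3L) {
    base <- lapply(base, function(cl) { cl$size <- c(6, 11); cl })
  }
  base
}

#' Synthetic scene specification
#'
#' @param shape image shape (length 2 or 3; default 128 x 128).
#' @param classes class catalog ([default_catalog()] by default). Intensity
#'   offsets must be nonzero: objects are salient against the background.
#' @param background list with `level` (base intensity, default 0.3),
#'   `noise_sd` (additive Gaussian noise, default 0.05) and `bias_field`
#'   (logical; smooth multiplicative field, default `FALSE`).
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(128L, 128L), classes = NULL,
                       background = list()) {
  shape <- as.integer(shape)
  stopifnot(length(shape) %in% 2:3)
  classes <- classes %||% default_catalog(length(shape))
  if (any(vapply(classes, function(cl) cl$offset == 0, logical(1))))
    stop("scene spec invalid: class intensity offsets must be nonzero", call. = FALSE)
  background <- modifyList(list(level = 0.3, noise_sd = 0.05, bias_field = FALSE),
                           background)
  structure(list(shape = shape, classes = classes, background = background),
            class = "scene_spec")
}

# One randomly-parameterized shape mask of a given family, centred at `ctr`.
shape_mask <- function(family, shape, ctr, size) {
  nd <- length(shape)
  grids <- lapply(seq_len(nd), function(a) seq_len(shape[a]) - ctr[a])
  if (nd == 2L) {
    dx <- matrix(grids[[1]], shape[1], shape[2])
    dy <- matrix(grids[[2]], shape[1], shape[2], byrow = TRUE)
    ang <- runif(1, 0, pi)
    rx <- dx * cos(ang) + dy * sin(ang)
    ry <- -dx * sin(ang) + dy * cos(ang)
    if (family == "ellipse") {
      b <- size * runif(1, 0.5, 0.9)
      return((rx / size)^2 + (ry / b)^2 <= 1)
    }
    th <- atan2(ry, rx)
    rr <- sqrt(rx^2 + ry^2)
    if (family == "blob") {
      amp <- runif(3, 0, 0.15); ph <- runif(3, 0, 2 * pi)
      rad <- size * (1 + amp[1] * cos(2 * th + ph[1]) +
                       amp[2] * cos(3 * th + ph[2]) + amp[3] * cos(4 * th + ph[3]))
      return(rr <= rad)
    }
    if (family == "bumpy") {
      amp <- runif(3, 0.1, 0.3); ph <- runif(3, 0, 2 * pi)
      rad <- size * (1 + amp[1] * cos(3 * th + ph[1]) +
                       amp[2] * cos(5 * th + ph[2]) + amp[3] * cos(6 * th + ph[3]))
      return(rr <= pmax(rad, size * 0.3))
    }
    if (family == "lobed") {
      m <- array(FALSE, shape)
      nlobe <- sample(2:3, 1)
      for (l in seq_len(nlobe)) {
        off <- runif(2, -0.6, 0.6) * size
        a <- size * runif(1, 0.6, 0.9); b <- a * runif(1, 0.5, 0.9)
        al <- runif(1, 0, pi)
        lx <- (dx - off[1]) * cos(al) + (dy - off[2]) * sin(al)
        ly <- -(dx - off[1]) * sin(al) + (dy - off[2]) * cos(al)
        m <- m | ((lx / a)^2 + (ly / b)^2 <= 1)
      }
      return(m)
    }
    stop("unknown shape family: ", family, call. = FALSE)
  }
  # 3D: ellipsoidal base with family-specific angular modulation
  dx <- array(grids[[1]], shape)
  dy <- array(rep(grids[[2]], each = shape[1]), shape)
  dz <- array(rep(grids[[3]], each = shape[1] * shape[2]), shape)
  ax <- c(size, size * runif(1, 0.6, 0.9), size * runif(1, 0.5, 0.8))
  rr <- sqrt((dx / ax[1])^2 + (dy / ax[2])^2 + (dz / ax[3])^2)
  if (family == "ellipse") return(rr <= 1)
  th <- atan2(dy, dx)
  mod <- switch(family,
    blob  = { amp <- runif(2, 0, 0.15); ph <- runif(2, 0, 2 * pi)
              1 + amp[1] * cos(2 * th + ph[1]) + amp[2] * cos(3 * th + ph[2]) },
    bumpy = { amp <- runif(2, 0.1, 0.3); ph <- runif(2, 0, 2 * pi)
              1 + amp[1] * cos(3 * th + ph[1]) + amp[2] * cos(5 * th + ph[2]) },
    lobed = { amp <- runif(1, 0.2, 0.35); ph <- runif(1, 0, 2 * pi)
              1 + amp * cos(2 * th + ph) },
    stop("unknown shape family: ", family, call. = FALSE))
  rr <= mod
}

# Dilate a mask by one pixel (4/6-connectivity) via axis shifts.
grow_mask <- function(m) {
  v <- as_volume(m)
  d <- dim(v)
  out <- v
  if (d[1] > 1L) {
    out[-1, , ] <- out[-1, , ] | v[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | v[-1, , ]
  }
  if (d[2] > 1L) {
    out[, -1, ] <- out[, -1, ] | v[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | v[, -1, ]
  }
  if (d[3] > 1L) {
    out[, , -1] <- out[, , -1] | v[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | v[, , -1]
  }
  array(out, dim(m))
}

#' Generate one synthetic labelled scene
#'
#' Places non-overlapping (and non-touching) instances of each catalog class
#' on a noisy background. Object pixels take `background$level + offset`
#' exactly before any noise, so with all noise terms zero the
#' object/background contrast equals the class offset. Deterministic given
#' `seed`.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed.
#' @return list with `image` (numeric array), `labels` (integer array; the
#'   catalog index of each class, 0 background) and `instances` (per
#'   instance: class index/name, pixel count).
#' @export
generate_scene <- function(spec, seed = 1L) {
  set.seed(seed)
  shape <- spec$shape
  labels <- array(0L, shape)
  occupied <- array(FALSE, shape)
  instances <- list()
  for (ci in seq_along(spec$classes)) {
    cl <- spec$classes[[ci]]
    n <- sample(cl$count[1]:cl$count[2], 1)
    placed <- 0L
    tries <- 0L
    while (placed < n && tries < 50L) {
      tries <- tries + 1L
      size <- runif(1, cl$size[1], cl$size[2])
      margin <- ceiling(size * 1.8) + 2
      if (any(shape < 2 * margin)) break
      ctr <- vapply(shape, function(s) runif(1, margin, s - margin), numeric(1))
      m <- shape_mask(cl$family, shape, ctr, size)
      if (sum(m) < 12 || any(occupied & grow_mask(m))) next
      labels[m] <- ci
      occupied <- occupied | grow_mask(m)
      placed <- placed + 1L
      instances[[length(instances) + 1L]] <-
        list(class = ci, name = cl$name, pixels = sum(m))
    }
  }
  image <- array(spec$background$level, shape)
  for (ci in seq_along(spec$classes)) {
    sel <- labels == ci
    if (any(sel)) {
      cl <- spec$classes[[ci]]
      image[sel] <- spec$background$level + cl$offset +
        rnorm(sum(sel), sd = cl$texture_sd)
    }
  }
  if (isTRUE(spec$background$bias_field)) {
    g <- lapply(seq_along(shape), function(a) {
      ph <- runif(1, 0, 2 * pi)
      1 + 0.1 * sin(2 * pi * (seq_len(shape[a]) / shape[a]) + ph)
    })
    field <- Reduce(`%o%`, g)
    image <- image * field
  }
  if (spec$background$noise_sd > 0) {
    image <- image + rnorm(length(image), sd = spec$background$noise_sd)
  }
  list(image = image, labels = labels, instances = instances)
}

#' Build a seen/unseen benchmark bundle
#'
#' Generates seeded scenes and extracts cropped binary instances; training
#' instances are drawn only from the `seen` classes while test instances
#' cover all catalog classes and are tagged seen/unseen. Training and test
#' scenes come from disjoint seed streams. Instances are preprocessed
#' (normalized, resized) when `prep = TRUE`.
#'
#' @param seen,unseen disjoint character vectors of catalog class names.
#' @param n_train total number of training instances.
#' @param n_test total number of test instances (balanced over classes).
#' @param n_val number of seen-class validation instances (for logging
#'   validation loss and calibrating refinement hyperparameters without
#'   touching held-out classes; see [calibrate_lambda()]).
#' @param seed integer seed for the whole bundle.
#' @param spec a [scene_spec()].
#' @param prep preprocess instances for the network (default `TRUE`).
#' @param target resize target passed to [prep_instance()].
#' @return list with `train`, `val`, `test` (instance lists; each test
#'   instance carries `$seen`), `seen`, `unseen` and the `spec`.
#' @export
make_benchmark <- function(seen = c("ellipse", "blob"),
                           unseen = c("lobed", "bumpy"),
                           n_train = 200L, n_test = 40L, n_val = 0L, seed = 1L,
                           spec = scene_spec(), prep = TRUE, target = NULL) {
  if (length(intersect(seen, unseen)))
    stop("input error: seen and unseen classes must be disjoint", call. = FALSE)
  names_all <- vapply(spec$classes, function(cl) cl$name, character(1))
  stopifnot(all(c(seen, unseen) %in% names_all))
  collect <- function(wanted, n_total, salt, quota = NULL) {
    out <- list()
    per_class <- setNames(rep(0L, length(wanted)), wanted)
    seeds <- child_seeds(seed, 10000L, salt)
    si <- 0L
    while (length(out) < n_total && si < 10000L) {
      si <- si + 1L
      sc <- generate_scene(spec, seed = seeds[si])
      inst <- extract_instances(sc$image, sc$labels, image_id = si)
      for (ins in inst) {
        nm <- names_all[ins$label]
        if (!nm %in% wanted) next
        if (!is.null(quota) && per_class[nm] >= quota) next
        if (length(out) >= n_total) break
        ins$class_name <- nm
        ins$seen <- nm %in% seen
        out[[length(out) + 1L]] <- ins
        per_class[nm] <- per_class[nm] + 1L
      }
    }
    out
  }
  train <- collect(seen, n_train, salt = 1L)
  test <- collect(c(seen, unseen), n_test, salt = 2L,
                  quota = ceiling(n_test / length(c(seen, unseen))))
  val <- if (n_val > 0L) collect(seen, n_val, salt = 3L) else list()
  if (prep) {
    train <- lapply(train, prep_instance, target = target)
    test <- lapply(test, prep_instance, target = target)
    val <- lapply(val, prep_instance, target = target)
  }
  list(train = train, val = val, test = test, seen = seen, unseen = unseen,
       spec = spec)
}

#' Robot-user scribble policy
#'
#' @param max_length maximum scribble length in pixels (default 8).
#' @param per_round number of mis-segmented components scribbled per error
#'   type and round (default 1: the largest).
#' @param seed integer seed (the default policy is deterministic; the seed
#'   is part of the reproducibility contract).
#' @return object of class `robot_user_policy`.
#' @export
robot_user_policy <- function(max_length = 8L, per_round = 1L, seed = 1L) {
  structure(list(max_length = as.integer(max_length),
                 per_round = as.integer(per_round), seed = as.integer(seed)),
            class = "robot_user_policy")
}

# A short axis-aligned segment through the median row of a component:
# always a subset of the component, hence of the mis-segmented set.
component_segment <- function(coords, max_length) {
  nd <- ncol(coords)
  sel <- coords
  if (nd == 3L) {
    mk <- sort(sel[, 3])[ceiling(nrow(sel) / 2)]
    sel <- sel[sel[, 3] == mk, , drop = FALSE]
  }
  mi <- sort(sel[, 1])[ceiling(nrow(sel) / 2)]
  sel <- sel[sel[, 1] == mi, , drop = FALSE]
  sel <- sel[order(sel[, 2]), , drop = FALSE]
  if (nrow(sel) > max_length) {
    start <- (nrow(sel) - max_length) %/% 2
    sel <- sel[(start + 1):(start + max_length), , drop = FALSE]
  }
  sel
}

#' Simulated corrective scribbles from a robot user
#'
#' Mimics a user who draws short scribbles only inside mis-segmented areas:
#' foreground scribbles on the largest false-negative components and
#' background scribbles on the largest false-positive components. Returns an
#' empty set when the prediction equals the truth. Deterministic.
#'
#' @param pred current binary labelling.
#' @param truth reference binary mask, same shape.
#' @param policy a [robot_user_policy()].
#' @return a [scribble_set()] whose pixels are all verified mis-segmented.
#' @export
robot_scribbles <- function(pred, truth, policy = robot_user_policy()) {
  stopifnot(all(dim(pred) == dim(truth)))
  pick <- function(err_mask) {
    if (!any(err_mask)) return(integer(0))
    vol <- as_volume(err_mask)
    comp <- array(.label_components_cpp(vol, dim(vol)), dim(err_mask))
    sizes <- tabulate(comp[comp > 0])
    top <- order(sizes, decreasing = TRUE)[seq_len(min(policy$per_round, length(sizes)))]
    idx <- integer(0)
    shape <- dim(err_mask)
    mult <- cumprod(c(1, shape[-length(shape)]))
    for (k in top) {
      coords <- which(comp == k, arr.ind = TRUE)
      seg <- component_segment(coords, policy$max_length)
      idx <- c(idx, as.integer(1 + (seg - 1) %*% mult))
    }
    idx
  }
  scribble_set(fg = pick(truth != 0 & pred == 0),
               bg = pick(truth == 0 & pred != 0),
               shape = dim(pred))
}
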