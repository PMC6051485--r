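# Binary CRF over the cropped region: unary terms from the network's
# softmax output, contrast-sensitive pairwise terms, optional hard scribble
# constraints. The pairwise term is submodular, so the label update is an
# exact global minimization by max-flow/min-cut.

PROB_EPS <- 1e-6   # probability clamp before logs
TIE_EPS  <- 1e-9   # deterministic tie-break: p = 0.5, lambda = 0 -> background

#' CRF parameters
#'
#' @param lambda nonnegative weight of the pairwise (smoothness) term.
#'   Application profiles from grid search: 3.0 for the 2D organ profile,
#'   10.0 for the 3D tumour profile.
#' @param sigma positive intensity-contrast scale, in normalized-intensity
#'   units (both profiles use 0.1).
#' @return object of class `crf_params`. The neighbourhood system is
#'   4-connectivity in 2D and 6-connectivity in 3D with unit neighbour
#'   distance.
#' @export
crf_params <- function(lambda = 3.0, sigma = 0.1) {
  if (lambda < 0) stop("input error: lambda must be >= 0", call. = FALSE)
  if (sigma <= 0) stop("input error: sigma must be > 0", call. = FALSE)
  structure(list(lambda = lambda, sigma = sigma), class = "crf_params")
}

#' Foreground/background scribble sets
#'
#' Scribbles are hard user constraints: pixels in `fg` must be labelled 1
#' and pixels in `bg` must be labelled 0 by every label update.
#'
#' @param fg,bg integer vectors of 1-based linear pixel indices within the
#'   region (either may be empty).
#' @param shape optional region shape for bounds checking.
#' @return object of class `scribble_set`.
#' @export
scribble_set <- function(fg = integer(0), bg = integer(0), shape = NULL) {
  fg <- as.integer(fg); bg <- as.integer(bg)
  if (length(intersect(fg, bg)) > 0)
    stop("input error: foreground and background scribbles overlap", call. = FALSE)
  if (!is.null(shape)) {
    n <- prod(shape)
    if (length(c(fg, bg)) && (min(c(fg, bg)) < 1L || max(c(fg, bg)) > n))
      stop("input error: scribble indices fall outside the region", call. = FALSE)
  }
  structure(list(fg = fg, bg = bg), class = "scribble_set")
}

#' Build scribbles from foreground/background masks
#'
#' @param fg_mask,bg_mask logical arrays of the region shape (or `NULL`).
#' @return a [scribble_set()].
#' @export
scribbles_from_masks <- function(fg_mask = NULL, bg_mask = NULL) {
  scribble_set(fg = if (is.null(fg_mask)) integer(0) else which(fg_mask != 0),
               bg = if (is.null(bg_mask)) integer(0) else which(bg_mask != 0))
}

empty_scribbles <- function(s) is.null(s) || (length(s$fg) + length(s$bg)) == 0L

scribble_indices <- function(s) if (is.null(s)) integer(0) else c(s$fg, s$bg)

#' Contrast-sensitive pairwise potential
#'
#' Zero when the two labels agree; otherwise
#' `exp(-(xi - xj)^2 / (2 sigma^2)) / dij`, so label changes are cheap
#' across strong intensity edges and expensive inside homogeneous regions.
#'
#' @param xi,xj (normalized) intensities of the two neighbouring pixels.
#' @param yi,yj binary labels.
#' @param dij positive Euclidean distance between the pixels.
#' @param sigma intensity-contrast scale.
#' @return nonnegative potential value.
#' @export
pairwise_term <- function(xi, xj, yi, yj, dij = 1, sigma = 0.1) {
  if (any(dij <= 0)) stop("input error: dij must be > 0", call. = FALSE)
  (yi != yj) * exp(-(xi - xj)^2 / (2 * sigma^2)) / dij
}

#' Unary potential from the softmax foreground probability
#'
#' `-log p` for a foreground label, `-log(1 - p)` for background, with `p`
#' clamped to `[1e-6, 1 - 1e-6]` before the logarithm.
#'
#' @param p_i foreground probability in `[0, 1]`.
#' @param y_i binary label.
#' @return nonnegative cost.
#' @export
unary_term <- function(p_i, y_i) {
  p <- clamp01(p_i, PROB_EPS)
  -(y_i * log(p) + (1 - y_i) * log(1 - p))
}

# Finite stand-in for +Inf: strictly larger than any achievable finite
# energy of the instance.
large_constant <- function(prob, params, n_pairs) {
  p <- clamp01(prob, PROB_EPS)
  sum(-log(p)) + sum(-log(1 - p)) + params$lambda * n_pairs + 1
}

#' Scribble-constrained unary potential
#'
#' For scribble pixels the label agreeing with the scribble costs 0 and the
#' disagreeing label costs a finite LARGE constant exceeding any achievable
#' energy, so every minimizer satisfies the constraints; other pixels fall
#' back to [unary_term()].
#'
#' @inheritParams unary_term
#' @param scribbles a [scribble_set()] (or `NULL`).
#' @param i 1-based linear pixel index.
#' @param large the LARGE constant (see [crf_energy()] for its derivation).
#' @return extended-real cost.
#' @export
constrained_unary <- function(p_i, y_i, scribbles, i, large = 1e9) {
  if (!empty_scribbles(scribbles)) {
    if (i %in% scribbles$fg) return(if (y_i == 1) 0 else large)
    if (i %in% scribbles$bg) return(if (y_i == 0) 0 else large)
  }
  unary_term(p_i, y_i)
}

# 4/6-connected neighbour pairs (each unordered pair once) with the pairwise
# exp coefficient for the region's normalized intensities.
neighbor_pairs <- function(x, sigma) {
  vol <- as_volume(x)
  d <- dim(vol)
  idx <- array(seq_len(prod(d)), d)
  pair_i <- integer(0); pair_j <- integer(0)
  if (d[1] > 1L) {
    pair_i <- c(pair_i, as.vector(idx[-d[1], , , drop = FALSE]))
    pair_j <- c(pair_j, as.vector(idx[-1L, , , drop = FALSE]))
  }
  if (d[2] > 1L) {
    pair_i <- c(pair_i, as.vector(idx[, -d[2], , drop = FALSE]))
    pair_j <- c(pair_j, as.vector(idx[, -1L, , drop = FALSE]))
  }
  if (d[3] > 1L) {
    pair_i <- c(pair_i, as.vector(idx[, , -d[3], drop = FALSE]))
    pair_j <- c(pair_j, as.vector(idx[, , -1L, drop = FALSE]))
  }
  coef <- exp(-(vol[pair_i] - vol[pair_j])^2 / (2 * sigma^2))
  list(i = pair_i, j = pair_j, coef = coef)
}

crf_unaries <- function(prob, scribbles, large) {
  p <- clamp01(as.vector(prob), PROB_EPS)
  u0 <- -log(1 - p)
  u1 <- -log(p)
  if (!empty_scribbles(scribbles)) {
    u1[scribbles$fg] <- 0;     u0[scribbles$fg] <- large
    u0[scribbles$bg] <- 0;     u1[scribbles$bg] <- large
  }
  list(u0 = u0, u1 = u1)
}

#' Total CRF energy of a labelling
#'
#' Sum of scribble-constrained unaries and `lambda` times the pairwise
#' potentials over the 4/6-connected neighbourhood (each unordered pair
#' counted once). Scribble violations contribute a LARGE constant equal to
#' the sum of all clamped unaries plus `lambda` times the number of
#' neighbour pairs plus one, which no constraint-satisfying labelling can
#' reach.
#'
#' @param labeling binary array, region shape.
#' @param prob foreground probability array.
#' @param region `image_region` or normalized intensity array.
#' @param scribbles a [scribble_set()] or `NULL`.
#' @param params a [crf_params()].
#' @return total energy (finite real).
#' @export
crf_energy <- function(labeling, prob, region, scribbles = NULL, params = crf_params()) {
  x <- region_intensities(region)
  stopifnot(all(dim(labeling) == dim(x)), all(dim(prob) == dim(x)))
  nb <- neighbor_pairs(x, params$sigma)
  large <- large_constant(prob, params, length(nb$coef))
  u <- crf_unaries(prob, scribbles, large)
  y <- as.vector(labeling)
  sum(ifelse(y == 1, u$u1, u$u0)) +
    params$lambda * sum(nb$coef * (y[nb$i] != y[nb$j]))
}

#' Exact CRF label update by max-flow/min-cut
#'
#' Minimizes the scribble-constrained CRF energy globally. The pairwise term
#' is submodular, so the two-label problem maps to a minimum s-t cut on the
#' pixel graph, solved exactly. At `lambda = 0` without scribbles the result
#' reduces to per-pixel thresholding of `prob` at 0.5 (ties to background).
#'
#' @inheritParams crf_energy
#' @return binary integer array of the region shape; scribble pixels always
#'   carry their scribble label.
#' @export
solve_labels <- function(prob, region, scribbles = NULL, params = crf_params()) {
  x <- region_intensities(region)
  stopifnot(all(dim(prob) == dim(x)))
  n <- length(prob)
  nb <- neighbor_pairs(x, params$sigma)
  large <- large_constant(prob, params, length(nb$coef))
  u <- crf_unaries(scribbles = scribbles, prob = prob, large = large)
  # infinitesimal foreground penalty on unconstrained pixels: deterministic
  # ties-to-background without measurably changing the energy
  free <- setdiff(seq_len(n), scribble_indices(scribbles))
  u$u1[free] <- u$u1[free] + TIE_EPS

  if (params$lambda == 0 || length(nb$coef) == 0L) {
    y <- as.integer(u$u1 < u$u0)
  } else {
    y <- .graph_cut_cpp(u$u0, u$u1, nb$i - 1L, nb$j - 1L, params$lambda * nb$coef)
  }
  array(y, dim(prob))
}

#' Brute-force CRF minimizer (test oracle)
#'
#' Exhaustively enumerates all labellings of a tiny region (at most 16
#' pixels) and returns one attaining the minimum of the same energy as
#' [crf_energy()]. Intended purely as an independent oracle for
#' [solve_labels()].
#'
#' @inheritParams crf_energy
#' @return binary integer array minimizing the energy.
#' @export
brute_force_solve <- function(prob, region, scribbles = NULL, params = crf_params()) {
  n <- length(prob)
  if (n > 16L) stop("refusing brute force on more than 16 pixels", call. = FALSE)
  x <- region_intensities(region)
  nb <- neighbor_pairs(x, params$sigma)
  large <- large_constant(prob, params, length(nb$coef))
  u <- crf_unaries(prob, scribbles, large)
  m <- 2^n
  labmat <- vapply(seq_len(n), function(b) bitwAnd(0:(m - 1), bitwShiftL(1L, b - 1L)) > 0,
                   logical(m))
  if (n == 1L) labmat <- matrix(labmat, ncol = 1L)
  energies <- labmat %*% u$u1 + (!labmat) %*% u$u0
  for (k in seq_along(nb$coef)) {
    energies <- energies + params$lambda * nb$coef[k] *
      (labmat[, nb$i[k]] != labmat[, nb$j[k]])
  }
  array(as.integer(labmat[which.min(energies), ]), dim(prob))
}
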