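#' Bounding box (0-based, half-open)
#'
#' Boxes use 0-based half-open `[lo, hi)` index ranges on every axis, so a
#' box with `lo = 0, hi = 10` covers the first ten pixels of an axis.
#'
#' @param lo,hi integer vectors of per-axis lower (inclusive) and upper
#'   (exclusive) indices; equal lengths of 2 or 3.
#' @return an object of class `bounding_box`.
#' @export
bounding_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != length(hi) || !length(lo) %in% 2:3)
    stop("input error: lo and hi must both have length 2 or 3", call. = FALSE)
  if (any(hi <= lo))
    stop("input error: bounding box requires lo < hi on every axis", call. = FALSE)
  if (any(lo < 0L))
    stop("input error: bounding box indices are 0-based and must be >= 0", call. = FALSE)
  structure(list(lo = lo, hi = hi), class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box> [%s) x [%s)\n",
              paste(x$lo, collapse = ", "), paste(x$hi, collapse = ", ")))
  invisible(x)
}

box_shape <- function(box) box$hi - box$lo

clip_box <- function(box, shape) {
  bounding_box(pmax(box$lo, 0L), pmin(box$hi, as.integer(shape)))
}

# Tight 0-based half-open box of a logical mask.
tight_box <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask has no foreground", call. = FALSE)
  bounding_box(apply(idx, 2, min) - 1L, apply(idx, 2, max))
}

expand_box <- function(box, lower_margin, upper_margin, shape) {
  clip_box(bounding_box(pmax(box$lo - as.integer(lower_margin), 0L),
                        box$hi + as.integer(upper_margin)), shape)
}

crop_array <- function(x, box) {
  d <- length(dim(x))
  if (d == 2L) {
    x[(box$lo[1] + 1L):box$hi[1], (box$lo[2] + 1L):box$hi[2], drop = FALSE]
  } else {
    x[(box$lo[1] + 1L):box$hi[1], (box$lo[2] + 1L):box$hi[2],
      (box$lo[3] + 1L):box$hi[3], drop = FALSE]
  }
}

#' Crop a region from an image
#'
#' Cuts the sub-array inside `box` and records the source geometry so the
#' result (or any map computed on it) can later be placed back into the
#' full image with [restore_to_source()].
#'
#' @param image numeric matrix (2D) or 3D array.
#' @param box a [bounding_box()] in 0-based half-open source coordinates.
#' @return an object of class `image_region`.
#' @export
crop_region <- function(image, box) {
  shape <- dim(image)
  if (length(shape) != length(box$lo))
    stop("input error: box dimensionality does not match the image", call. = FALSE)
  if (any(box$hi > shape))
    stop("input error: box exceeds image bounds", call. = FALSE)
  structure(list(intensities = crop_array(image, box),
                 original_box = box, source_shape = shape,
                 dims = length(shape),
                 normalization = NULL, resize = NULL),
            class = "image_region")
}

#' @export
print.image_region <- function(x, ...) {
  cat(sprintf("<image_region> %s%s%s\n",
              paste(dim(x$intensities), collapse = "x"),
              if (is.null(x$normalization)) "" else ", normalized",
              if (is.null(x$resize)) "" else sprintf(", resized from %s",
                paste(x$resize$orig_shape, collapse = "x"))))
  invisible(x)
}

as_image_region <- function(x, dims = ndims_of(x)) {
  if (inherits(x, "image_region")) return(x)
  structure(list(intensities = x, original_box = NULL, source_shape = dim(x),
                 dims = dims, normalization = NULL, resize = NULL),
            class = "image_region")
}

#' Convert a labelled image into cropped binary training instances
#'
#' Every connected component of every non-background class becomes one
#' training instance: the instance mask is binarized against the instance's
#' class label, its tight bounding box is expanded per side by an integer
#' margin drawn uniformly from `margin_range`, clipped to the image, and
#' both intensities and mask are cropped to that box.
#'
#' @param image numeric matrix or 3D array of intensities.
#' @param labels integer label map of the same shape, values in `0..K-1`
#'   with 0 = background.
#' @param margin_range inclusive integer range of the random per-side box
#'   margin (default 0 to 10 pixels/voxels).
#' @param margin_sampler optional `function(n)` returning `n` integer
#'   margins; overrides `margin_range` (used to pin margins in tests).
#' @param image_id identifier stored on each instance.
#' @return list of `training_instance` objects, each with elements `region`
#'   (raw cropped intensities), `mask` (binary, >= 1 foreground pixel),
#'   `box`, `label` and `image_id`. All-background label maps give an empty
#'   list.
#' @export
extract_instances <- function(image, labels, margin_range = c(0L, 10L),
                              margin_sampler = NULL, image_id = NULL) {
  stopifnot(identical(dim(image), dim(labels)))
  if (is.null(margin_sampler)) {
    margin_sampler <- function(n) {
      as.integer(floor(runif(n, margin_range[1], margin_range[2] + 1)))
    }
  }
  shape <- dim(image)
  classes <- sort(setdiff(unique(as.vector(labels)), 0L))
  out <- list()
  for (cl in classes) {
    comp <- .label_components_cpp(as_volume(labels == cl), dim(as_volume(labels)))
    comp <- array(comp, dim(labels))
    for (q in seq_len(max(comp))) {
      mask <- comp == q
      tb <- tight_box(mask)
      nd <- length(shape)
      box <- expand_box(tb, margin_sampler(nd), margin_sampler(nd), shape)
      out[[length(out) + 1L]] <- structure(
        list(region = crop_array(image, box),
             mask = crop_array(mask, box) * 1L,
             box = box, tight_box = tb, label = cl, image_id = image_id),
        class = "training_instance")
    }
  }
  out
}

#' Normalize a region to zero mean and unit standard deviation
#'
#' Standardizes the region by its own mean and standard deviation, recording
#' both so the operation is traceable. A constant region (sd = 0) maps to
#' all zeros with sd recorded as 1, avoiding division blow-up.
#'
#' @param region an `image_region` or bare numeric array.
#' @return an `image_region` with normalized intensities and a
#'   `normalization` record `(mean, sd)`.
#' @export
normalize_region <- function(region) {
  region <- as_image_region(region)
  x <- region$intensities
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) {
    region$intensities <- array(0, dim(x))
    region$normalization <- list(mean = m, sd = 1)
  } else {
    region$intensities <- (x - m) / s
    region$normalization <- list(mean = m, sd = s)
  }
  region
}

# Output shape for an isotropic rescale fixing the min (2D) or max (3D) side.
resized_shape <- function(shape, mode, target) {
  scale <- switch(mode,
    "2d_min_side" = target / min(shape),
    "3d_max_side" = target / max(shape),
    stop("unknown resize mode: ", mode, call. = FALSE))
  out <- pmax(1L, as.integer(round(shape * scale)))
  # force the controlling side to hit the target exactly despite rounding
  if (mode == "2d_min_side") out[which.min(shape)] <- as.integer(target)
  else out[which.max(shape)] <- as.integer(target)
  out
}

#' Resize a region isotropically for the network input
#'
#' 2D regions are scaled so the smaller of width/height equals `target`
#' (default profile: 96 pixels); 3D regions so the largest side equals
#' `target` (default profile: 80 voxels). The scale is recorded for exact
#' inversion by [restore_to_source()]. Intensities are linearly interpolated.
#'
#' @param region an `image_region` or bare array.
#' @param mode `"2d_min_side"` or `"3d_max_side"` (chosen automatically from
#'   the region dimensionality when `NULL`).
#' @param target positive integer side length.
#' @return the resized `image_region` with a `resize` record.
#' @export
resize_for_network <- function(region, mode = NULL, target = NULL) {
  region <- as_image_region(region)
  if (is.null(mode)) mode <- if (region$dims == 2L) "2d_min_side" else "3d_max_side"
  if (is.null(target)) target <- if (region$dims == 2L) 96L else 80L
  stopifnot(target >= 1)
  shape <- dim(region$intensities)
  out_shape <- resized_shape(shape, mode, target)
  v <- .resample_cpp(as_volume(region$intensities), dim(as_volume(region$intensities)),
                     as.integer(c(out_shape, rep(1L, 3 - length(out_shape)))), 1L)
  region$resize <- list(orig_shape = shape, new_shape = out_shape,
                        mode = mode, target = target)
  region$intensities <- as_user_shape(v, region$dims)
  region
}

resample_array <- function(x, out_shape, method = c("linear", "nearest")) {
  method <- match.arg(method)
  dims <- ndims_of(x)
  v <- .resample_cpp(as_volume(x * 1.0), dim(as_volume(x)),
                     as.integer(c(out_shape, rep(1L, 3 - length(out_shape)))),
                     if (method == "linear") 1L else 0L)
  as_user_shape(v, dims)
}

#' Map a cropped-region result back to source-image coordinates
#'
#' Inverts the resize recorded on `region` (nearest neighbour for binary
#' masks, linear for probability maps) and places the result into a
#' background-valued canvas of the source image at the original box.
#'
#' @param x binary mask or probability map with the region's (resized)
#'   shape.
#' @param region the `image_region` that produced `x`; must carry crop (and,
#'   if applied, resize) records.
#' @param kind `"mask"` (nearest interpolation) or `"prob"` (linear).
#' @return array of the full source-image shape; pixels outside the box are
#'   0 (background).
#' @export
restore_to_source <- function(x, region, kind = c("mask", "prob")) {
  kind <- match.arg(kind)
  if (!inherits(region, "image_region") || is.null(region$original_box))
    stop("state error: region carries no crop record", call. = FALSE)
  if (!is.null(region$resize)) {
    if (!identical(dim(x), NULL) && !all(dim(x) == region$resize$new_shape))
      stop("input error: x does not match the region's resized shape", call. = FALSE)
    x <- resample_array(x, region$resize$orig_shape,
                        method = if (kind == "mask") "nearest" else "linear")
  }
  canvas <- array(0, region$source_shape)
  box <- region$original_box
  if (region$dims == 2L) {
    canvas[(box$lo[1] + 1L):box$hi[1], (box$lo[2] + 1L):box$hi[2]] <- x
  } else {
    canvas[(box$lo[1] + 1L):box$hi[1], (box$lo[2] + 1L):box$hi[2],
           (box$lo[3] + 1L):box$hi[3]] <- x
  }
  canvas
}

#' Preprocess a training instance for the network
#'
#' Normalizes and resizes an instance's region (and resizes its mask with
#' nearest-neighbour interpolation) to the network input convention.
#'
#' @param inst a `training_instance` from [extract_instances()].
#' @param target resize target (defaults per dimensionality: 96 / 80).
#' @return the instance with `region` replaced by a prepared `image_region`
#'   and `mask` resized to match.
#' @export
prep_instance <- function(inst, target = NULL) {
  region <- normalize_region(inst$region)
  region <- resize_for_network(region, target = target)
  inst$region <- region
  inst$mask <- resample_array(inst$mask, dim(region$intensities), "nearest")
  inst
}
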