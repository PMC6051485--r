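# Readers/writers for the supported on-disk formats (PNG/TIFF for 2D,
# NIfTI for 3D), YAML configs and RDS checkpoints with an embedded spec
# checksum.

img_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.png$", lp)) "png"
  else if (grepl("\\.tiff?$", lp)) "tiff"
  else if (grepl("\\.nii(\\.gz)?$", lp)) "nifti"
  else stop("unsupported image format: ", path, call. = FALSE)
}

#' Read a 2D image or 3D volume
#'
#' PNG and TIFF give 2D matrices (multi-channel files are averaged to
#' grayscale); NIfTI gives arrays. Axis order is (row, column[, slice]).
#'
#' @param path file path (.png, .tif/.tiff, .nii, .nii.gz).
#' @return numeric matrix or array.
#' @export
read_image <- function(path) {
  switch(img_format(path),
    png = {
      x <- png::readPNG(path)
      if (length(dim(x)) == 3L) x <- apply(x, c(1, 2), mean)
      unclass(x)
    },
    tiff = {
      x <- tiff::readTIFF(path)
      if (length(dim(x)) == 3L) x <- apply(x, c(1, 2), mean)
      unclass(x)
    },
    nifti = {
      x <- RNifti::readNifti(path)
      array(as.numeric(x), dim(x))
    })
}

#' Write a 2D image or 3D volume
#'
#' PNG/TIFF writers clamp to `[0, 1]`; NIfTI stores raw values.
#'
#' @param x numeric matrix or array.
#' @param path output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  switch(img_format(path),
    png = png::writePNG(pmin(pmax(x, 0), 1), path),
    tiff = tiff::writeTIFF(pmin(pmax(x, 0), 1), path),
    nifti = RNifti::writeNifti(x, path))
  invisible(path)
}

#' Read an integer label map
#'
#' PNG/TIFF label images are assumed 8-bit (value = label / 255); NIfTI
#' label volumes are rounded to integers.
#'
#' @param path file path.
#' @return integer matrix or array.
#' @export
read_label_map <- function(path) {
  x <- read_image(path)
  if (img_format(path) %in% c("png", "tiff")) x <- x * 255
  storage.mode(x) <- "integer"
  x
}

#' Write an integer label map
#'
#' @param labels integer matrix or array.
#' @param path output path (8-bit PNG/TIFF or NIfTI).
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  if (img_format(path) %in% c("png", "tiff")) {
    write_image(labels / 255, path)
  } else {
    write_image(labels, path)
  }
}

#' Save / load a network checkpoint
#'
#' Checkpoints embed the network spec and a parameter checksum that
#' [load_checkpoint()] verifies.
#'
#' @param net a `boxseg_net`.
#' @param path output `.rds` path.
#' @return `path` invisibly (`save_checkpoint`); the restored `boxseg_net`
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(spec = net$spec, params = net$params, nfeat = net$nfeat,
               checksum = param_checksum(net$params)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!isTRUE(all.equal(ck$checksum, param_checksum(ck$params))))
    stop("state error: checkpoint checksum mismatch", call. = FALSE)
  validate_network_spec(ck$spec)
  structure(list(spec = ck$spec, dims = ck$spec$dims, params = ck$params,
                 nfeat = ck$nfeat),
            class = "boxseg_net")
}

#' Serialize a network spec to / from YAML
#'
#' @param spec a [network_spec()].
#' @param path YAML file path.
#' @return `path` invisibly (`write_network_spec`); a validated
#'   `network_spec` (`read_network_spec`).
#' @export
write_network_spec <- function(spec, path) {
  validate_network_spec(spec)
  yaml::write_yaml(list(dims = spec$dims,
                        compression_channels = spec$compression_channels,
                        classifier_channels = spec$classifier$channels,
                        blocks = lapply(spec$blocks, function(b)
                          list(kernel = b$kernel, dilation = b$dilation,
                               channels = b$channels, layers = b$layers))),
                   path)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  y <- yaml::read_yaml(path)
  blocks <- lapply(y$blocks, function(b)
    list(kernel = as.integer(b$kernel), dilation = as.integer(b$dilation),
         channels = as.integer(b$channels), layers = as.integer(b$layers)))
  network_spec(blocks, dims = y$dims,
               compression_channels = y$compression_channels,
               classifier_channels = y$classifier_channels %||% 2L)
}

#' Export a training instance as image files with a JSON sidecar
#'
#' Writes the cropped intensities and binary mask (PNG for 2D, NIfTI for
#' 3D) plus a JSON sidecar recording the bounding box, source image, class
#' label and any normalization/resize records.
#'
#' @param inst a `training_instance`.
#' @param dir output directory.
#' @param name file stem (default `instance`).
#' @return the sidecar path, invisibly.
#' @export
export_instance <- function(inst, dir, name = "instance") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  region <- inst$region
  x <- if (inherits(region, "image_region")) region$intensities else region
  ext <- if (ndims_of(x) == 2L) ".png" else ".nii.gz"
  rng <- range(x)
  x01 <- if (diff(rng) > 0) (x - rng[1]) / diff(rng) else x * 0
  write_image(if (ext == ".png") x01 else x, file.path(dir, paste0(name, ext)))
  write_label_map(inst$mask, file.path(dir, paste0(name, "_mask", ext)))
  side <- list(box = list(lo = inst$box$lo, hi = inst$box$hi),
               label = inst$label, image_id = inst$image_id)
  if (inherits(region, "image_region")) {
    side$normalization <- region$normalization
    side$resize <- region$resize
  }
  sidecar <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(side, sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(sidecar)
}

#' Export a fine-tuning weight map for inspection
#'
#' Writes the three-valued weight map as a three-tone image (0 = black,
#' 1 = grey, omega = white) in PNG (2D) or raw values in NIfTI (3D).
#'
#' @param w weight map from [build_weight_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weight_map <- function(w, path) {
  if (img_format(path) == "nifti") write_image(w, path)
  else write_image(w / max(w, 1), path)
  invisible(path)
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML file carries the CRF, uncertainty, fine-tuning and training
#' parameters; missing entries fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return list with `finetune` ([finetune_config()]) and `train`
#'   ([train_config()]).
#' @export
read_boxseg_config <- function(path) {
  y <- yaml::read_yaml(path) %||% list()
  crf <- do.call(crf_params, y$crf %||% list())
  unc <- do.call(uncertainty_params, y$uncertainty %||% list())
  ft_args <- y$finetune %||% list()
  ft <- do.call(finetune_config, c(ft_args, list(crf = crf, unc = unc)))
  tr <- do.call(train_config, y$train %||% list())
  list(finetune = ft, train = tr)
}

#' @rdname read_boxseg_config
#' @param cfg list as returned by `read_boxseg_config()`.
#' @export
write_boxseg_config <- function(cfg, path) {
  ft <- cfg$finetune
  y <- list(
    crf = list(lambda = ft$crf$lambda, sigma = ft$crf$sigma),
    uncertainty = list(t0 = ft$unc$t0, t1 = ft$unc$t1, epsilon = ft$unc$epsilon,
                       omega = ft$unc$omega, gamma = ft$unc$gamma),
    finetune = list(rounds = ft$rounds, lr = ft$lr, steps = ft$steps,
                    momentum = ft$momentum, seed = ft$seed),
    train = cfg$train[c("batch_size", "momentum", "weight_decay",
                        "max_iterations", "initial_lr", "lr_halving_interval",
                        "val_interval", "seed")])
  yaml::write_yaml(y, path)
  invisible(path)
}
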