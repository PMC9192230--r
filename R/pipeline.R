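# File I/O, run configuration and the end-to-end commands behind the
# command-line interface (inst/cli/uatransnet.R).
#
# Canonical on-disk image format is 8-bit grayscale PNG, scaled to [0, 1] on
# read; TIFF and single-slice NIfTI are accepted and converted on read.

#' Read a grayscale image
#'
#' Reads PNG or TIFF (multichannel images are averaged to one channel) or a
#' single-slice NIfTI volume; intensities are rescaled to `[0, 1]`.
#'
#' @param path file path (`.png`, `.tif`/`.tiff`, `.nii`/`.nii.gz`).
#' @return h x w numeric matrix in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    img <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    img <- tiff::readTIFF(path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI requires the RNifti package")
    vol <- as.array(RNifti::readNifti(path))
    if (length(dim(vol)) > 2) {
      if (any(dim(vol)[-(1:2)] > 1)) stop("only single-slice NIfTI supported")
      vol <- array(vol, dim(vol)[1:2])
    }
    rng <- range(vol)
    img <- if (diff(rng) > 0) (vol - rng[1]) / diff(rng) else vol * 0
  } else stop("unsupported image format: ", path)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]),
                                              drop = FALSE], c(1, 2), mean)
  as.matrix(img)
}

#' Write a grayscale image or mask as 8-bit PNG
#' @param image h x w matrix in `[0, 1]` (masks may be 0/1 integer).
#' @param path output path.
#' @export
write_gray_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Assemble and validate a run configuration
#'
#' All knobs of the pipeline in one validated list: phantom spec, network
#' config, region-growing config, mean-teacher settings and the training
#' schedule (100 epochs, initial learning rate 0.001 dropping to 0.0001 at
#' the switch epoch, cosine-annealed).
#'
#' @param path optional YAML file whose top-level keys override the
#'   defaults; nested keys (e.g. `network$depth`) override per field.
#' @param ... named overrides applied after the file.
#' @return a `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    seed = 1L,
    epochs = 100L,
    batch_size = 8L,
    lr_initial = 1e-3,
    lr_after_switch = 1e-4,
    cosine = TRUE,
    threshold = 0.5,
    n_train = 200L,
    n_val = 40L,
    phantom = list(image_size = c(64L, 64L), n_tumors = 1L,
                   semi_axis_range = c(6, 14), fg_intensity = 0.8,
                   bg_intensity = 0.2, noise_sd = 0.05, edge_blur_sigma = 1),
    network = list(preset = "test-scale"),
    region_grow = list(),
    mean_teacher = list(alpha = 0.99, cons_weight = 1, ramp_up = FALSE,
                        noise_sd = 0.05, confidence_threshold = 0.5),
    alpha_grid = mgam_alpha_grid()
  )
  if (!is.null(path)) cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  cfg <- utils::modifyList(cfg, list(...))
  stopifnot(cfg$epochs >= 1, cfg$batch_size >= 1,
            cfg$lr_initial > 0, cfg$lr_after_switch > 0,
            cfg$threshold > 0, cfg$threshold < 1)
  structure(cfg, class = "run_config")
}

config_phantom_spec <- function(cfg, seed = cfg$seed)
  do.call(phantom_spec, c(cfg$phantom, list(seed = seed)))

config_net <- function(cfg) {
  nw <- cfg$network
  if (!is.null(nw$preset)) {
    base <- net_config_preset(nw$preset)
    nw$preset <- NULL
    do.call(net_config, utils::modifyList(unclass(base), nw))
  } else do.call(net_config, nw)
}

echo_config <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
}

#' Generate a phantom dataset on disk
#'
#' Writes image/mask PNG pairs and a `manifest.csv` listing path, seed and
#' tumor geometry; deterministic per seed.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory.
#' @param n number of phantoms (default `cfg$n_train`).
#' @return the manifest data.frame, invisibly.
#' @export
cmd_generate <- function(cfg, out_dir, n = cfg$n_train) {
  echo_config(cfg, out_dir)
  if (n == 0) {
    warning("n = 0: writing an empty manifest")
    manifest <- data.frame(image = character(0), mask = character(0),
                           seed = integer(0), n_tumors = integer(0),
                           tumor_px = integer(0))
  } else {
    items <- generate_dataset(config_phantom_spec(cfg), n, seed = cfg$seed)
    manifest <- do.call(rbind, lapply(seq_along(items), function(i) {
      it <- items[[i]]
      ip <- file.path(out_dir, sprintf("img_%04d.png", i))
      mp <- file.path(out_dir, sprintf("mask_%04d.png", i))
      write_gray_png(it$image, ip)
      write_gray_png(it$mask, mp)
      data.frame(image = ip, mask = mp, seed = it$meta$seed,
                 n_tumors = length(it$meta$tumors), tumor_px = sum(it$mask))
    }))
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

read_manifest_items <- function(manifest_path) {
  man <- utils::read.csv(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    structure(list(image = read_gray_image(man$image[i]),
                   mask = (read_gray_image(man$mask[i]) > 0.5) + 0L,
                   meta = list(seed = man$seed[i])),
              class = "labeled_image")
  })
}

#' Segment the suspected region of one image (classical pipeline)
#'
#' Writes the mask PNG plus a JSON sidecar with the ROI box, threshold
#' trajectory and size estimate.
#'
#' @param image_path input image.
#' @param out_prefix output prefix (`<prefix>_mask.png`, `<prefix>.json`).
#' @param cfg a [run_config()] (region-growing knobs under `$region_grow`).
#' @return the mask, invisibly.
#' @export
cmd_preprocess <- function(image_path, out_prefix, cfg = run_config()) {
  img <- read_gray_image(image_path)
  rg <- do.call(region_grow_config, cfg$region_grow)
  mask <- segment_suspected_region(img, rg)
  write_gray_png(mask, paste0(out_prefix, "_mask.png"))
  roi <- attr(mask, "roi")
  jsonlite::write_json(
    list(input = image_path, roi = unclass(roi),
         theta_trajectory = attr(mask, "theta_trajectory"),
         size_estimate = unclass(attr(mask, "size_estimate")),
         region_px = sum(mask)),
    paste0(out_prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(mask)
}

#' Train the segmentation network on a phantom dataset
#'
#' Generates (or loads) the dataset, trains per the schedule in `cfg`, logs
#' per-epoch metrics to CSV, and saves a checkpoint with the config embedded.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory.
#' @param manifest optional manifest CSV of a dataset on disk; when `NULL`
#'   the phantoms are generated in memory.
#' @param verbose print per-epoch progress.
#' @return the trained model, invisibly.
#' @export
cmd_train <- function(cfg, out_dir, manifest = NULL, verbose = FALSE) {
  echo_config(cfg, out_dir)
  items <- if (is.null(manifest)) {
    generate_dataset(config_phantom_spec(cfg), cfg$n_train + cfg$n_val,
                     seed = cfg$seed)
  } else {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    read_manifest_items(manifest)
  }
  n_val <- min(cfg$n_val, length(items) - 1L)
  val <- if (n_val > 0) items[seq_len(n_val) + (length(items) - n_val)] else NULL
  train <- items[seq_len(length(items) - n_val)]
  model <- build_model(config_net(cfg), seed = cfg$seed)
  model <- train_segmenter(model, train, epochs = cfg$epochs,
                           batch_size = cfg$batch_size,
                           lr_initial = cfg$lr_initial,
                           lr_late = cfg$lr_after_switch,
                           cosine = cfg$cosine, val_items = val,
                           seed = cfg$seed, verbose = verbose)
  utils::write.csv(model$history, file.path(out_dir, "epoch_log.csv"),
                   row.names = FALSE)
  save_checkpoint(model, file.path(out_dir, "checkpoint.rds"))
  invisible(model)
}

#' Save / load a model checkpoint (config embedded)
#' @param model a `uat_model`.
#' @param path checkpoint path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "uat_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "uat_model")) stop("not a uat_model checkpoint")
  model
}

#' Evaluate a checkpoint on a dataset
#'
#' @param checkpoint path to a checkpoint from [cmd_train()].
#' @param cfg a [run_config()]; the evaluation set is regenerated from its
#'   phantom spec (or read from `manifest`).
#' @param out_csv optional path for the per-image metric report (one row per
#'   image plus a summary row).
#' @param manifest optional manifest CSV.
#' @return the [aggregate_metrics()] result, invisibly.
#' @export
cmd_eval <- function(checkpoint, cfg = run_config(), out_csv = NULL,
                     manifest = NULL) {
  model <- load_checkpoint(checkpoint)
  items <- if (is.null(manifest))
    generate_dataset(config_phantom_spec(cfg), cfg$n_val,
                     seed = cfg$seed + 1L)
  else read_manifest_items(manifest)
  res <- evaluate_segmenter(model, items, threshold = cfg$threshold)
  if (!is.null(out_csv)) {
    rep <- res$per_image
    rep$image <- seq_len(nrow(rep))
    summary_row <- cbind(as.data.frame(t(res$macro$mean)),
                         image = NA_integer_)
    utils::write.csv(rbind(rep, summary_row), out_csv, row.names = FALSE)
  }
  invisible(res)
}

#' Segment one image with a trained checkpoint
#'
#' @param checkpoint checkpoint path.
#' @param image_path input image path.
#' @param out_path output mask PNG.
#' @param threshold probability-to-mask threshold.
#' @return the binary mask, invisibly.
#' @export
cmd_segment <- function(checkpoint, image_path, out_path, threshold = 0.5) {
  model <- load_checkpoint(checkpoint)
  img <- read_gray_image(image_path)
  mask <- model_predict(model, img, threshold = threshold)
  write_gray_png(mask, out_path)
  invisible(mask)
}

#' Mean-teacher dataset optimization over a labeled/unlabeled mix
#'
#' Trains the classifier with the mean-teacher scheme and writes the
#' effective/difficult partition (ids + confidence scores) as CSV.
#'
#' @param labeled list of `list(image, label)` items.
#' @param unlabeled list of images to score and partition.
#' @param cfg a [run_config()] (mean-teacher knobs under `$mean_teacher`).
#' @param out_csv optional partition CSV path.
#' @param epochs training epochs (default `cfg$epochs`).
#' @param net optional classifier [net_config()].
#' @return list with the `state` and the `partition`, invisibly.
#' @export
cmd_optimize_dataset <- function(labeled, unlabeled, cfg = run_config(),
                                 out_csv = NULL, epochs = cfg$epochs,
                                 net = NULL) {
  mt <- cfg$mean_teacher
  if (is.null(net))
    net <- net_config(depth = 2L, base_width = 8L, gn_groups = 8L,
                      input_size = dim(labeled[[1]]$image))
  cls <- build_classifier(net, seed = cfg$seed)
  state <- teacher_student_state(cls, alpha = mt$alpha)
  state <- train_mean_teacher(state, labeled, unlabeled, epochs = epochs,
                              batch_size = cfg$batch_size,
                              lr = cfg$lr_initial,
                              cons_weight = mt$cons_weight,
                              ramp_up = isTRUE(mt$ramp_up),
                              noise_sd = mt$noise_sd, seed = cfg$seed)
  part <- partition_dataset(state$model, unlabeled,
                            confidence_threshold = mt$confidence_threshold,
                            params = state$student)
  if (!is.null(out_csv)) {
    utils::write.csv(data.frame(
      id = names(part$scores), score = as.numeric(part$scores),
      part = ifelse(seq_along(part$scores) %in% part$effective,
                    "effective", "difficult")), out_csv, row.names = FALSE)
  }
  invisible(list(state = state, partition = part))
}

#' Fixed fusion-weight grid experiment
#'
#' Trains and evaluates the test-scale network once per `(a1, a2)`
#' combination of the alpha grid, with the fusion weights frozen at the given
#' values, and tabulates the evaluation metrics per combination.
#'
#' @param cfg a [run_config()].
#' @param out_csv optional CSV path for the metric table.
#' @param epochs training epochs per combination.
#' @param n_train,n_val dataset sizes per combination.
#' @return data.frame with one row per combination.
#' @export
cmd_alpha_grid <- function(cfg = run_config(), out_csv = NULL, epochs = 2L,
                           n_train = 24L, n_val = 8L) {
  items <- generate_dataset(config_phantom_spec(cfg), n_train + n_val,
                            seed = cfg$seed)
  train <- items[seq_len(n_train)]
  val <- items[n_train + seq_len(n_val)]
  rows <- lapply(cfg$alpha_grid, function(ab) {
    model <- build_model(config_net(cfg), seed = cfg$seed)
    model$params[["mgam.a1"]] <- ab[1]
    model$params[["mgam.a2"]] <- ab[2]
    frozen <- c("mgam.a1", "mgam.a2")
    model <- train_segmenter(model, train, epochs = epochs,
                             batch_size = cfg$batch_size,
                             lr_initial = cfg$lr_initial,
                             lr_late = cfg$lr_after_switch,
                             seed = cfg$seed, frozen = frozen)
    m <- evaluate_segmenter(model, val, threshold = cfg$threshold)
    data.frame(a1 = ab[1], a2 = ab[2], t(m$macro$mean))
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
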