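# UATransNet assembly: group-normalized residual convolution blocks, encoder
# with 2x2 max pooling, MGAM bottleneck, and a decoder with residual or dense
# multiscale skip fusion, ending in a 1-channel sigmoid head.

#' Network configuration
#'
#' @param depth number of encoder scales (>= 2); channel widths double per
#'   scale from `base_width`.
#' @param base_width channels at the first scale; must be a multiple of
#'   `gn_groups`.
#' @param gn_groups GroupNorm group count.
#' @param skip_mode `"residual"` (each decoder block fuses the encoder skip
#'   with the upsampled previous decoder feature, plus an additive shortcut)
#'   or `"dense"` (each decoder block fuses the skip with all previous
#'   decoder-stage outputs).
#' @param use_mgam include the attention bottleneck.
#' @param n_heads attention head count for the channel-attention component;
#'   the bottleneck width must be divisible by it.
#' @param input_size spatial size `c(h, w)` the model is built for (the
#'   learned position embedding is tied to it); must be divisible by
#'   `2^(depth - 1)`.
#' @param in_channels input image channels.
#' @return a `net_config`.
#' @export
net_config <- function(depth = 3L, base_width = 8L, gn_groups = 8L,
                       skip_mode = c("residual", "dense"), use_mgam = TRUE,
                       n_heads = 1L, input_size = c(64L, 64L),
                       in_channels = 1L) {
  skip_mode <- match.arg(skip_mode)
  depth <- as.integer(depth); base_width <- as.integer(base_width)
  stopifnot(depth >= 2, base_width >= gn_groups,
            base_width %% gn_groups == 0, n_heads >= 1)
  if (any(input_size %% 2L^(depth - 1L) != 0L))
    stop("input_size must be divisible by 2^(depth - 1)")
  bottleneck <- base_width * 2L^(depth - 1L)
  if (bottleneck %% n_heads != 0L)
    stop("bottleneck width must be divisible by n_heads")
  structure(list(depth = depth, base_width = base_width,
                 gn_groups = as.integer(gn_groups), skip_mode = skip_mode,
                 use_mgam = isTRUE(use_mgam), n_heads = as.integer(n_heads),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels)),
            class = "net_config")
}

#' Named configuration presets
#'
#' `"test-scale"` is a small CPU-friendly model (depth 3, width 8, 64 x 64
#' input); `"paper-scale"` is the full-size preset (depth 5, width 36,
#' 256 x 256 input), whose parameter count lands in the 15-20 M range typical
#' of lightweight U-shaped segmenters of this family.
#'
#' @param name preset name.
#' @export
net_config_preset <- function(name = c("test-scale", "paper-scale")) {
  switch(match.arg(name),
    "test-scale" = net_config(depth = 3L, base_width = 8L, gn_groups = 8L,
                              input_size = c(64L, 64L)),
    "paper-scale" = net_config(depth = 5L, base_width = 36L, gn_groups = 12L,
                               input_size = c(256L, 256L))
  )
}

net_widths <- function(cfg)
  as.integer(cfg$base_width * 2^(seq_len(cfg$depth) - 1))

init_conv <- function(params, px, k, cin, cout) {
  params[[paste0(px, ".w")]] <-
    array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
          c(k, k, cin, cout))
  params[[paste0(px, ".b")]] <- numeric(cout)
  params
}

init_gn <- function(params, px, c0) {
  params[[paste0(px, ".g")]] <- rep(1, c0)
  params[[paste0(px, ".b")]] <- numeric(c0)
  params
}

init_res_block <- function(params, px, cin, cout) {
  params <- init_conv(params, paste0(px, ".c1"), 3L, cin, cout)
  params <- init_gn(params, paste0(px, ".g1"), cout)
  params <- init_conv(params, paste0(px, ".c2"), 3L, cout, cout)
  params <- init_gn(params, paste0(px, ".g2"), cout)
  params <- init_conv(params, paste0(px, ".c3"), 3L, cout, cout)
  params <- init_gn(params, paste0(px, ".g3"), cout)
  if (cin != cout) params <- init_conv(params, paste0(px, ".sc"), 1L, cin, cout)
  params
}

# three 3x3 conv + GroupNorm + ReLU stages with an additive shortcut
res_block_ag <- function(lv, px, x, groups) {
  h1 <- ag_relu(ag_groupnorm(ag_conv(x, lv[[paste0(px, ".c1.w")]],
                                     lv[[paste0(px, ".c1.b")]]),
                             lv[[paste0(px, ".g1.g")]],
                             lv[[paste0(px, ".g1.b")]], groups))
  h2 <- ag_relu(ag_groupnorm(ag_conv(h1, lv[[paste0(px, ".c2.w")]],
                                     lv[[paste0(px, ".c2.b")]]),
                             lv[[paste0(px, ".g2.g")]],
                             lv[[paste0(px, ".g2.b")]], groups))
  h3 <- ag_groupnorm(ag_conv(h2, lv[[paste0(px, ".c3.w")]],
                             lv[[paste0(px, ".c3.b")]]),
                     lv[[paste0(px, ".g3.g")]], lv[[paste0(px, ".g3.b")]],
                     groups)
  sc <- if (!is.null(lv[[paste0(px, ".sc.w")]]))
    ag_conv(x, lv[[paste0(px, ".sc.w")]], lv[[paste0(px, ".sc.b")]])
  else x
  ag_relu(ag_add(h3, sc))
}

decoder_in_channels <- function(cfg) {
  wd <- net_widths(cfg)
  d <- cfg$depth
  if (cfg$skip_mode == "residual") {
    vapply(seq(d - 1L, 1L), function(s) wd[s] + wd[s + 1L], integer(1))
  } else {
    # dense: skip + bottleneck + all earlier decoder outputs
    vapply(seq(d - 1L, 1L), function(s) {
      hist_w <- c(wd[d], if (s < d - 1L) wd[seq(d - 1L, s + 1L)])
      wd[s] + sum(hist_w)
    }, integer(1))
  }
}

init_seg_params <- function(cfg) {
  wd <- net_widths(cfg)
  d <- cfg$depth
  params <- list()
  cin <- cfg$in_channels
  for (i in seq_len(d)) {
    params <- init_res_block(params, paste0("enc", i), cin, wd[i])
    cin <- wd[i]
  }
  dec_in <- decoder_in_channels(cfg)
  for (j in seq_along(dec_in)) {
    s <- d - j  # decoder stage producing scale-s features
    params <- init_res_block(params, paste0("dec", s), dec_in[j], wd[s])
  }
  params <- init_conv(params, "head", 1L, wd[1], 1L)
  if (cfg$use_mgam) {
    hb <- cfg$input_size %/% 2L^(d - 1L)
    c0 <- wd[d]
    sdp <- 1 / sqrt(c0)
    params[["mgam.pos"]] <- array(0, c(hb[1], hb[2], c0))
    params[["mgam.wq"]] <- matrix(stats::rnorm(c0 * c0, 0, sdp), c0, c0)
    params[["mgam.wk"]] <- matrix(stats::rnorm(c0 * c0, 0, sdp), c0, c0)
    params[["mgam.wv"]] <- matrix(stats::rnorm(c0 * c0, 0, sdp), c0, c0)
    if (cfg$n_heads > 1L)
      params[["mgam.wo"]] <- matrix(stats::rnorm(c0 * c0, 0, sdp), c0, c0)
    c1 <- gcac_c1(c0)
    params <- init_conv(params, "mgam.gcv", 1L, c0, c1)
    params <- init_conv(params, "mgam.gcw", 1L, c0, c1)
    params[["mgam.a1"]] <- 0
    params[["mgam.a2"]] <- 0
  }
  params
}

seg_forward_ag <- function(lv, cfg, x) {
  d <- cfg$depth
  g <- cfg$gn_groups
  skips <- vector("list", d - 1L)
  cur <- x
  for (i in seq_len(d)) {
    cur <- res_block_ag(lv, paste0("enc", i), cur, g)
    if (i < d) {
      skips[[i]] <- cur
      cur <- ag_maxpool(cur)
    }
  }
  if (cfg$use_mgam) cur <- mgam_forward_ag(lv, "mgam.", cur, cfg$n_heads)
  history <- list(cur)
  for (s in seq(d - 1L, 1L)) {
    sk <- skips[[s]]
    dd <- dim(sk$val)
    inputs <- if (cfg$skip_mode == "residual") {
      list(sk, ag_resize(cur, dd[1], dd[2]))
    } else {
      c(list(sk), lapply(history, function(hh) ag_resize(hh, dd[1], dd[2])))
    }
    cur <- res_block_ag(lv, paste0("dec", s), ag_concat(inputs), g)
    if (cfg$skip_mode == "dense") history <- c(history, list(cur))
  }
  ag_conv(cur, lv[["head.w"]], lv[["head.b"]])  # logits
}

#' Build a segmentation model
#'
#' Constructs the full network for `cfg`: encoder of `depth` residual-block +
#' max-pool stages, the MGAM bottleneck when `use_mgam`, a decoder following
#' `skip_mode`, and a 1-channel sigmoid head.  Shared (non-attention)
#' parameters are drawn first, so two models built from the same seed that
#' differ only in `use_mgam` share their backbone initialization exactly.
#'
#' @param cfg a [net_config()].
#' @param seed integer seed for parameter initialization.
#' @return a `uat_model` with elements `cfg`, `params` and `n_params`.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  params <- with_seed(seed, init_seg_params(cfg))
  structure(list(cfg = cfg, params = params, task = "segmentation",
                 n_params = count_params(params)),
            class = "uat_model")
}

#' Total trainable parameter count
#' @param params a model parameter list (or a `uat_model`).
#' @export
count_params <- function(params) {
  if (inherits(params, "uat_model")) params <- params$params
  sum(vapply(params, length, numeric(1)))
}

#' @export
print.uat_model <- function(x, ...) {
  cat(sprintf("uat_model (%s): depth %d, base width %d, skip '%s', mgam %s\n",
              x$task, x$cfg$depth, x$cfg$base_width, x$cfg$skip_mode,
              if (x$cfg$use_mgam && x$task == "segmentation") "on" else "off"))
  cat(sprintf("  parameters: %s\n", format(x$n_params, big.mark = ",")))
  invisible(x)
}

#' Forward pass of a segmentation model
#'
#' @param model a `uat_model` built by [build_model()].
#' @param image h x w numeric matrix matching the model's `input_size`.
#' @param threshold optional probability cut; when given, a 0/1 mask is
#'   returned instead of the probability map.
#' @return h x w matrix of tumor probabilities in `[0, 1]` (or a 0/1 mask).
#' @export
model_predict <- function(model, image, threshold = NULL) {
  stopifnot(inherits(model, "uat_model"), model$task == "segmentation")
  if (!all(dim(image) == model$cfg$input_size))
    stop("image size does not match the model's input_size")
  ag_reset()
  lv <- lapply(model$params, ag_leaf)
  x <- ag_leaf(array(image, c(dim(image), 1L)))
  logits <- seg_forward_ag(lv, model$cfg, x)
  p <- 1 / (1 + exp(-logits$val[, , 1]))
  if (is.null(threshold)) p else (p >= threshold) + 0L
}

#' Count of cross-stage decoder feature reuses
#'
#' For the dense decoder every stage consumes the outputs of all earlier
#' decoder stages (bottleneck included), giving `d * (d - 1) / 2` cross-stage
#' reuses at depth `d`; the residual decoder reuses only the immediately
#' previous stage.
#'
#' @param cfg a [net_config()].
#' @export
count_feature_reuses <- function(cfg) {
  d <- cfg$depth
  if (cfg$skip_mode == "dense") d * (d - 1L) / 2L else d - 1L
}

# --- classifier variant ---------------------------------------------------

init_cls_params <- function(cfg) {
  wd <- net_widths(cfg)
  params <- list()
  cin <- cfg$in_channels
  for (i in seq_len(cfg$depth)) {
    params <- init_res_block(params, paste0("enc", i), cin, wd[i])
    cin <- wd[i]
  }
  c0 <- wd[cfg$depth]
  params[["fc.w"]] <- matrix(stats::rnorm(c0, 0, 1 / sqrt(c0)), 1L, c0)
  params[["fc.b"]] <- 0
  params
}

cls_forward_ag <- function(lv, cfg, x) {
  cur <- x
  for (i in seq_len(cfg$depth)) {
    cur <- res_block_ag(lv, paste0("enc", i), cur, cfg$gn_groups)
    cur <- ag_maxpool(cur)
  }
  ag_affine(ag_gap(cur), lv[["fc.w"]], lv[["fc.b"]])  # scalar logit
}

#' Build a binary classifier from the same residual backbone
#'
#' Residual-block + max-pool stack followed by global average pooling and a
#' fully connected head emitting one class probability (for example,
#' effective vs difficult cases).  Used as both the student and the teacher
#' of the mean-teacher scheme.
#'
#' @param cfg a [net_config()]; `input_size` must be divisible by `2^depth`.
#' @param seed integer seed for parameter initialization.
#' @export
build_classifier <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  if (any(cfg$input_size %% 2L^cfg$depth != 0L))
    stop("classifier input_size must be divisible by 2^depth")
  params <- with_seed(seed, init_cls_params(cfg))
  structure(list(cfg = cfg, params = params, task = "classification",
                 n_params = count_params(params)),
            class = "uat_model")
}

#' Predicted class probability of a classifier
#'
#' @param model a `uat_model` built by [build_classifier()].
#' @param image h x w numeric matrix.
#' @param params optional parameter list overriding `model$params` (e.g. the
#'   teacher weights of a mean-teacher state).
#' @export
classifier_predict <- function(model, image, params = NULL) {
  stopifnot(inherits(model, "uat_model"), model$task == "classification")
  ag_reset()
  lv <- lapply(params %||% model$params, ag_leaf)
  x <- ag_leaf(array(image, c(dim(image), 1L)))
  z <- cls_forward_ag(lv, model$cfg, x)
  1 / (1 + exp(-z$val))
}
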