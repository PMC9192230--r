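# Synthetic MRI-like phantom generator.
#
# The clinical images this package targets are not redistributable, so every
# downstream stage is exercised on synthetic phantoms: one or more bright,
# roughly elliptical tumor regions on a darker tissue background, with blurred
# edges and additive Gaussian noise.  Intensities live in [0, 1].

#' Specification of a synthetic tumor phantom
#'
#' @param image_size integer vector `c(h, w)` in pixels.
#' @param n_tumors number of elliptical tumors (>= 0).
#' @param semi_axis_range `c(min, max)` semi-axis lengths in pixels; each
#'   ellipse draws its two semi-axes uniformly from this range and a rotation
#'   angle uniformly from `[0, pi)`.
#' @param fg_intensity mean tumor intensity in `[0, 1]`; must exceed
#'   `bg_intensity` (the tumor is modelled as brighter than surrounding
#'   tissue).
#' @param bg_intensity mean background intensity in `[0, 1]`.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param edge_blur_sigma Gaussian blur sigma in pixels applied to the
#'   two-level intensity field before noise (0 disables blurring).
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   phantoms.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(64L, 64L), n_tumors = 1L,
                         semi_axis_range = c(6, 14), fg_intensity = 0.8,
                         bg_intensity = 0.2, noise_sd = 0.05,
                         edge_blur_sigma = 1, seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 1),
            n_tumors >= 0, length(semi_axis_range) == 2,
            semi_axis_range[1] > 0, semi_axis_range[1] <= semi_axis_range[2],
            fg_intensity >= 0, fg_intensity <= 1,
            bg_intensity >= 0, bg_intensity <= 1,
            noise_sd >= 0, edge_blur_sigma >= 0)
  if (fg_intensity <= bg_intensity)
    stop("fg_intensity must exceed bg_intensity (tumor brighter than tissue)")
  if (n_tumors > 0 && 2 * semi_axis_range[2] >= min(image_size))
    stop("tumor does not fit: 2 * max semi-axis must be below min(image_size)")
  structure(list(image_size = as.integer(image_size),
                 n_tumors = as.integer(n_tumors),
                 semi_axis_range = as.numeric(semi_axis_range),
                 fg_intensity = fg_intensity, bg_intensity = bg_intensity,
                 noise_sd = noise_sd, edge_blur_sigma = edge_blur_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# evaluate the RNG-consuming expression under a fixed seed, restoring
# .Random.seed afterwards so callers' RNG streams are untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# pixel-center rasterization of a rotated ellipse
rasterize_ellipse <- function(h, w, center, a, b, phi) {
  dr <- matrix(seq_len(h) - center[1], h, w)
  dc <- matrix(seq_len(w) - center[2], h, w, byrow = TRUE)
  u <- dr * cos(phi) + dc * sin(phi)
  v <- -dr * sin(phi) + dc * cos(phi)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate one labeled phantom image
#'
#' Draws `n_tumors` rotated ellipses (placed uniformly so that each fits
#' inside the frame), paints them at `fg_intensity` on a `bg_intensity`
#' background, blurs the two-level field, adds Gaussian noise and clips to
#' `[0, 1]`.  The mask is the union of the rasterized ellipses, unaffected by
#' blur and noise.
#'
#' @param spec a [phantom_spec()].
#' @return A `labeled_image`: list with `image` (h x w matrix in `[0, 1]`),
#'   `mask` (h x w 0/1 matrix) and `meta` (spec plus tumor geometry).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  with_seed(spec$seed, {
    mask <- matrix(0L, h, w)
    geom <- list()
    if (spec$n_tumors > 0) {
      for (i in seq_len(spec$n_tumors)) {
        a <- stats::runif(1, spec$semi_axis_range[1], spec$semi_axis_range[2])
        b <- stats::runif(1, spec$semi_axis_range[1], spec$semi_axis_range[2])
        phi <- stats::runif(1, 0, pi)
        rad <- max(a, b)
        cr <- stats::runif(1, 1 + rad, h - rad)
        cc <- stats::runif(1, 1 + rad, w - rad)
        mask <- mask | rasterize_ellipse(h, w, c(cr, cc), a, b, phi)
        geom[[i]] <- list(center = c(cr, cc), a = a, b = b, phi = phi)
      }
      mask <- mask + 0L
    }
    img <- matrix(spec$bg_intensity, h, w)
    img[mask == 1L] <- spec$fg_intensity
    if (spec$edge_blur_sigma > 0)
      img <- as.matrix(EBImage::gblur(img, sigma = spec$edge_blur_sigma))
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, mask = mask,
                   meta = list(spec = spec, seed = spec$seed, tumors = geom)),
              class = "labeled_image")
  })
}

#' Generate a reproducible phantom dataset
#'
#' Each item gets its own derived seed, so the dataset is deterministic given
#' `(spec, n, seed)` while items are mutually independent.
#'
#' @param spec a [phantom_spec()] (its `seed` field is ignored here).
#' @param n number of phantoms (>= 1).
#' @param seed integer master seed.
#' @return list of `labeled_image` objects.
#' @export
generate_dataset <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n < 1) stop("n must be >= 1")
  item_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  lapply(item_seeds, function(s) {
    sp <- spec
    sp$seed <- s
    generate_phantom(sp)
  })
}

rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

#' Augment a labeled image
#'
#' Applies the same geometric transform to image and mask.  `rot90` rotates
#' counter-clockwise; `scale` resizes by `factor` (bilinear; the mask is
#' re-thresholded at 0.5 to stay binary) and center-crops or zero-pads back to
#' the original frame.
#'
#' @param item a `labeled_image`.
#' @param op one of `"rot90"`, `"rot180"`, `"rot270"`, `"flip_h"`,
#'   `"flip_v"`, `"scale"`.
#' @param factor scale factor for `op = "scale"`.
#' @return the transformed `labeled_image`.
#' @export
augment <- function(item, op, factor = 1.1) {
  ops <- c("rot90", "rot180", "rot270", "flip_h", "flip_v", "scale")
  if (!op %in% ops)
    stop("unknown augmentation op '", op, "'; expected one of: ",
         paste(ops, collapse = ", "))
  tf <- switch(op,
    rot90  = rot90_ccw,
    rot180 = function(m) rot90_ccw(rot90_ccw(m)),
    rot270 = function(m) rot90_ccw(rot90_ccw(rot90_ccw(m))),
    flip_h = function(m) m[, ncol(m):1, drop = FALSE],
    flip_v = function(m) m[nrow(m):1, , drop = FALSE],
    scale  = function(m) rescale_to_frame(m, factor)
  )
  item$image <- tf(item$image)
  item$mask <- if (op == "scale") (tf(item$mask) > 0.5) + 0L else tf(item$mask)
  item$meta$augment <- c(item$meta$augment, op)
  item
}

# resize by `factor` then center-crop / zero-pad back to the original frame
rescale_to_frame <- function(m, factor) {
  h <- nrow(m); w <- ncol(m)
  nh <- max(1L, round(h * factor)); nw <- max(1L, round(w * factor))
  r <- .resize_bilinear_fwd(array(m, c(h, w, 1)), nh, nw)[, , 1]
  out <- matrix(0, h, w)
  if (nh >= h) {
    r0 <- (nh - h) %/% 2; c0 <- (nw - w) %/% 2
    out <- r[r0 + seq_len(h), c0 + seq_len(w)]
  } else {
    r0 <- (h - nh) %/% 2; c0 <- (w - nw) %/% 2
    out[r0 + seq_len(nh), c0 + seq_len(nw)] <- r
  }
  out
}
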