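# Classical suspected-region preprocessing: ROI detection, contrast clipping,
# windowed filtering, Otsu-based tumor size estimation and adaptive seeded
# region growing.  Images are h x w matrices in [0, 1]; coordinates are
# 1-based (row, col); ROI boxes are closed integer ranges
# [row0, row1] x [col0, col1].

#' Detect a rectangular region of interest around bright pixels
#'
#' A simple intensity-percentile detector: the ROI is the bounding box (plus a
#' fixed margin, clipped to the frame) of all pixels at or above the given
#' intensity percentile.  It stands in for a learned suspicious-region
#' detector and relies on the same prior as the rest of the pipeline: the
#' tumor is brighter than surrounding tissue.
#'
#' @param image h x w numeric matrix in `[0, 1]`.
#' @param bright_percentile fraction in (0, 1); pixels at or above this
#'   intensity quantile are considered bright.
#' @param margin margin in pixels added around the tight bounding box.
#' @return an `roi_box`: list with integer `row0`, `col0`, `row1`, `col1`.
#' @export
detect_roi <- function(image, bright_percentile = 0.95, margin = 2L) {
  stopifnot(is.matrix(image), bright_percentile > 0, bright_percentile < 1)
  if (diff(range(image)) == 0) stop("no suspicious region: image is constant")
  # order-statistic quantile; ties with the image minimum never count as
  # bright, so a small bright blob on a flat background is boxed tightly
  thr <- stats::quantile(image, bright_percentile, names = FALSE, type = 1)
  hit <- which(image >= thr & image > min(image), arr.ind = TRUE)
  roi_box(max(1L, min(hit[, 1]) - margin), max(1L, min(hit[, 2]) - margin),
          min(nrow(image), max(hit[, 1]) + margin),
          min(ncol(image), max(hit[, 2]) + margin))
}

#' @export
roi_box <- function(row0, col0, row1, col1) {
  row0 <- as.integer(row0); col0 <- as.integer(col0)
  row1 <- as.integer(row1); col1 <- as.integer(col1)
  stopifnot(row0 >= 1, col0 >= 1, row0 <= row1, col0 <= col1)
  structure(list(row0 = row0, col0 = col0, row1 = row1, col1 = col1),
            class = "roi_box")
}

roi_dims <- function(roi) c(roi$row1 - roi$row0 + 1L, roi$col1 - roi$col0 + 1L)
roi_rows <- function(roi) roi$row0:roi$row1
roi_cols <- function(roi) roi$col0:roi$col1

#' Two-tailed histogram contrast clipping
#'
#' Linearly rescales intensities so that the lowest and highest `tail_weight`
#' cumulative-mass fractions of the histogram map to 0 and 1; interior pixel
#' ordering is preserved.  A degenerate (single-valued) image is returned
#' unchanged.
#'
#' @param image h x w numeric matrix.
#' @param tail_weight fraction in (0, 0.5) of histogram mass clipped at each
#'   tail (default 5%).
#' @return the contrast-adjusted image, same shape, in `[0, 1]`.
#' @export
clip_histogram <- function(image, tail_weight = 0.05) {
  stopifnot(tail_weight > 0, tail_weight < 0.5)
  lo <- stats::quantile(image, tail_weight, names = FALSE)
  hi <- stats::quantile(image, 1 - tail_weight, names = FALSE)
  if (hi <= lo) return(image)
  pmin(pmax((image - lo) / (hi - lo), 0), 1)
}

#' Filter window size from the ROI: 5% of the larger side, rounded up to odd
#'
#' @param roi an `roi_box`.
#' @return odd integer >= 3.
#' @export
roi_window_size <- function(roi) {
  d <- roi_dims(roi)
  w <- as.integer(ceiling(0.05 * max(d)))
  if (w %% 2L == 0L) w <- w + 1L
  max(w, 3L)
}

apply_in_roi <- function(image, roi, fn) {
  out <- image
  out[roi_rows(roi), roi_cols(roi)] <- fn(image[roi_rows(roi), roi_cols(roi)])
  out
}

check_window <- function(window, roi) {
  stopifnot(window >= 3, window %% 2 == 1)
  if (any(window > roi_dims(roi)))
    stop("filter window (", window, ") larger than ROI")
}

#' Windowed filters applied inside the ROI only
#'
#' `median_filter_roi` removes impulse noise, `mean_filter_roi` smooths false
#' contours left by the median, and `laplacian_enhance` sharpens edges by
#' adding `lambda * (-Laplacian)`; all use the same odd window and leave
#' pixels outside the ROI unchanged.
#'
#' @param image h x w numeric matrix in `[0, 1]`.
#' @param roi an `roi_box`.
#' @param window odd window size >= 3, typically [roi_window_size()].
#' @param lambda edge-enhancement strength for `laplacian_enhance`.
#' @return the filtered image, same shape.
#' @export
median_filter_roi <- function(image, roi, window) {
  check_window(window, roi)
  apply_in_roi(image, roi, function(sub) median_filter(sub, window))
}

# exact sliding-window median with replicate padding (kept exact so constant
# regions pass through bit-identically)
median_filter <- function(m, window) {
  r <- (window - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  pad <- m[pmin(pmax(seq_len(h + 2L * r) - r, 1L), h),
           pmin(pmax(seq_len(w + 2L * r) - r, 1L), w), drop = FALSE]
  stack <- vapply(seq_len(window), function(i)
    vapply(seq_len(window), function(j)
      pad[i + seq_len(h) - 1L, j + seq_len(w) - 1L, drop = FALSE],
      matrix(0, h, w)), array(0, c(h, w, window)))
  apply(array(stack, c(h, w, window^2)), c(1, 2), stats::median)
}

#' @rdname median_filter_roi
#' @export
mean_filter_roi <- function(image, roi, window) {
  check_window(window, roi)
  k <- matrix(1 / window^2, window, window)
  apply_in_roi(image, roi, function(sub)
    as.matrix(EBImage::filter2(sub, k, boundary = "replicate")))
}

#' @rdname median_filter_roi
#' @export
laplacian_enhance <- function(image, roi, window, lambda = 0.5) {
  check_window(window, roi)
  k <- matrix(1, window, window)
  k[(window + 1L) %/% 2L, (window + 1L) %/% 2L] <- 1 - window^2
  apply_in_roi(image, roi, function(sub) {
    lap <- as.matrix(EBImage::filter2(sub, k, boundary = "replicate"))
    pmin(pmax(sub + lambda * (-lap), 0), 1)
  })
}

#' Otsu threshold by exhaustive search over a 256-bin histogram
#'
#' Bins span the observed intensity range; the returned level is the bin
#' boundary maximizing between-class variance, tie-broken toward the lowest
#' qualifying bin.  Pixels `<= level` form the dark class.
#'
#' @param x numeric vector or matrix with at least two distinct values.
#' @param n_bins histogram resolution.
#' @return the threshold intensity level.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (diff(rng) == 0) stop("Otsu threshold undefined for single-valued input")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  p <- counts / sum(counts)
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[n_bins]
  # between-class variance for a cut after bin t (t = 1..n_bins-1)
  t <- seq_len(n_bins - 1L)
  valid <- w0[t] > 0 & w0[t] < 1
  sb <- rep(-Inf, n_bins - 1L)
  sb[valid] <- (mt * w0[t][valid] - m0[t][valid])^2 /
    (w0[t][valid] * (1 - w0[t][valid]))
  best <- which.max(sb)  # which.max takes the first (lowest) maximizer
  breaks[best + 1L]
}

#' Estimate tumor size bounds from the ROI histogram
#'
#' Splits the ROI at the Otsu level; the pixel counts of the smaller and
#' larger classes bound the plausible tumor size, and the level itself seeds
#' the region-growing threshold.
#'
#' @param image h x w numeric matrix (typically after filtering).
#' @param roi an `roi_box`.
#' @return a `size_estimate`: list with `lower_px`, `upper_px`, `otsu_level`.
#' @export
estimate_tumor_size <- function(image, roi) {
  sub <- image[roi_rows(roi), roi_cols(roi)]
  level <- otsu_threshold(sub)
  n_dark <- sum(sub <= level)
  n_bright <- sum(sub > level)
  structure(list(lower_px = min(n_dark, n_bright),
                 upper_px = max(n_dark, n_bright),
                 otsu_level = level),
            class = "size_estimate")
}

#' Select seed pixels from the central third of the ROI
#'
#' Returns the `k` brightest pixels within the central third of the ROI along
#' both axes, ties broken by row-major order.  If `k` exceeds the central
#' region size it is capped with a warning.
#'
#' @param image h x w numeric matrix.
#' @param roi an `roi_box`.
#' @param k number of seeds (>= 1).
#' @return k x 2 integer matrix of (row, col) image coordinates.
#' @export
select_seeds <- function(image, roi, k = 5L) {
  stopifnot(k >= 1)
  d <- roi_dims(roi)
  third <- function(n) {
    a <- floor(n / 3) + 1L
    b <- n - floor(n / 3)
    a:b
  }
  rows <- roi$row0 - 1L + third(d[1])
  cols <- roi$col0 - 1L + third(d[2])
  grid <- expand.grid(row = rows, col = cols)
  if (k > nrow(grid)) {
    warning("k capped to central-region size (", nrow(grid), ")")
    k <- nrow(grid)
  }
  vals <- image[cbind(grid$row, grid$col)]
  rowmajor <- (grid$row - 1L) * ncol(image) + grid$col
  ord <- order(-vals, rowmajor)[seq_len(k)]
  as.matrix(grid[ord, c("row", "col"), drop = FALSE])
}

neighbor_offsets <- function(connectivity) {
  if (connectivity == 4L) cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  else if (connectivity == 8L)
    cbind(rep(c(-1L, 0L, 1L), 3L), rep(c(-1L, 0L, 1L), each = 3L))[-5L, ]
  else stop("connectivity must be 4 or 8")
}

#' Seeded region growing with a running region mean
#'
#' Grows breadth-first from the seeds.  A frontier pixel with intensity `I`
#' joins the region iff `I > theta` and `mu - I < theta`, where `mu` is the
#' mean intensity of the region accepted so far (recomputed after every
#' accepted pixel); seeds always belong to the region.  Frontier pixels that
#' fail are re-examined as long as the previous pass accepted anything, since
#' `mu` shifts as the region grows; growth stops when a full pass accepts no
#' pixel.
#'
#' @param image h x w numeric matrix.
#' @param seeds n x 2 matrix of (row, col) 1-based coordinates.
#' @param theta intensity threshold.
#' @param connectivity 4 or 8.
#' @param mu_frozen optional fixed region mean; when supplied, `mu` is held at
#'   this value instead of the running mean (used for monotonicity analysis).
#' @return h x w 0/1 mask.
#' @export
region_grow <- function(image, seeds, theta, connectivity = 4L,
                        mu_frozen = NULL) {
  stopifnot(is.matrix(seeds), ncol(seeds) == 2, nrow(seeds) >= 1)
  h <- nrow(image); w <- ncol(image)
  if (any(seeds[, 1] < 1 | seeds[, 1] > h | seeds[, 2] < 1 | seeds[, 2] > w))
    stop("seed outside image")
  off <- neighbor_offsets(as.integer(connectivity))
  acc <- matrix(FALSE, h, w)
  acc[seeds] <- TRUE
  s_sum <- sum(image[seeds[!duplicated(seeds[, 1] + h * seeds[, 2]), , drop = FALSE]])
  s_n <- sum(acc)
  frontier <- unique_neighbors(seeds, off, h, w, acc)
  repeat {
    if (nrow(frontier) == 0) break
    accepted_any <- FALSE
    deferred <- matrix(0L, 0L, 2L)
    i <- 1L
    queue <- frontier
    while (i <= nrow(queue)) {
      r <- queue[i, 1L]; cc <- queue[i, 2L]
      i <- i + 1L
      if (acc[r, cc]) next
      I <- image[r, cc]
      mu <- if (is.null(mu_frozen)) s_sum / s_n else mu_frozen
      if (I > theta && (mu - I) < theta) {
        acc[r, cc] <- TRUE
        s_sum <- s_sum + I
        s_n <- s_n + 1L
        accepted_any <- TRUE
        nb <- sweep_neighbors(r, cc, off, h, w)
        nb <- nb[!acc[nb], , drop = FALSE]
        if (nrow(nb)) queue <- rbind(queue, nb)
      } else {
        deferred <- rbind(deferred, c(r, cc))
      }
    }
    if (!accepted_any || nrow(deferred) == 0) break
    frontier <- deferred[!acc[deferred], , drop = FALSE]
  }
  acc + 0L
}

sweep_neighbors <- function(r, cc, off, h, w) {
  nb <- cbind(r + off[, 1L], cc + off[, 2L])
  nb[nb[, 1L] >= 1 & nb[, 1L] <= h & nb[, 2L] >= 1 & nb[, 2L] <= w, ,
     drop = FALSE]
}

unique_neighbors <- function(pts, off, h, w, acc) {
  nb <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i)
    sweep_neighbors(pts[i, 1L], pts[i, 2L], off, h, w)))
  nb <- nb[!acc[nb], , drop = FALSE]
  nb[!duplicated(nb[, 1L] + h * nb[, 2L]), , drop = FALSE]
}

#' Configuration of the adaptive region-growing segmentation
#'
#' @param theta_step threshold decrement per adaptation round (intensity
#'   units; default 5% of the `[0, 1]` range).
#' @param max_rounds maximum number of adaptation rounds.
#' @param connectivity 4 or 8.
#' @param seed_k number of seed pixels.
#' @param bright_percentile,margin forwarded to [detect_roi()].
#' @param tail_weight forwarded to [clip_histogram()].
#' @param lambda forwarded to [laplacian_enhance()].
#' @export
region_grow_config <- function(theta_step = 0.05, max_rounds = 20L,
                               connectivity = 4L, seed_k = 5L,
                               bright_percentile = 0.95, margin = 2L,
                               tail_weight = 0.05, lambda = 0.5) {
  stopifnot(theta_step > 0, max_rounds >= 1, connectivity %in% c(4L, 8L))
  structure(list(theta_step = theta_step, max_rounds = as.integer(max_rounds),
                 connectivity = as.integer(connectivity),
                 seed_k = as.integer(seed_k),
                 bright_percentile = bright_percentile,
                 margin = as.integer(margin), tail_weight = tail_weight,
                 lambda = lambda),
            class = "region_grow_config")
}

#' Segment the suspected tumor region of an image
#'
#' Runs the full classical pipeline: ROI detection, contrast clipping,
#' median / mean / Laplacian filtering inside the ROI with the 5%-window
#' rule, Otsu-based size estimation, seed selection and adaptive seeded
#' region growing.  The growth threshold starts at the Otsu level; after each
#' pass, if the region is smaller than the lower size bound the threshold is
#' lowered by `theta_step` and growth continues; it stops once the region
#' reaches the lower bound, exceeds the upper bound, or `max_rounds` is
#' exhausted (returning the best mask so far with a warning).
#'
#' @param image h x w numeric matrix in `[0, 1]`.
#' @param config a [region_grow_config()].
#' @return h x w 0/1 mask in full-image coordinates, with attributes `roi`,
#'   `theta_trajectory`, `size_estimate` and `seeds`.
#' @export
segment_suspected_region <- function(image, config = region_grow_config()) {
  roi <- detect_roi(image, config$bright_percentile, config$margin)
  proc <- clip_histogram(image, config$tail_weight)
  window <- roi_window_size(roi)
  proc <- median_filter_roi(proc, roi, window)
  proc <- mean_filter_roi(proc, roi, window)
  proc <- laplacian_enhance(proc, roi, window, config$lambda)
  est <- tryCatch(estimate_tumor_size(proc, roi), error = function(e) {
    sub <- proc[roi_rows(roi), roi_cols(roi)]
    structure(list(lower_px = 1L, upper_px = length(sub),
                   otsu_level = mean(range(sub))),
              class = "size_estimate")
  })
  seeds <- select_seeds(proc, roi, config$seed_k)
  sub <- proc[roi_rows(roi), roi_cols(roi)]
  seeds_local <- cbind(seeds[, 1L] - roi$row0 + 1L, seeds[, 2L] - roi$col0 + 1L)
  theta <- est$otsu_level
  best <- NULL; best_size <- -1L
  trajectory <- numeric(0)
  for (round in seq_len(config$max_rounds)) {
    trajectory <- c(trajectory, theta)
    m <- region_grow(sub, seeds_local, theta, config$connectivity)
    size <- sum(m)
    if (size > best_size) { best <- m; best_size <- size }
    if (size >= est$lower_px || size > est$upper_px) break
    theta <- theta - config$theta_step
    if (round == config$max_rounds)
      warning("max_rounds exhausted; returning best-so-far mask")
    if (theta <= 0) break
  }
  out <- matrix(0L, nrow(image), ncol(image))
  out[roi_rows(roi), roi_cols(roi)] <- best
  attr(out, "roi") <- roi
  attr(out, "theta_trajectory") <- trajectory
  attr(out, "size_estimate") <- est
  attr(out, "seeds") <- seeds
  out
}
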