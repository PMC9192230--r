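# Independent oracles and small fixture builders shared across tests.

# Brute-force ellipse rasterization: count pixels whose center satisfies the
# (axis-aligned) ellipse inequality, by explicit double loop.
oracle_ellipse_count <- function(h, w, center, a, b) {
  n <- 0L
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    if (((r - center[1]) / a)^2 + ((cc - center[2]) / b)^2 <= 1) n <- n + 1L
  }
  n
}

# Flood fill oracle for region growing with a FIXED mean mu: the admissible
# set {I > theta & mu - I < theta} is order-independent, so the grown region
# is the connected component of that set containing the seeds (plus the
# seeds themselves).  Repeat-scan until fixpoint.
oracle_flood_fill <- function(image, seeds, theta, mu, connectivity = 4L) {
  h <- nrow(image); w <- ncol(image)
  ok <- image > theta & (mu - image) < theta
  acc <- matrix(FALSE, h, w)
  acc[seeds] <- TRUE
  off <- if (connectivity == 4L) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
         else Filter(Negate(is.null),
                     unlist(lapply(-1:1, function(a) lapply(-1:1, function(b)
                       if (a || b) c(a, b))), recursive = FALSE))
  repeat {
    changed <- FALSE
    for (r in seq_len(h)) for (cc in seq_len(w)) {
      if (acc[r, cc] || !ok[r, cc]) next
      for (d in off) {
        rr <- r + d[1]; c2 <- cc + d[2]
        if (rr >= 1 && rr <= h && c2 >= 1 && c2 <= w && acc[rr, c2]) {
          acc[r, cc] <- TRUE
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  acc + 0L
}

# Exhaustive Otsu search done independently: for each of the 256 candidate
# bin-boundary levels, split the raw pixel values and compute the
# between-class variance directly from the two groups.
oracle_otsu <- function(v, n_bins = 256L) {
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  best_level <- NA_real_; best_var <- -Inf
  for (t in seq_len(n_bins - 1L)) {
    level <- breaks[t + 1L]
    lo <- v[v <= level]; hi <- v[v > level]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v)
    bv <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (bv > best_var + 1e-15) { best_var <- bv; best_level <- level }
  }
  best_level
}

# Row-normalized softmax computed naively (no max shift), for small inputs.
oracle_softmax_rows <- function(m) t(apply(m, 1, function(r) exp(r) / sum(exp(r))))

# connectivity check: is the set of 1-pixels 4/8-connected?
is_connected_mask <- function(mask, connectivity = 4L) {
  pts <- which(mask == 1, arr.ind = TRUE)
  if (nrow(pts) <= 1) return(TRUE)
  seed <- pts[1, , drop = FALSE]
  comp <- oracle_flood_fill((mask == 1) + 0, seed, theta = 0.5, mu = 1,
                            connectivity = connectivity)
  all(comp[mask == 1] == 1)
}

# small noiseless single-ellipse phantom used across preprocessing tests
clean_phantom <- function(seed = 1L, noise_sd = 0.02) {
  generate_phantom(phantom_spec(image_size = c(64L, 64L), n_tumors = 1L,
                                semi_axis_range = c(7, 12),
                                noise_sd = noise_sd, edge_blur_sigma = 1,
                                seed = seed))
}

# binary-classification phantom mix: "effective" = large clear tumor,
# "difficult" = small, dim, blurred tumor
make_cls_items <- function(n_easy, n_hard, seed, size = 32L) {
  easy_spec <- phantom_spec(image_size = c(size, size), n_tumors = 1L,
                            semi_axis_range = c(0.2 * size, 0.3 * size),
                            fg_intensity = 0.9, bg_intensity = 0.2,
                            noise_sd = 0.03, edge_blur_sigma = 1)
  hard_spec <- phantom_spec(image_size = c(size, size), n_tumors = 1L,
                            semi_axis_range = c(1.5, 0.13 * size),
                            fg_intensity = 0.45, bg_intensity = 0.2,
                            noise_sd = 0.08, edge_blur_sigma = 2)
  easy <- generate_dataset(easy_spec, n_easy, seed = seed)
  hard <- generate_dataset(hard_spec, n_hard, seed = seed + 1L)
  c(lapply(easy, function(it) list(image = it$image, label = 1)),
    lapply(hard, function(it) list(image = it$image, label = 0)))
}
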