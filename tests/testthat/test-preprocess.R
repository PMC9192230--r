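test_that("detect_roi boxes bright regions and rejects constant images", {
  img <- matrix(0.1, 20, 20)
  img[8:10, 12:14] <- 0.9
  roi <- detect_roi(img, bright_percentile = 0.95, margin = 0L)
  expect_equal(unclass(roi)[c("row0", "col0", "row1", "col1")],
               list(row0 = 8L, col0 = 12L, row1 = 10L, col1 = 14L))
  # margin expands but clips at the frame
  roi2 <- detect_roi(img, bright_percentile = 0.95, margin = 50L)
  expect_equal(c(roi2$row0, roi2$col0, roi2$row1, roi2$col1), c(1, 1, 20, 20))
  # bright everywhere -> (margin-completed) full-frame box
  checker <- matrix(c(0.9, 1), 16, 16)
  roi3 <- detect_roi(checker, bright_percentile = 0.5, margin = 1L)
  expect_equal(c(roi3$row0, roi3$col0, roi3$row1, roi3$col1), c(1, 1, 16, 16))
  expect_error(detect_roi(matrix(0.5, 8, 8)), "no suspicious region")
})

test_that("clip_histogram maps the 5% tails to 0/1 and preserves order", {
  set.seed(1)
  img <- matrix(runif(10000), 100, 100)
  out <- clip_histogram(img, 0.05)
  lo <- quantile(img, 0.05); hi <- quantile(img, 0.95)
  expect_equal(out[img <= lo], rep(0, sum(img <= lo)))
  expect_equal(out[img >= hi], rep(1, sum(img >= hi)))
  # interior pixels rescaled linearly; ranking preserved
  interior <- img > lo & img < hi
  expect_equal(out[interior], (img[interior] - lo) / (hi - lo))
  ord <- order(img)
  expect_true(!is.unsorted(out[ord]))
  # constant image unchanged
  flat <- matrix(0.4, 5, 5)
  expect_identical(clip_histogram(flat), flat)
})

test_that("roi_window_size follows the 5%-of-longer-side odd rule", {
  expect_equal(roi_window_size(roi_box(1, 1, 100, 60)), 5)
  expect_equal(roi_window_size(roi_box(1, 1, 20, 20)), 3)
  expect_equal(roi_window_size(roi_box(1, 1, 101, 40)), 7)
})

test_that("ROI filters touch only the ROI and behave on known inputs", {
  base <- matrix(0.5, 20, 20)
  roi <- roi_box(5, 5, 15, 15)

  # constant ROI: median/mean identity, Laplacian term zero
  expect_equal(median_filter_roi(base, roi, 3), base)
  expect_equal(mean_filter_roi(base, roi, 3), base)
  expect_equal(laplacian_enhance(base, roi, 3), base)

  # a single impulse inside a constant ROI is removed by the 3x3 median
  imp <- base
  imp[10, 10] <- 1
  med <- median_filter_roi(imp, roi, 3)
  expect_equal(med[10, 10], 0.5)

  # mean filter pulls a checkerboard toward 0.5 (explicit 3x3 average)
  cb <- matrix(rep(c(0, 1), length.out = 400), 20, 20)
  mn <- mean_filter_roi(cb, roi, 3)
  inner <- mn[7:13, 7:13]
  expect_true(all(abs(inner - 0.5) < 0.25))
  expect_equal(mn[1:4, ], cb[1:4, ])  # untouched outside ROI

  # filters only modify ROI pixels
  imp2 <- imp; imp2[2, 2] <- 0.9
  expect_equal(median_filter_roi(imp2, roi, 3)[2, 2], 0.9)
  expect_error(median_filter_roi(base, roi_box(1, 1, 3, 3), 5), "larger")
})

test_that("otsu_threshold matches an exhaustive independent search", {
  # bimodal: equal counts at 50/255 and 200/255
  v <- c(rep(50 / 255, 100), rep(200 / 255, 100))
  th <- otsu_threshold(v)
  expect_gt(th, 50 / 255)
  expect_lt(th, 200 / 255)

  set.seed(3)
  for (i in 1:5) {
    x <- c(rnorm(300, 0.3, 0.05), rnorm(120, 0.75, 0.06))
    x <- pmin(pmax(x, 0), 1)
    expect_equal(otsu_threshold(x), oracle_otsu(x), tolerance = 1e-12)
  }
  # cross-check class separation against EBImage's Otsu on an image
  img <- matrix(pmin(pmax(c(rnorm(2000, 0.25, 0.05), rnorm(2096, 0.8, 0.05)),
                          0), 1), 64, 64)
  ours <- otsu_threshold(img)
  ref <- EBImage::otsu(EBImage::Image(img), range = range(img))
  expect_equal(sum(img > ours), sum(img > ref))
  expect_error(otsu_threshold(rep(0.5, 10)), "single-valued")
})

test_that("estimate_tumor_size splits the ROI into size bounds", {
  img <- matrix(0.1, 20, 20)
  img[8:13, 8:13] <- 0.9
  est <- estimate_tumor_size(img, roi_box(1, 1, 20, 20))
  expect_equal(est$lower_px, 36)
  expect_equal(est$upper_px, 364)
  expect_gt(est$otsu_level, 0.1)
  expect_lt(est$otsu_level, 0.9)
  # symmetric half-bright split
  half <- matrix(rep(c(0.2, 0.8), each = 200), 20, 20)
  est2 <- estimate_tumor_size(half, roi_box(1, 1, 20, 20))
  expect_equal(est2$lower_px, est2$upper_px)
})

test_that("select_seeds picks the brightest central pixels", {
  img <- matrix(0.2, 30, 30)
  roi <- roi_box(1, 1, 30, 30)
  img[15, 16] <- 0.95
  expect_equal(unname(select_seeds(img, roi, 1)), matrix(c(15L, 16L), 1)[, , drop = FALSE])

  # flat center: row-major tie-break, first 3 in reading order
  flat <- matrix(0.5, 9, 9)
  s <- select_seeds(flat, roi_box(1, 1, 9, 9), 3)
  expect_equal(unname(s), cbind(c(4L, 4L, 4L), c(4L, 5L, 6L)))

  # bright block at the corner is outside the central third: brute-force
  # top-k within the central window ignores it
  corner <- matrix(0.2, 30, 30)
  corner[1:3, 1:3] <- 1
  corner[14:16, 14:16] <- 0.6
  s2 <- select_seeds(corner, roi, 4)
  expect_true(all(s2[, 1] >= 11 & s2[, 1] <= 20))
  expect_true(all(corner[s2] == 0.6))
  expect_warning(select_seeds(flat, roi_box(1, 1, 3, 3), 99), "capped")
})

test_that("region_grow honors both intensity conditions (flood-fill oracle)", {
  img <- matrix(0.2, 5, 5)
  img[2:4, 2:4] <- 0.8
  m <- region_grow(img, cbind(3L, 3L), theta = 0.4)
  expect_equal(sum(m), 9)
  expect_equal(m, oracle_flood_fill(img, cbind(3L, 3L), 0.4, 0.8))

  # theta above the maximum: region = seeds only
  m2 <- region_grow(img, cbind(3L, 3L), theta = 0.95)
  expect_equal(sum(m2), 1)

  # theta ~ 0 admits the connected component of positive pixels
  img3 <- matrix(0, 7, 7)
  img3[2:3, 2:3] <- 0.5
  img3[6:7, 6:7] <- 0.5  # disconnected from the seed component
  m3 <- region_grow(img3, cbind(2L, 2L), theta = 1e-9)
  expect_equal(m3, oracle_flood_fill(img3, cbind(2L, 2L), 1e-9, 0.5))
  expect_equal(sum(m3), 4)
  expect_error(region_grow(img, cbind(9L, 1L), 0.5), "seed outside")
})

test_that("region_grow output is connected, contains seeds, monotone in theta", {
  set.seed(42)
  for (rep in 1:4) {
    it <- clean_phantom(seed = rep)
    seeds <- which(it$mask == 1, arr.ind = TRUE)[1:2, , drop = FALSE]
    for (conn in c(4L, 8L)) {
      m <- region_grow(it$image, seeds, theta = 0.4, connectivity = conn)
      expect_true(all(m[seeds] == 1))
      expect_true(is_connected_mask(m, conn))
    }
    # frozen-mu monotonicity: lower theta grows a superset
    hi <- region_grow(it$image, seeds, theta = 0.5, mu_frozen = 0.7)
    lo <- region_grow(it$image, seeds, theta = 0.4, mu_frozen = 0.7)
    expect_true(all(lo[hi == 1] == 1))
    # and each agrees with the order-independent flood-fill oracle
    expect_equal(hi, oracle_flood_fill(it$image, seeds, 0.5, 0.7))
    expect_equal(lo, oracle_flood_fill(it$image, seeds, 0.4, 0.7))
  }
})

test_that("segment_suspected_region recovers clean phantoms", {
  dscs <- vapply(1:5, function(s) {
    it <- clean_phantom(seed = s)
    m <- segment_suspected_region(it$image)
    roi <- attr(m, "roi")
    # no pixels outside the ROI box
    outside <- m
    outside[roi$row0:roi$row1, roi$col0:roi$col1] <- 0L
    expect_equal(sum(outside), 0)
    dsc_from_masks(m, it$mask)
  }, numeric(1))
  expect_gt(mean(dscs), 0.8)

  # noiseless tumor-free phantom is constant: ROI detection refuses it
  flat <- generate_phantom(phantom_spec(n_tumors = 0L, noise_sd = 0,
                                        seed = 3L))
  expect_error(segment_suspected_region(flat$image), "no suspicious region")
  # noisy tumor-free phantom: whatever grows stays confined to the ROI box
  noisy <- generate_phantom(phantom_spec(n_tumors = 0L, noise_sd = 0.02,
                                         seed = 3L))
  res <- tryCatch(segment_suspected_region(noisy$image), error = identity)
  if (!inherits(res, "error")) {
    roi <- attr(res, "roi")
    outside <- res
    outside[roi$row0:roi$row1, roi$col0:roi$col1] <- 0L
    expect_equal(sum(outside), 0)
  }
})
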