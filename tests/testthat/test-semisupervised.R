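test_that("supervised cross-entropy matches hand computations", {
  expect_equal(supervised_loss(1, 0.8), -log(0.8), tolerance = 1e-12)
  expect_equal(supervised_loss(1, 0.8), 0.22314, tolerance = 1e-4)
  expect_equal(supervised_loss(c(1, 0), c(0.8, 0.2)), -log(0.8),
               tolerance = 1e-12)
  # perfect predictions go to ~0 under clipping, never -Inf
  expect_lt(supervised_loss(c(1, 0), c(1, 0)), 1e-6)
  expect_true(is.finite(supervised_loss(1, 0)))
  expect_error(supervised_loss(c(1, 0), 0.5), "length mismatch")
})

test_that("KL divergence matches closed form and satisfies Gibbs' inequality", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0, tolerance = 1e-12)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)), 0.14384,
               tolerance = 1e-4)
  set.seed(1)
  for (i in 1:20) {
    p <- as_two_point(runif(1))
    q <- as_two_point(runif(1))
    expect_gte(kl_divergence(p, q), 0)
  }
  expect_error(kl_divergence(c(0.5, 0.6), c(0.5, 0.5)), "probability")
})

test_that("JS divergence is symmetric, bounded by ln 2, zero iff equal", {
  p <- as_two_point(0.3); q <- as_two_point(0.85)
  expect_equal(js_consistency_loss(p, p), 0, tolerance = 1e-10)
  expect_equal(js_consistency_loss(p, q), js_consistency_loss(q, p),
               tolerance = 1e-12)
  set.seed(2)
  for (i in 1:20) {
    a <- as_two_point(runif(1)); b <- as_two_point(runif(1))
    expect_lte(js_consistency_loss(a, b), log(2) + 1e-9)
    expect_gte(js_consistency_loss(a, b), 0)
  }
  # opposite point masses approach the ln 2 bound
  e <- 1e-6
  expect_equal(js_consistency_loss(as_two_point(1 - e), as_two_point(e)),
               log(2), tolerance = 1e-4)
})

test_that("total loss is additive with a consistency weight", {
  expect_equal(total_loss(0.3, 0.2), 0.5)
  expect_equal(total_loss(0.3, 0.2, weight = 0), 0.3)
  expect_equal(total_loss(0.3, 0), 0.3)
})

test_that("EMA teacher update is an elementwise convex combination", {
  cfg <- net_config(depth = 2, base_width = 8, gn_groups = 4,
                    input_size = c(8, 8))
  cls <- build_classifier(cfg, seed = 1)
  st <- teacher_student_state(cls, alpha = 0.99)
  # push the student somewhere else, then update
  st$student <- lapply(st$student, function(p) p + 1)
  up <- ema_update(st)
  for (nm in names(up$teacher)) {
    expect_equal(up$teacher[[nm]], 0.99 * st$teacher[[nm]] +
                   0.01 * st$student[[nm]], tolerance = 1e-12)
    lo <- pmin(st$teacher[[nm]], st$student[[nm]])
    hi <- pmax(st$teacher[[nm]], st$student[[nm]])
    expect_true(all(up$teacher[[nm]] >= lo - 1e-12 &
                    up$teacher[[nm]] <= hi + 1e-12))
  }
  # boundary decays
  st0 <- st; st0$alpha <- 0
  expect_equal(ema_update(st0)$teacher, st$student)
  st1 <- st; st1$alpha <- 1
  expect_equal(ema_update(st1)$teacher, st$teacher)
})

test_that("teacher parameters decay geometrically toward a frozen student", {
  cfg <- net_config(depth = 2, base_width = 8, gn_groups = 4,
                    input_size = c(8, 8))
  st <- teacher_student_state(build_classifier(cfg, seed = 2), alpha = 0.9)
  st$teacher <- lapply(st$teacher, function(p) p + 2)  # displace the teacher
  dist <- function(s) sqrt(sum(mapply(function(a, b) sum((a - b)^2),
                                      s$teacher, s$student)))
  d0 <- dist(st)
  for (k in 1:3) {
    st <- ema_update(st)
    # ||theta' - theta|| shrinks by exactly alpha per update
    expect_equal(dist(st), d0 * 0.9^k, tolerance = 1e-9)
  }
})

test_that("the differentiable JS consistency matches the reference and its
          gradient passes finite differences", {
  u <- asNamespace("uatransnet")
  z <- c(0.3, -0.5, 1.2)
  q <- c(0.7, 0.2, 0.9)
  u$ag_reset()
  zn <- u$ag_leaf(z)
  loss <- u$ag_js_binary(zn, q)
  # forward agrees with the distribution-level JS, averaged over samples
  p <- 1 / (1 + exp(-z))
  ref <- mean(vapply(seq_along(z), function(i)
    js_consistency_loss(as_two_point(p[i]), as_two_point(q[i])), numeric(1)))
  expect_equal(loss$val, ref, tolerance = 1e-10)
  # backward agrees with central finite differences
  u$ag_backward(loss)
  eps <- 1e-6
  for (i in seq_along(z)) {
    zp <- z; zp[i] <- zp[i] + eps
    zm <- z; zm[i] <- zm[i] - eps
    at <- function(zz) { u$ag_reset(); u$ag_js_binary(u$ag_leaf(zz), q)$val }
    expect_equal(zn$grad[i], (at(zp) - at(zm)) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("mean_teacher_step trains and reduces to supervised at weight 0", {
  cfg <- net_config(depth = 2, base_width = 8, gn_groups = 4,
                    input_size = c(16, 16))
  labeled <- make_cls_items(3, 3, seed = 10, size = 16)
  unlabeled <- lapply(make_cls_items(3, 3, seed = 20, size = 16), `[[`,
                      "image")
  st <- teacher_student_state(build_classifier(cfg, seed = 3), alpha = 0.95)
  set.seed(1)
  r1 <- mean_teacher_step(st, labeled, unlabeled, cons_weight = 1)
  expect_true(all(is.finite(r1$losses)))
  expect_gte(r1$losses[["consistency"]], 0)
  expect_equal(r1$losses[["total"]],
               r1$losses[["supervised"]] + r1$losses[["consistency"]],
               tolerance = 1e-10)
  # with weight 0 the consistency term vanishes from the loss
  set.seed(1)
  r0 <- mean_teacher_step(st, labeled, unlabeled, cons_weight = 0)
  expect_equal(r0$losses[["consistency"]], 0)
  expect_equal(r0$losses[["total"]], r0$losses[["supervised"]])
  expect_error(mean_teacher_step(st, list()), "nonempty")
})

test_that("mean-teacher training is reproducible under a fixed seed", {
  cfg <- net_config(depth = 2, base_width = 8, gn_groups = 4,
                    input_size = c(16, 16))
  labeled <- make_cls_items(3, 3, seed = 30, size = 16)
  unlabeled <- lapply(make_cls_items(2, 2, seed = 40, size = 16), `[[`,
                      "image")
  run <- function() {
    st <- teacher_student_state(build_classifier(cfg, seed = 4), alpha = 0.9)
    train_mean_teacher(st, labeled, unlabeled, epochs = 2, batch_size = 3,
                       seed = 99)
  }
  s1 <- run(); s2 <- run()
  expect_identical(s1$student, s2$student)
  expect_identical(s1$teacher, s2$teacher)
  expect_identical(s1$history, s2$history)
})

test_that("partition_dataset splits by confidence with sane boundaries", {
  cfg <- net_config(depth = 2, base_width = 8, gn_groups = 4,
                    input_size = c(16, 16))
  cls <- build_classifier(cfg, seed = 5)
  imgs <- lapply(make_cls_items(4, 4, seed = 50, size = 16), `[[`, "image")
  p0 <- partition_dataset(cls, imgs, confidence_threshold = 0)
  expect_length(p0$effective, 8)
  expect_length(p0$difficult, 0)
  p1 <- partition_dataset(cls, imgs, confidence_threshold = 1)
  expect_length(p1$effective, 0)
  expect_length(p1$difficult, 8)
  pm <- partition_dataset(cls, imgs, confidence_threshold = 0.5)
  expect_setequal(c(pm$effective, pm$difficult), seq_along(imgs))
  expect_equal(sum(pm$proportions), 1)
})
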