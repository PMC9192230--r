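# Mean-teacher dataset optimization: supervised cross-entropy plus a
# Jensen-Shannon consistency loss between student and teacher predictions on
# unlabeled data, with the teacher an exponential moving average (EMA) of the
# student, and the resulting effective/difficult dataset partition.

EPS_PROB <- 1e-7

clip_prob <- function(p) pmin(pmax(p, EPS_PROB), 1 - EPS_PROB)

#' Mean binary cross-entropy (supervised loss)
#'
#' `-(1/n) * sum(l * log p + (1 - l) * log(1 - p))` in natural log, with
#' probabilities clipped at 1e-7.
#'
#' @param labels 0/1 vector.
#' @param preds probability vector of the same length.
#' @export
supervised_loss <- function(labels, preds) {
  if (length(labels) != length(preds)) stop("length mismatch")
  stopifnot(length(labels) >= 1, all(labels %in% c(0, 1)))
  p <- clip_prob(preds)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

check_dist <- function(p, name) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop(name, " is not a probability distribution (mass must be 1)")
}

#' Kullback-Leibler divergence
#'
#' `KL(P || Q) = sum p * ln(p / q)` in nats, with clipping at 1e-7; both
#' arguments must be probability distributions (mass 1 within 1e-6).
#'
#' @param p,q probability vectors over the same support.
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("distributions must share a support")
  check_dist(p, "p"); check_dist(q, "q")
  pc <- clip_prob(p); qc <- clip_prob(q)
  sum(pc * log(pc / qc))
}

#' Jensen-Shannon consistency loss
#'
#' `JS(P, Q) = KL(P || M) / 2 + KL(Q || M) / 2` with `M = (P + Q) / 2`:
#' symmetric, nonnegative and bounded by ln 2.
#'
#' @param p,q probability vectors over the same support.
#' @export
js_consistency_loss <- function(p, q) {
  if (length(p) != length(q)) stop("distributions must share a support")
  check_dist(p, "p"); check_dist(q, "q")
  m <- (p + q) / 2
  0.5 * kl_divergence(p, m) + 0.5 * kl_divergence(q, m)
}

#' Total loss: supervised plus weighted consistency
#' @param sup supervised loss.
#' @param cons consistency loss.
#' @param weight consistency weight.
#' @export
total_loss <- function(sup, cons, weight = 1) {
  stopifnot(is.finite(sup), is.finite(cons), is.finite(weight))
  sup + weight * cons
}

#' Two-point distribution of a binary probability
#' @param p probability of the positive class.
#' @export
as_two_point <- function(p) c(p, 1 - p)

#' Create a teacher-student state
#'
#' The teacher starts as a copy of the student and thereafter tracks it by
#' exponential moving average with decay `alpha`.
#'
#' @param model a classifier `uat_model` (provides the architecture and the
#'   initial student parameters).
#' @param alpha EMA decay in `[0, 1]`.
#' @export
teacher_student_state <- function(model, alpha = 0.99) {
  stopifnot(inherits(model, "uat_model"), alpha >= 0, alpha <= 1)
  structure(list(model = model, student = model$params,
                 teacher = model$params, alpha = alpha,
                 opt = adam_init(model$params)),
            class = "teacher_student_state")
}

#' EMA update of the teacher parameters
#'
#' `theta'_t = alpha * theta'_{t-1} + (1 - alpha) * theta_t`, elementwise;
#' the student is untouched.  Every teacher parameter is a convex combination
#' of its previous value and the student's.
#'
#' @param state a `teacher_student_state`.
#' @export
ema_update <- function(state) {
  stopifnot(inherits(state, "teacher_student_state"))
  if (!identical(lapply(state$student, dim), lapply(state$teacher, dim)) ||
      !identical(names(state$student), names(state$teacher)))
    stop("student and teacher parameter collections are incongruent")
  a <- state$alpha
  state$teacher <- Map(function(th, st) a * th + (1 - a) * st,
                       state$teacher, state$student)
  state
}

#' One mean-teacher optimization step
#'
#' The student is run on the labeled batch (cross-entropy against the labels)
#' and on the unlabeled batch; the teacher is run on the unlabeled batch
#' under independent input-noise augmentation.  The student takes one Adam
#' step on `supervised + weight * JS(student, teacher)`, then the teacher is
#' EMA-updated.
#'
#' @param state a `teacher_student_state`.
#' @param batch_labeled list of `list(image, label)` with 0/1 labels;
#'   nonempty.
#' @param batch_unlabeled list of images (matrices); may be empty, in which
#'   case the step is purely supervised.
#' @param lr Adam learning rate.
#' @param cons_weight consistency weight.
#' @param noise_sd standard deviation of the Gaussian input noise used as
#'   augmentation on the unlabeled batch.
#' @return list with the updated `state` and the `losses` (supervised,
#'   consistency, total).
#' @export
mean_teacher_step <- function(state, batch_labeled, batch_unlabeled = list(),
                              lr = 1e-3, cons_weight = 1, noise_sd = 0.05) {
  stopifnot(inherits(state, "teacher_student_state"))
  if (length(batch_labeled) == 0) stop("labeled batch must be nonempty")
  cfg <- state$model$cfg
  noisy <- function(img) {
    if (noise_sd <= 0) return(img)
    pmin(pmax(img + matrix(stats::rnorm(length(img), 0, noise_sd),
                           nrow(img)), 0), 1)
  }
  # teacher predictions on independently augmented unlabeled inputs
  q <- vapply(batch_unlabeled, function(img)
    classifier_predict(state$model, noisy(img), params = state$teacher),
    numeric(1))

  ag_reset()
  lv <- lapply(state$student, ag_leaf)
  zl <- lapply(batch_labeled, function(it) {
    x <- ag_leaf(array(it$image, c(dim(it$image), 1L)))
    cls_forward_ag(lv, cfg, x)
  })
  z_lab <- ag_cat(zl)
  labels <- vapply(batch_labeled, `[[`, numeric(1), "label")
  sup <- ag_bce_logits(z_lab, labels)
  if (length(batch_unlabeled) > 0 && cons_weight > 0) {
    zu <- lapply(batch_unlabeled, function(img) {
      x <- ag_leaf(array(noisy(img), c(dim(img), 1L)))
      cls_forward_ag(lv, cfg, x)
    })
    cons <- ag_js_binary(ag_cat(zu), q)
    loss <- ag_add(sup, ag_scale(cons, cons_weight))
    cons_val <- cons$val
  } else {
    loss <- sup
    cons_val <- 0
  }
  ag_backward(loss)
  st <- adam_step(state$student, collect_grads(lv), state$opt, lr)
  state$student <- st$params
  state$opt <- st$state
  state <- ema_update(state)
  list(state = state,
       losses = c(supervised = sup$val, consistency = cons_val,
                  total = loss$val))
}

# concatenate scalar logit nodes into one vector node
ag_cat <- function(ns) {
  ag_node(vapply(ns, function(n) as.numeric(n$val), numeric(1)), ns,
          function(g) as.list(g))
}

#' Train a classifier with (or without) the mean-teacher scheme
#'
#' Runs epochs of [mean_teacher_step()] over shuffled mini-batches.  With
#' `cons_weight = 0` (or no unlabeled data) this reduces to plain supervised
#' training of the student.
#'
#' @param state a `teacher_student_state`.
#' @param labeled list of `list(image, label)` items.
#' @param unlabeled list of images.
#' @param epochs,batch_size training schedule.
#' @param lr Adam learning rate.
#' @param cons_weight consistency weight; when `ramp_up` is `TRUE` it is
#'   ramped linearly from 0 over the first half of training.
#' @param ramp_up linearly ramp the consistency weight.
#' @param noise_sd input-noise augmentation level.
#' @param seed RNG seed (shuffling and augmentation noise).
#' @return the final `teacher_student_state`, with a `history` data.frame of
#'   per-epoch losses attached.
#' @export
train_mean_teacher <- function(state, labeled, unlabeled = list(),
                               epochs = 10L, batch_size = 8L, lr = 1e-3,
                               cons_weight = 1, ramp_up = FALSE,
                               noise_sd = 0.05, seed = 1L) {
  stopifnot(inherits(state, "teacher_student_state"), length(labeled) >= 1)
  history <- data.frame()
  with_seed(seed, {
    for (epoch in seq_len(epochs)) {
      w <- if (ramp_up) cons_weight * min(1, epoch / max(1, epochs / 2))
           else cons_weight
      ord <- sample(length(labeled))
      uord <- if (length(unlabeled)) sample(length(unlabeled)) else integer(0)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      ubatches <- if (length(uord))
        split(uord, cut(seq_along(uord), length(batches), labels = FALSE))
      else NULL
      ep <- c(supervised = 0, consistency = 0, total = 0)
      for (bi in seq_along(batches)) {
        bu <- if (is.null(ubatches)) list() else unlabeled[ubatches[[bi]]]
        res <- mean_teacher_step(state, labeled[batches[[bi]]], bu,
                                 lr = lr, cons_weight = w,
                                 noise_sd = noise_sd)
        state <- res$state
        ep <- ep + res$losses
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, t(ep / length(batches))))
    }
  })
  state$history <- history
  state
}

#' Partition a dataset into effective and difficult parts
#'
#' Scores every item with the classifier's predicted probability of being an
#' effective (well-delineated) case; items at or above the confidence
#' threshold go to the effective part, the rest to the difficult part.
#'
#' @param model a classifier `uat_model`.
#' @param images list of images (matrices).
#' @param confidence_threshold cut on the predicted probability.
#' @param params optional parameter override (e.g. teacher weights).
#' @param ids item identifiers (default `seq_along(images)`).
#' @return a `partition_result`: list with `effective`, `difficult`,
#'   `scores` and `proportions`.
#' @export
partition_dataset <- function(model, images, confidence_threshold = 0.5,
                              params = NULL, ids = seq_along(images)) {
  scores <- vapply(images, function(img)
    classifier_predict(model, img, params = params), numeric(1))
  eff <- ids[scores >= confidence_threshold]
  structure(list(effective = eff, difficult = setdiff(ids, eff),
                 scores = stats::setNames(scores, ids),
                 proportions = c(effective = length(eff) / length(ids),
                                 difficult = 1 - length(eff) / length(ids))),
            class = "partition_result")
}
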