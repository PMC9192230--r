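# Optimization: Adam, the two-phase cosine-annealed learning-rate schedule,
# and the segmentation training / evaluation loops.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Two-phase cosine-annealed learning rate
#'
#' The base rate is `lr_initial` for the first half of training and
#' `lr_late` afterwards; cosine annealing over the full run is applied on
#' top of the base (reaching `eta_min` at the final epoch).
#'
#' @param epoch 1-based epoch index.
#' @param epochs total epochs.
#' @param lr_initial base rate for the first phase.
#' @param lr_late base rate after the switch epoch.
#' @param switch_epoch last epoch of the first phase (default `epochs / 2`).
#' @param cosine apply cosine annealing on top of the base rate.
#' @param eta_min floor of the annealed rate, as a fraction of the base.
#' @export
lr_schedule <- function(epoch, epochs, lr_initial = 1e-3, lr_late = 1e-4,
                        switch_epoch = NULL, cosine = TRUE, eta_min = 0.1) {
  if (is.null(switch_epoch)) switch_epoch <- floor(epochs / 2)
  base <- if (epoch <= switch_epoch) lr_initial else lr_late
  if (!cosine || epochs <= 1) return(base)
  frac <- (epoch - 1) / (epochs - 1)
  base * (eta_min + (1 - eta_min) * 0.5 * (1 + cos(pi * frac)))
}

seg_loss_node <- function(lv, cfg, item) {
  x <- ag_leaf(array(item$image, c(dim(item$image), 1L)))
  logits <- seg_forward_ag(lv, cfg, x)
  target <- array(item$mask, dim(logits$val))
  bce <- ag_bce_logits(logits, target)
  dice <- ag_dice_loss(ag_sigmoid(logits), target)
  ag_add(bce, dice)
}

collect_grads <- function(lv) lapply(lv, function(nd) nd$grad)

acc_grads <- function(acc, lv) {
  for (nm in names(lv)) {
    g <- lv[[nm]]$grad
    if (is.null(g)) next
    acc[[nm]] <- if (is.null(acc[[nm]])) g else acc[[nm]] + g
  }
  acc
}

#' Train a segmentation model on labeled images
#'
#' Minimizes binary cross-entropy plus soft Dice with Adam, mini-batch
#' gradient averaging, and the two-phase cosine-annealed schedule.  When
#' `val_items` is given, mean validation DSC (at threshold 0.5) is logged per
#' epoch.
#'
#' @param model a `uat_model` from [build_model()].
#' @param items list of `labeled_image` training items.
#' @param epochs number of epochs.
#' @param batch_size mini-batch size (gradients averaged per batch).
#' @param lr_initial,lr_late,cosine see [lr_schedule()].
#' @param val_items optional list of held-out `labeled_image`s.
#' @param seed RNG seed for shuffling.
#' @param frozen names of parameters excluded from optimization (their
#'   gradients are discarded), e.g. pinned fusion weights.
#' @param verbose print one line per epoch.
#' @return the trained model; `model$history` holds per-epoch mean loss,
#'   learning rate and validation DSC.
#' @export
train_segmenter <- function(model, items, epochs = 10L, batch_size = 8L,
                            lr_initial = 1e-3, lr_late = 1e-4, cosine = TRUE,
                            val_items = NULL, seed = 1L,
                            frozen = character(0), verbose = FALSE) {
  stopifnot(inherits(model, "uat_model"), model$task == "segmentation",
            length(items) >= 1)
  params <- model$params
  opt <- adam_init(params)
  history <- data.frame()
  orders <- with_seed(seed, lapply(seq_len(epochs), function(e)
    sample(length(items))))
  for (epoch in seq_len(epochs)) {
    lr <- lr_schedule(epoch, epochs, lr_initial, lr_late, cosine = cosine)
    ord <- orders[[epoch]]
    losses <- numeric(0)
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      gacc <- list()
      bl <- 0
      for (i in b) {
        ag_reset()
        lv <- lapply(params, ag_leaf)
        loss <- seg_loss_node(lv, model$cfg, items[[i]])
        ag_backward(loss)
        gacc <- acc_grads(gacc, lv)
        bl <- bl + loss$val
      }
      gacc <- lapply(gacc, function(g) g / length(b))
      gacc[frozen] <- NULL
      st <- adam_step(params, gacc, opt, lr)
      params <- st$params
      opt <- st$state
      losses <- c(losses, bl / length(b))
    }
    val_dsc <- NA_real_
    if (!is.null(val_items)) {
      model$params <- params
      val_dsc <- mean(vapply(val_items, function(it)
        dsc_from_masks(model_predict(model, it$image, threshold = 0.5),
                       it$mask), numeric(1)), na.rm = TRUE)
    }
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         loss = mean(losses),
                                         val_dsc = val_dsc))
    if (verbose)
      message(sprintf("epoch %d: lr %.2e loss %.4f val_dsc %.3f",
                      epoch, lr, mean(losses), val_dsc))
  }
  model$params <- params
  model$history <- history
  model
}

#' Evaluate a segmentation model on labeled images
#'
#' @param model a trained `uat_model`.
#' @param items list of `labeled_image`s.
#' @param threshold probability-to-mask threshold.
#' @return output of [aggregate_metrics()] over the predicted masks.
#' @export
evaluate_segmenter <- function(model, items, threshold = 0.5) {
  preds <- lapply(items, function(it)
    model_predict(model, it$image, threshold = threshold))
  aggregate_metrics(preds, lapply(items, `[[`, "mask"))
}
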