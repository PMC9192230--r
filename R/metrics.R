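# Pixel-wise segmentation metrics, confusion-matrix utilities, percent-change
# computation and stratified cohort splitting.

#' Confusion counts from a predicted and a true binary mask
#'
#' @param pred,truth equal-shaped 0/1 matrices.
#' @return a `confusion_counts`: list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_from_masks <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("mask shape mismatch")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("masks must be binary (0/1)")
  confusion_counts(tp = sum(pred == 1 & truth == 1),
                   fp = sum(pred == 1 & truth == 0),
                   fn = sum(pred == 0 & truth == 1),
                   tn = sum(pred == 0 & truth == 0))
}

#' @rdname confusion_from_masks
#' @param tp,fp,fn,tn nonnegative counts.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Segmentation metric suite from confusion counts
#'
#' Computes accuracy, precision, recall, intersection-over-union, Dice
#' similarity and F1.  Metrics with a zero denominator are reported as `NA`
#' (undefined), never silently as 0.
#'
#' @param c a `confusion_counts`.
#' @return a `metric_set`: named list with `acc`, `pre`, `rec`, `iou`, `dsc`,
#'   `f1`.
#' @export
compute_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$tp + c$fp + c$fn + c$tn
  if (total == 0) stop("all-zero confusion counts")
  pre <- safe_ratio(c$tp, c$tp + c$fp)
  rec <- safe_ratio(c$tp, c$tp + c$fn)
  f1 <- if (is.na(pre) || is.na(rec)) NA_real_ else
    safe_ratio(2 * pre * rec, pre + rec)
  structure(list(
    acc = safe_ratio(c$tp + c$tn, total),
    pre = pre,
    rec = rec,
    iou = safe_ratio(c$tp, c$tp + c$fp + c$fn),
    dsc = safe_ratio(2 * c$tp, 2 * c$tp + c$fp + c$fn),
    f1 = f1
  ), class = "metric_set")
}

#' Dice similarity coefficient between two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; `NA` when both masks are empty.
#'
#' @param a,b equal-shaped 0/1 matrices.
#' @export
dsc_from_masks <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shape mismatch")
  s <- sum(a == 1) + sum(b == 1)
  if (s == 0) return(NA_real_)
  2 * sum(a == 1 & b == 1) / s
}

#' Percent change between two counts
#'
#' `100 * (after - before) / before`.
#'
#' @param before positive baseline count.
#' @param after count after the intervention.
#' @export
percent_change <- function(before, after) {
  if (before <= 0) stop("before must be > 0")
  100 * (after - before) / before
}

#' Stratified train/test split
#'
#' Splits records into train and test sets so that each stratum contributes
#' train cases in (approximately) the global `train_fraction`, using
#' largest-remainder rounding so the global train count is hit exactly.
#' Deterministic given the seed.
#'
#' @param ids vector of record identifiers.
#' @param strata vector of stratum labels, same length as `ids`.
#' @param train_fraction fraction in (0, 1).
#' @param seed integer RNG seed.
#' @return a `split_plan`: list with `train_ids`, `test_ids`, `strata`,
#'   `seed` and the realized `train_fraction`.
#' @export
stratified_split <- function(ids, strata, train_fraction, seed = 1L) {
  stopifnot(length(ids) == length(strata), length(ids) >= 2)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be strictly between 0 and 1")
  n <- length(ids)
  target <- round(train_fraction * n)
  target <- min(max(target, 1L), n - 1L)
  levs <- unique(strata)
  sizes <- vapply(levs, function(l) sum(strata == l), numeric(1))
  exact <- sizes * target / n
  base <- floor(exact)
  rem <- target - sum(base)
  # largest remainders get the leftover train slots
  extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
  per_stratum <- base
  per_stratum[extra] <- per_stratum[extra] + 1L
  train <- with_seed(seed, {
    unlist(lapply(seq_along(levs), function(i) {
      members <- ids[strata == levs[i]]
      if (per_stratum[i] == 0) return(members[0])
      sample(members, per_stratum[i])
    }), use.names = FALSE)
  })
  structure(list(train_ids = train,
                 test_ids = setdiff(ids, train),
                 strata = strata, seed = seed,
                 train_fraction = length(train) / n),
            class = "split_plan")
}

#' Aggregate per-image metrics over a test set
#'
#' Computes metrics per image, reports their mean and standard deviation
#' (macro average) alongside the metrics of the pooled confusion counts
#' (micro average).
#'
#' @param preds,truths lists of equal-shaped 0/1 matrices.
#' @return list with `per_image` (data.frame), `macro` (mean and sd per
#'   metric) and `micro` (a `metric_set` from pooled counts).
#' @export
aggregate_metrics <- function(preds, truths) {
  stopifnot(length(preds) == length(truths), length(preds) >= 1)
  rows <- lapply(seq_along(preds), function(i) {
    m <- compute_metrics(confusion_from_masks(preds[[i]], truths[[i]]))
    as.data.frame(unclass(m))
  })
  per_image <- do.call(rbind, rows)
  pooled <- Reduce(function(a, b) confusion_counts(a$tp + b$tp, a$fp + b$fp,
                                                   a$fn + b$fn, a$tn + b$tn),
                   lapply(seq_along(preds), function(i)
                     confusion_from_masks(preds[[i]], truths[[i]])))
  list(per_image = per_image,
       macro = list(mean = colMeans(per_image, na.rm = TRUE),
                    sd = apply(per_image, 2, stats::sd, na.rm = TRUE)),
       micro = compute_metrics(pooled))
}
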