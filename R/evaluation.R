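#' Dice overlap coefficient between two binary masks
#'
#' `2|P & G| / (|P| + |G|)`, with an additive epsilon guarding the
#' empty-vs-empty case (which scores 1: nothing to find, nothing found).
#'
#' @param pred,truth binary arrays of equal shape.
#' @param epsilon smoothing constant.
#' @return A number in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth, epsilon = 1e-5) {
  check_same_shape(pred, truth)
  (2 * sum(pred * truth) + epsilon) / (sum(pred) + sum(truth) + epsilon)
}

#' Evaluate a segmentation model slice-wise and subject-wise
#'
#' Computes the two protocol metrics on a list of labeled volumes: the 2D Dice
#' ratio, scored slice by slice over all test slices, and the 3D Dice ratio,
#' scored per subject after re-stacking the slice predictions into a volume.
#' Probabilities are binarized by strict comparison `p > threshold`
#' (so an all-0.5 map at threshold 0.5 predicts background everywhere). Slices
#' where both the prediction and the ground truth are empty are excluded from
#' the 2D mean — the epsilon smoothing would score them 1.0 and inflate the
#' average.
#'
#' @param model a `spikeseg_ann` or `spikeseg_snn` (anything with a `predict`
#'   method returning probabilities).
#' @param volumes list of `labeled_volume`s.
#' @param threshold decision threshold on the probability, default 0.5.
#' @param axis slicing axis.
#' @param ... passed to `predict` (e.g. `T`, `batch_size`).
#' @return An object of class `dice_report`.
#' @export
evaluate_model <- function(model, volumes, threshold = 0.5, axis = 1L, ...) {
  if (!length(volumes)) stop("empty test set")
  sl <- stack_slices(volumes, axis)
  probs <- stats::predict(model, sl$x, ...)
  report_from_probs(probs, sl, threshold)
}

report_from_probs <- function(probs, sl, threshold) {
  pred <- (probs > threshold) * 1
  n <- dim(pred)[4L]
  d2 <- rep(NA_real_, n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    p <- pred[, , 1L, i]; g <- sl$y[, , 1L, i]
    keep[i] <- sum(p) + sum(g) > 0
    d2[i] <- dice_coefficient(p, g)
  }
  subj <- unique(sl$subject)
  d3 <- vapply(subj, function(s) {
    ix <- sl$subject == s
    dice_coefficient(pred[, , 1L, ix, drop = FALSE],
                     sl$y[, , 1L, ix, drop = FALSE])
  }, 1)
  d2k <- d2[keep]
  structure(list(
    dice_2d_mean = mean(d2k), dice_2d_sd = stats::sd(d2k),
    dice_3d_mean = mean(d3), dice_3d_sd = stats::sd(d3),
    per_slice = data.frame(subject = sl$subject, slice = sl$slice,
                           dice = d2, scored = keep),
    per_subject = data.frame(subject = subj, dice = as.numeric(d3)),
    threshold = threshold), class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("Dice @ threshold %.2f: 2D %.4f +/- %.4f (%d slices), 3D %.4f +/- %.4f (%d subjects)\n",
              x$threshold, x$dice_2d_mean, x$dice_2d_sd, sum(x$per_slice$scored),
              x$dice_3d_mean, x$dice_3d_sd, nrow(x$per_subject)))
  invisible(x)
}

#' Output-threshold sweep
#'
#' Evaluates the fixed probability maps of a model under a grid of decision
#' thresholds (probabilities are computed once and re-thresholded). The default
#' grid is the fine 0.43-0.54 grid in steps of 0.01; `coarse = TRUE` selects
#' 0.1-0.6 in steps of 0.1. Note that moving the threshold from 0.5 to `t` is
#' exactly equivalent, on the probability scale, to scaling the outputs by
#' `0.5 / t` and keeping the 0.5 threshold.
#'
#' @param model a model with a `predict` method.
#' @param volumes list of `labeled_volume`s.
#' @param thresholds grid of thresholds in (0, 1).
#' @param coarse use the coarse 0.1-0.6 grid.
#' @param axis slicing axis.
#' @param ... passed to `predict`.
#' @return A `data.frame` with columns `threshold`, `dice_2d`, `dice_3d`.
#' @export
threshold_sweep <- function(model, volumes,
                            thresholds = seq(0.43, 0.54, by = 0.01),
                            coarse = FALSE, axis = 1L, ...) {
  if (coarse) thresholds <- seq(0.1, 0.6, by = 0.1)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0, 1)")
  sl <- stack_slices(volumes, axis)
  probs <- stats::predict(model, sl$x, ...)
  rows <- lapply(thresholds, function(th) {
    r <- report_from_probs(probs, sl, th)
    data.frame(threshold = th, dice_2d = r$dice_2d_mean,
               dice_3d = r$dice_3d_mean)
  })
  do.call(rbind, rows)
}

#' Align and compare convergence traces
#'
#' Tabulates the evaluation Dice of the fine-tuning and direct-training runs at
#' their (shared) batch checkpoints and reports the first batch at which each
#' method reaches a target Dice (`NA` if never).
#'
#' @param finetune_trace,direct_trace `spikeseg_trace` objects with in-loop
#'   evaluations recorded at identical batch counts.
#' @param target Dice level whose first crossing is reported, default 0.8.
#' @return `list(table, crossing)`: a `data.frame` with one row per checkpoint
#'   and the per-method first-crossing batch counts.
#' @export
convergence_compare <- function(finetune_trace, direct_trace, target = 0.8) {
  bf <- finetune_trace$eval_batch
  bd <- direct_trace$eval_batch
  m <- min(length(bf), length(bd))
  if (m == 0L || !identical(bf[seq_len(m)], bd[seq_len(m)]))
    stop("traces have misaligned evaluation checkpoints")
  tab <- data.frame(batch = bf[seq_len(m)],
                    finetune = finetune_trace$eval_dice[seq_len(m)],
                    direct = direct_trace$eval_dice[seq_len(m)])
  crossing <- c(
    finetune = first_crossing(finetune_trace$eval_batch,
                              finetune_trace$eval_dice, target),
    direct = first_crossing(direct_trace$eval_batch,
                            direct_trace$eval_dice, target))
  list(table = tab, crossing = crossing, target = target)
}

first_crossing <- function(batches, dice, target) {
  hit <- which(dice >= target)
  if (length(hit)) batches[min(hit)] else NA_integer_
}
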