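#' Loss configuration for segmentation training
#'
#' @param kind `"bce"`, `"dice"` or `"bce_dice"` (weighted combination).
#' @param epsilon smoothing constant used both as a clamp inside the BCE logs
#'   and as the additive smoother of the Dice ratio. Default `1e-5`.
#' @param bce_weight,dice_weight weights of the combined loss; they must sum to
#'   1. Defaults 0.3 and 0.7.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(kind = c("bce_dice", "bce", "dice"), epsilon = 1e-5,
                        bce_weight = 0.3, dice_weight = 0.7) {
  kind <- match.arg(kind)
  if (epsilon <= 0) stop("'epsilon' must be > 0")
  if (abs(bce_weight + dice_weight - 1) > 1e-12)
    stop("loss weights must sum to 1")
  structure(list(kind = kind, epsilon = epsilon,
                 bce_weight = bce_weight, dice_weight = dice_weight),
            class = "loss_config")
}

#' Segmentation losses
#'
#' `bce_loss` is the mean over pixels of the per-pixel binary cross-entropy
#' `-[r log s + (1 - r) log(1 - s)]`, with predictions clamped to
#' `[epsilon, 1 - epsilon]` inside the logs. `dice_loss` is one minus the
#' smoothed Dice coefficient `(2*sum(s*r) + eps) / (sum(s) + sum(r) + eps)`,
#' computed per sample (last array dimension) and averaged; lower is better and
#' perfect overlap gives ~0. `combined_loss` is the weighted sum
#' `bce_weight * BCE + dice_weight * Dice` (defaults 0.3 / 0.7).
#'
#' @param pred numeric array of predicted probabilities in `[0, 1]`.
#' @param target numeric array of `{0,1}` ground-truth labels, same shape.
#' @param epsilon smoothing constant.
#' @param config a [loss_config] for `combined_loss`.
#' @return A single non-negative number.
#' @export
bce_loss <- function(pred, target, epsilon = 1e-5) {
  check_same_shape(pred, target)
  s <- pmin(pmax(pred, epsilon), 1 - epsilon)
  mean(-(target * log(s) + (1 - target) * log(1 - s)))
}

#' @rdname bce_loss
#' @export
dice_loss <- function(pred, target, epsilon = 1e-5) {
  check_same_shape(pred, target)
  d <- dim(pred)
  if (is.null(d)) {
    n <- 1L
    dim(pred) <- dim(target) <- c(length(pred), 1L)
  } else {
    n <- d[length(d)]
    dim(pred) <- dim(target) <- c(prod(d) / n, n)
  }
  num <- 2 * colSums(pred * target) + epsilon
  den <- colSums(pred) + colSums(target) + epsilon
  mean(1 - num / den)
}

#' @rdname bce_loss
#' @export
combined_loss <- function(pred, target, config = loss_config()) {
  config$bce_weight * bce_loss(pred, target, config$epsilon) +
    config$dice_weight * dice_loss(pred, target, config$epsilon)
}

#' @rdname bce_loss
#' @param kind which loss to evaluate; taken from `config` by default.
#' @export
segmentation_loss <- function(pred, target, config = loss_config(),
                              kind = config$kind) {
  switch(kind,
         bce = bce_loss(pred, target, config$epsilon),
         dice = dice_loss(pred, target, config$epsilon),
         bce_dice = combined_loss(pred, target, config))
}

check_same_shape <- function(a, b) {
  da <- if (is.null(dim(a))) length(a) else dim(a)
  db <- if (is.null(dim(b))) length(b) else dim(b)
  if (!identical(as.integer(da), as.integer(db)))
    stop("shape mismatch between prediction (", paste(da, collapse = "x"),
         ") and target (", paste(db, collapse = "x"), ")")
  invisible(TRUE)
}

# Gradient of the configured loss with respect to the pre-sigmoid logits.
# pred = sigmoid(logit). BCE: d/dlogit = (s - r)/Npix. Dice: per-sample chain
# through the ratio, then * s(1-s).
loss_grad_logit <- function(pred, target, config = loss_config(),
                            kind = config$kind) {
  d <- dim(pred)
  n <- d[length(d)]
  grad_bce <- function() (pred - target) / length(pred)
  grad_dice <- function() {
    p <- pred; r <- target
    dim(p) <- dim(r) <- c(prod(d) / n, n)
    num <- 2 * colSums(p * r) + config$epsilon
    den <- colSums(p) + colSums(r) + config$epsilon
    ds <- -(2 * r * rep(den, each = nrow(p)) - rep(num, each = nrow(p))) /
      rep(den^2, each = nrow(p)) / n
    dim(ds) <- d
    ds * pred * (1 - pred)
  }
  g <- switch(kind,
              bce = grad_bce(),
              dice = grad_dice(),
              bce_dice = config$bce_weight * grad_bce() +
                config$dice_weight * grad_dice())
  g
}
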