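#' Training configuration
#'
#' Hyperparameters of the three training stages. Defaults follow the reference
#' protocol: Adam with initial learning rate 0.001 for both ANN and SNN,
#' batch size 26, 100 ANN epochs and 35 SNN epochs at full scale, a
#' reduce-on-plateau schedule monitoring the training loss, and the same time
#' step count `T_train` for fine-tuning and inference. The plateau patience (5
#' monitored evaluations) and reduction factor (0.1) are package choices, not
#' protocol values.
#'
#' @param stage `"ann"`, `"finetune"` or `"direct"`.
#' @param epochs training epochs (default 100 for the ANN stage, 35 otherwise).
#' @param batch_size minibatch size, default 26.
#' @param lr initial Adam learning rate, default 0.001.
#' @param T_train SNN time steps during fine-tuning/direct training.
#' @param loss a [loss_config].
#' @param encoder_mode spike encoder used by the SNN stages.
#' @param alpha surrogate-gradient scale constant.
#' @param patience,factor,min_lr reduce-on-plateau schedule.
#' @param eval_every evaluate (and record Dice) every this many batches; 0
#'   disables in-loop evaluation.
#' @param seed RNG seed for shuffling, dropout and spike sampling.
#' @return An object of class `run_config`.
#' @export
run_config <- function(stage = c("ann", "finetune", "direct"), epochs = NULL,
                       batch_size = 26L, lr = 1e-3, T_train = 200L,
                       loss = loss_config(), encoder_mode = c("ternary", "binary"),
                       alpha = 0.3, patience = 5L, factor = 0.1,
                       min_lr = 1e-6, eval_every = 0L, seed = 1L) {
  stage <- match.arg(stage)
  encoder_mode <- match.arg(encoder_mode)
  if (is.null(epochs)) epochs <- if (stage == "ann") 100L else 35L
  if (epochs < 1) stop("'epochs' must be >= 1")
  if (lr <= 0) stop("'lr' must be > 0")
  if (T_train < 1) stop("'T_train' must be >= 1")
  structure(list(stage = stage, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 T_train = as.integer(T_train), loss = loss,
                 encoder_mode = encoder_mode, alpha = alpha,
                 patience = as.integer(patience), factor = factor,
                 min_lr = min_lr, eval_every = as.integer(eval_every),
                 seed = as.integer(seed)),
            class = "run_config")
}

# ---- optimizer and scheduler ------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  keys <- names(params) %||% seq_along(params)
  for (i in keys) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = params, state = state)
}

plateau_init <- function(lr, patience, factor, min_lr) {
  list(lr = lr, best = Inf, wait = 0L, patience = patience, factor = factor,
       min_lr = min_lr)
}

plateau_update <- function(sch, monitored) {
  if (monitored < sch$best - 1e-12) {
    sch$best <- monitored
    sch$wait <- 0L
  } else {
    sch$wait <- sch$wait + 1L
    if (sch$wait >= sch$patience) {
      sch$lr <- max(sch$lr * sch$factor, sch$min_lr)
      sch$wait <- 0L
    }
  }
  sch
}

new_trace <- function() {
  structure(list(batch = integer(), loss = numeric(), lr = numeric(),
                 eval_batch = integer(), eval_dice = numeric()),
            class = "spikeseg_trace")
}

#' @export
print.spikeseg_trace <- function(x, ...) {
  cat(sprintf("<training trace> %d batches, final loss %.4f\n",
              length(x$loss), utils::tail(x$loss, 1)))
  if (length(x$eval_batch))
    cat(sprintf("  %d evaluations, final Dice %.4f\n",
                length(x$eval_batch), utils::tail(x$eval_dice, 1)))
  invisible(x)
}

#' @export
plot.spikeseg_trace <- function(x, ...) {
  graphics::plot(x$batch, x$loss, type = "l", xlab = "batch", ylab = "loss", ...)
  if (length(x$eval_batch)) {
    graphics::par(new = TRUE)
    graphics::plot(x$eval_batch, x$eval_dice, type = "b", col = "blue",
                   axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
    graphics::axis(4, col.axis = "blue")
    graphics::mtext("Dice", side = 4, line = 2, col = "blue")
  }
  invisible(x)
}

# ---- stage 1: ANN training --------------------------------------------------

#' Train the ANN to convergence
#'
#' Stage 1 of the pipeline: minibatch Adam on the configured segmentation loss,
#' with a reduce-on-plateau learning-rate schedule monitoring the mean epoch
#' loss and retention of the best-loss weights. Aborts with a diagnostic on a
#' non-finite loss.
#'
#' @param ann a `spikeseg_ann` (see [build_ann]).
#' @param images,masks arrays `(H, W, 1, N)`; masks are `{0,1}`.
#' @param config a [run_config] with `stage = "ann"`.
#' @return The trained `spikeseg_ann` with `$trace`.
#' @export
train_ann <- function(ann, images, masks, config = run_config("ann")) {
  stopifnot(inherits(ann, "spikeseg_ann"))
  images <- as_image_batch(images); masks <- as_image_batch(masks)
  set.seed(config$seed)
  n <- dim(images)[4L]
  opt <- adam_init(ann$params)
  sch <- plateau_init(config$lr, config$patience, config$factor, config$min_lr)
  trace <- new_trace()
  best <- list(loss = Inf, params = ann$params)
  bcount <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_losses <- numeric()
    for (ix in batch_indices(n, config$batch_size)) {
      b <- ord[ix]
      xb <- images[, , , b, drop = FALSE]
      yb <- masks[, , , b, drop = FALSE]
      mk <- sample_dropout_masks(ann$spec, length(b))
      fw <- unet_forward(ann$params, ann$spec, xb, masks = mk, keep_cache = TRUE)
      l <- segmentation_loss(fw$prob, yb, config$loss)
      if (!is.finite(l))
        stop("non-finite training loss at batch ", bcount + 1L,
             " (learning rate too high or degenerate data)")
      gr <- unet_backward(ann$params, ann$spec, fw$cache,
                          loss_grad_logit(fw$prob, yb, config$loss))
      st <- adam_step(ann$params, gr, opt, sch$lr)
      ann$params <- st$params; opt <- st$state
      bcount <- bcount + 1L
      trace$batch <- c(trace$batch, bcount)
      trace$loss <- c(trace$loss, l)
      trace$lr <- c(trace$lr, sch$lr)
      ep_losses <- c(ep_losses, l)
    }
    epl <- mean(ep_losses)
    if (epl < best$loss) best <- list(loss = epl, params = ann$params)
    sch <- plateau_update(sch, epl)
  }
  ann$params <- best$params
  ann$trace <- trace
  ann$config <- config
  ann
}

# ---- stages 3 / direct: spike-based training --------------------------------

snn_train_loop <- function(params, thresholds, spec, images, masks, config,
                           eval_fn = NULL) {
  n <- dim(images)[4L]
  opt <- adam_init(params)
  sch <- plateau_init(config$lr, config$patience, config$factor, config$min_lr)
  trace <- new_trace()
  bcount <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_losses <- numeric()
    for (ix in batch_indices(n, config$batch_size)) {
      b <- ord[ix]
      xb <- images[, , , b, drop = FALSE]
      yb <- masks[, , , b, drop = FALSE]
      mk <- sample_dropout_masks(spec, length(b))
      fw <- snn_unet_forward(params, spec, thresholds, xb, T = config$T_train,
                             mode = config$encoder_mode, masks = mk,
                             store_trace = TRUE)
      l <- segmentation_loss(fw$prob, yb, config$loss)
      if (!is.finite(l)) stop("non-finite training loss during spike-based training")
      gr <- snn_unet_backward(params, spec, thresholds, fw$trace,
                              loss_grad_logit(fw$prob, yb, config$loss),
                              alpha = config$alpha)
      st <- adam_step(params, gr, opt, sch$lr)
      params <- st$params; opt <- st$state
      bcount <- bcount + 1L
      trace$batch <- c(trace$batch, bcount)
      trace$loss <- c(trace$loss, l)
      trace$lr <- c(trace$lr, sch$lr)
      ep_losses <- c(ep_losses, l)
      if (!is.null(eval_fn) && config$eval_every > 0L &&
          bcount %% config$eval_every == 0L) {
        trace$eval_batch <- c(trace$eval_batch, bcount)
        trace$eval_dice <- c(trace$eval_dice, eval_fn(params, thresholds))
      }
    }
    sch <- plateau_update(sch, mean(ep_losses))
  }
  list(params = params, trace = trace)
}

#' Fine-tune a converted SNN with surrogate-gradient BPTT
#'
#' Stage 3: starting from the transferred weights and balanced thresholds, the
#' forward pass is unrolled for `T_train` steps, the loss is computed on the
#' sigmoid of the accumulated output potential, and the backward pass
#' accumulates gradients across all time steps, substituting the linear
#' surrogate for the spike derivative at every hidden neuron. Only weights are
#' updated; thresholds stay fixed.
#'
#' @param snn a converted `spikeseg_snn` (see [convert]); an unconverted
#'   network is rejected.
#' @param images,masks training data `(H, W, 1, N)`.
#' @param config a [run_config] with `stage = "finetune"`.
#' @param eval_fn optional `function(params, thresholds)` returning a Dice
#'   score, called every `config$eval_every` batches.
#' @return The fine-tuned `spikeseg_snn` with `$trace`.
#' @export
finetune_snn <- function(snn, images, masks, config = run_config("finetune"),
                         eval_fn = NULL) {
  stopifnot(inherits(snn, "spikeseg_snn"))
  if (!isTRUE(snn$converted))
    stop("fine-tuning requires a converted network with balanced thresholds; run convert() first")
  images <- as_image_batch(images); masks <- as_image_batch(masks)
  set.seed(config$seed)
  res <- snn_train_loop(snn$params, snn$thresholds, snn$spec, images, masks,
                        config, eval_fn)
  snn$params <- res$params
  snn$trace <- res$trace
  snn$T <- config$T_train
  snn$encoder_mode <- config$encoder_mode
  snn$config <- config
  snn
}

#' Train an SNN directly from random initialization
#'
#' The comparison baseline: the identical spike-based training loop as
#' [finetune_snn], but starting from randomly initialized weights with all
#' thresholds fixed at 1 (no conversion).
#'
#' @param spec a [network_spec].
#' @param images,masks training data.
#' @param config a [run_config] with `stage = "direct"`.
#' @param eval_fn as in [finetune_snn].
#' @return A trained `spikeseg_snn` with `$trace`.
#' @export
direct_train_snn <- function(spec, images, masks, config = run_config("direct"),
                             eval_fn = NULL) {
  images <- as_image_batch(images); masks <- as_image_batch(masks)
  set.seed(config$seed)
  snn <- build_snn(spec, encoder_mode = config$encoder_mode,
                   T = config$T_train)
  res <- snn_train_loop(snn$params, snn$thresholds, snn$spec, images, masks,
                        config, eval_fn)
  snn$params <- res$params
  snn$trace <- res$trace
  snn$config <- config
  snn
}

#' Write a training trace as a delimited log table
#'
#' One row per batch with columns `batch`, `loss`, `lr` and (where in-loop
#' evaluation ran) `dice` at the evaluated batches, `NA` elsewhere.
#'
#' @param trace a `spikeseg_trace`.
#' @param path output file; tab-separated.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "spikeseg_trace"))
  tab <- data.frame(batch = trace$batch, loss = trace$loss, lr = trace$lr,
                    dice = NA_real_)
  if (length(trace$eval_batch))
    tab$dice[match(trace$eval_batch, tab$batch)] <- trace$eval_dice
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a network checkpoint
#'
#' Self-describing archive keyed by layer name; the format is shared by ANN
#' and SNN objects so conversion round-trips through disk.
#'
#' @param model a `spikeseg_ann` or `spikeseg_snn`.
#' @param path file path (`.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
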