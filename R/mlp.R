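# Dense (fully-connected) networks with the same spiking semantics as the
# U-Net: ReLU hidden layers in the ANN build, IF sheets with soft reset in the
# SNN build, a non-firing accumulating output layer, no biases. Used for
# rate-fidelity checks of the conversion, for the binary-vs-ternary encoder
# comparison on toy classification sets, and as the small, fully inspectable
# network on which BPTT is verified.

#' Build a small fully-connected ReLU network
#'
#' @param sizes integer vector of layer widths, input first, output last.
#' @param seed optional seed for He-style initialization.
#' @return Object of class `spikeseg_mlp`: a list of weight matrices
#'   (`n_out x n_in`, no biases).
#' @export
build_mlp <- function(sizes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- lapply(seq_len(length(sizes) - 1L), function(i) {
    matrix(stats::rnorm(sizes[i + 1L] * sizes[i], sd = sqrt(2 / sizes[i])),
           sizes[i + 1L], sizes[i])
  })
  structure(list(W = W, sizes = as.integer(sizes)), class = "spikeseg_mlp")
}

#' @export
print.spikeseg_mlp <- function(x, ...) {
  cat("Dense ReLU network, layers:", paste(x$sizes, collapse = " -> "), "\n")
  invisible(x)
}

# X: N x d matrix. Returns hidden activations (post-ReLU) and linear outputs.
mlp_forward <- function(mlp, X) {
  W <- mlp$W
  acts <- vector("list", length(W) - 1L)
  A <- X
  for (i in seq_len(length(W) - 1L)) {
    A <- relu(A %*% t(W[[i]]))
    acts[[i]] <- A
  }
  list(acts = acts, out = A %*% t(W[[length(W)]]))
}

#' Train a dense classifier by softmax cross-entropy
#'
#' Minibatch Adam on the softmax cross-entropy; used for the toy
#' classification sets of the binary/ternary encoder comparison.
#'
#' @param mlp a [build_mlp] network.
#' @param X `N x d` inputs, `y` integer class labels in `1..K`.
#' @param epochs,batch_size,lr optimization settings.
#' @param seed seed for batch shuffling.
#' @return The trained network (with `$trace` of per-epoch losses).
#' @export
train_mlp_classifier <- function(mlp, X, y, epochs = 60L, batch_size = 32L,
                                 lr = 1e-3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- max(y)
  Yh <- matrix(0, nrow(X), K); Yh[cbind(seq_len(nrow(X)), y)] <- 1
  opt <- adam_init(mlp$W)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nrow(X))
    tot <- 0
    for (ix in batch_indices(nrow(X), batch_size)) {
      b <- ord[ix]
      fw <- mlp_forward(mlp, X[b, , drop = FALSE])
      P <- exp(fw$out - apply(fw$out, 1, max))
      P <- P / rowSums(P)
      tot <- tot - sum(log(pmax(P[cbind(seq_along(b), y[b])], 1e-12)))
      dZ <- (P - Yh[b, , drop = FALSE]) / length(b)
      grads <- mlp_backward_dense(mlp, X[b, , drop = FALSE], fw, dZ)
      st <- adam_step(mlp$W, grads, opt, lr)
      mlp$W <- st$params; opt <- st$state
    }
    losses[ep] <- tot / nrow(X)
  }
  mlp$trace <- losses
  mlp
}

# standard dense backprop; dZ is dL/d(linear output)
mlp_backward_dense <- function(mlp, X, fw, dZ) {
  W <- mlp$W
  nl <- length(W)
  grads <- vector("list", nl)
  dA <- dZ
  for (i in nl:1) {
    Ain <- if (i == 1L) X else fw$acts[[i - 1L]]
    grads[[i]] <- t(dA) %*% Ain
    if (i > 1L) {
      dA <- (dA %*% W[[i]]) * (fw$acts[[i - 1L]] > 0)
    }
  }
  grads
}

# Spiking forward of the dense network, vectorized over samples.
# X: N x d inputs in the encoder range. Returns accumulated outputs, per-layer
# firing rates, and (optionally) the full trace for BPTT.
snn_mlp_forward <- function(W, thresholds, X, T, mode = c("ternary", "binary"),
                            store_trace = FALSE, record_layer = NULL) {
  mode <- match.arg(mode)
  nh <- length(W) - 1L
  N <- nrow(X)
  u <- lapply(W[seq_len(nh)], function(w) matrix(0, N, nrow(w)))
  u_out <- matrix(0, N, nrow(W[[length(W)]]))
  spike_sum <- numeric(nh)
  rec_max <- -Inf
  trace <- if (store_trace)
    list(s = lapply(seq_len(nh), function(i) array(0, c(N, nrow(W[[i]]), T))),
         m = lapply(seq_len(nh), function(i) array(0, c(N, nrow(W[[i]]), T))),
         x = array(0, c(N, ncol(X), T)), T = T)
  for (t in seq_len(T)) {
    xt <- matrix(unclass(poisson_encode(X, 1L, mode = mode)), N, ncol(X))
    if (store_trace) trace$x[, , t] <- xt
    A <- xt
    for (i in seq_len(nh)) {
      Z <- A %*% t(W[[i]])
      if (!is.null(record_layer) && record_layer == i)
        rec_max <- max(rec_max, max(Z))
      m <- u[[i]] + Z
      s <- (m > thresholds[i]) * 1
      u[[i]] <- m - thresholds[i] * s
      spike_sum[i] <- spike_sum[i] + sum(s)
      if (store_trace) { trace$m[[i]][, , t] <- m; trace$s[[i]][, , t] <- s }
      A <- s
    }
    u_out <- u_out + A %*% t(W[[length(W)]])
  }
  list(u_out = u_out,
       rates = spike_sum / (T * N * vapply(W[seq_len(nh)], nrow, 1L)),
       rate_maps = lapply(seq_len(nh), function(i)
         if (store_trace) apply(trace$s[[i]], c(1, 2), mean) else NULL),
       layer_stat = rec_max, trace = trace)
}

# BPTT for the dense SNN; du_out is dL/d(u_out) (N x n_out). Same recurrence
# as the convolutional case.
snn_mlp_backward <- function(W, thresholds, trace, du_out, alpha = 0.3) {
  nh <- length(W) - 1L
  T <- trace$T
  grads <- lapply(W, function(w) array(0, dim(w)))
  dcarry <- lapply(trace$s, function(a) matrix(0, dim(a)[1], dim(a)[2]))
  for (t in T:1) {
    s_last <- trace$s[[nh]][, , t, drop = FALSE]; dim(s_last) <- dim(s_last)[-3]
    grads[[nh + 1L]] <- grads[[nh + 1L]] + t(du_out) %*% s_last
    ds <- du_out %*% W[[nh + 1L]]
    for (i in nh:1) {
      m <- trace$m[[i]][, , t, drop = FALSE]; dim(m) <- dim(m)[-3]
      g <- surrogate_grad(m, thresholds[i], alpha)
      dm <- ds * g + dcarry[[i]] * (1 - thresholds[i] * g)
      dcarry[[i]] <- dm
      Ain <- if (i == 1L) {
        a <- trace$x[, , t, drop = FALSE]; dim(a) <- dim(a)[-3]; a
      } else {
        a <- trace$s[[i - 1L]][, , t, drop = FALSE]; dim(a) <- dim(a)[-3]; a
      }
      grads[[i]] <- grads[[i]] + t(dm) %*% Ain
      if (i > 1L) ds <- dm %*% W[[i]]
    }
  }
  grads
}

#' SpikeNorm threshold balancing for a dense network
#'
#' Same sequential maximum-weighted-input rule as the convolutional
#' [balance_thresholds], on a dense network.
#'
#' @param mlp a `spikeseg_mlp` (trained ANN weights).
#' @param X calibration inputs (`N x d`).
#' @param config a [conversion_config].
#' @param seed optional seed for the balancing encodings.
#' @return Numeric vector of hidden-layer thresholds.
#' @export
balance_mlp_thresholds <- function(mlp, X, config = conversion_config(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nh <- length(mlp$W) - 1L
  v <- rep(1, nh)
  scaled <- logical(nh)
  for (i in seq_len(nh)) {
    fwd <- snn_mlp_forward(mlp$W, v, X, T = config$T_balance,
                           mode = config$encoder_mode, record_layer = i)
    stat <- fwd$layer_stat
    if (!is.finite(stat) || stat <= 0) {
      warning("dense layer ", i, " received no positive drive; keeping threshold 1")
    } else {
      v[i] <- stat
      scaled[i] <- TRUE
    }
  }
  # final uniform rescale, after all layers are balanced
  v[scaled] <- v[scaled] * config$threshold_scale
  v
}

#' Rate fidelity of a converted dense network
#'
#' Converts a ReLU MLP by SpikeNorm balancing and measures how faithfully the
#' spiking network's rate code reproduces the ANN: the Pearson correlation
#' between the SNN's time-averaged output potential (`u_out / T`) and the
#' ANN's output pre-activations across all neurons and samples, plus
#' per-hidden-layer correlations between firing rates and ANN activations.
#'
#' @param mlp a `spikeseg_mlp` with ReLU semantics (the source ANN).
#' @param X inputs (`N x d`) in the encoder range.
#' @param T_balance,T_infer balancing and inference time steps.
#' @param mode encoder mode.
#' @param seed RNG seed.
#' @return `list(output_correlation, hidden_correlations, thresholds)`.
#' @export
conversion_rate_fidelity <- function(mlp, X, T_balance = 500L,
                                     T_infer = 2000L,
                                     mode = c("binary", "ternary"),
                                     seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  cfg <- conversion_config(T_balance = T_balance, encoder_mode = mode,
                           T_infer = T_infer)
  v <- balance_mlp_thresholds(mlp, X, cfg)
  ann <- mlp_forward(mlp, X)
  fwd <- snn_mlp_forward(mlp$W, v, X, T = T_infer, mode = mode,
                         store_trace = TRUE)
  hidden <- vapply(seq_along(v), function(i)
    stats::cor(as.numeric(fwd$rate_maps[[i]]), as.numeric(ann$acts[[i]])), 1)
  list(output_correlation = stats::cor(as.numeric(fwd$u_out / T_infer),
                                       as.numeric(ann$out)),
       hidden_correlations = hidden, thresholds = v)
}
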