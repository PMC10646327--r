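# Spiking realization of the U-Net and its backpropagation-through-time.
#
# Forward, per time step t:
#   * the input image is Poisson rate-coded into spikes x_t;
#   * every hidden weight layer (encoder/bottleneck/decoder convolutions and
#     the transposed convolutions) feeds a sheet of IF neurons: the weighted
#     input is integrated into a persistent membrane potential, a spike fires
#     where the potential strictly exceeds the layer threshold, and the
#     threshold is subtracted from firing neurons (soft reset);
#   * average pooling acts on spike values (producing fractional drive for the
#     next layer), skip connections concatenate spike maps time-step-wise;
#   * the output 1x1 convolution accumulates into non-firing potentials.
# After T steps the probability map is sigmoid(u_out / out_scale). The default
# out_scale is T / prod(thresholds): under the rate code every spiking layer
# transmits roughly activation / v_l, so the accumulated potential carries the
# ANN logit attenuated by the product of the thresholds; dividing by
# T / prod(v) decodes the rate back onto the ANN's logit scale. (With unit
# thresholds -- direct training -- this reduces to the plain time average.)
#
# Backward (BPTT): the loss gradient flows once into u_out (which is a plain
# sum over t, so every step receives the same dL/du_out), and is then chased
# backwards through time. At an IF layer with pre-reset potential m_t,
# spike s_t = H(m_t - v) and carried potential u_t = m_t - v*s_t:
#   dL/dm_t = dL/ds_t * g(m_t) + dL/du_t * (1 - v * g(m_t)),
# where g is the linear surrogate (surrogate_grad) standing in for the
# zero-a.e. spike derivative, and dL/du_{t-1} = dL/dm_t is the carry.
# Thresholds are never updated here; only weights receive gradients.

# Forward simulation. images: (H, W, 1, N) in the encoder's input range.
# store_trace keeps everything BPTT needs (per-layer spikes after dropout and
# pre-reset membranes, plus the encoded input), as per-time-step lists.
# record_layer/record_stat support SpikeNorm threshold balancing: the named
# layer's weighted-input statistic is tracked (running max, or all values when
# a percentile is requested). record_rates accumulates mean |spike| per layer.
snn_unet_forward <- function(params, spec, thresholds, images, T,
                             mode = c("ternary", "binary"),
                             out_scale = NULL, masks = NULL,
                             store_trace = FALSE, record_rates = FALSE,
                             record_layer = NULL, record_values = FALSE) {
  mode <- match.arg(mode)
  T <- as.integer(T)
  d <- dim(images)
  N <- d[4L]
  L <- spec$levels
  lnames <- spiking_layer_names(spec)
  if (!setequal(names(thresholds), lnames))
    stop("threshold count mismatch: need one per spiking layer")
  if (any(thresholds <= 0)) stop("firing thresholds must be positive")
  if (is.null(out_scale)) out_scale <- T / prod(unlist(thresholds))
  sh <- unet_shapes(spec)$act

  u <- lapply(sh[lnames], function(s) array(0, c(s, N)))
  u_out <- array(0, c(spec$input_shape, 1L, N))
  trace <- NULL
  if (store_trace) {
    trace <- list(
      s = sapply(lnames, function(nm) vector("list", T), simplify = FALSE),
      m = sapply(lnames, function(nm) vector("list", T), simplify = FALSE),
      x = vector("list", T), masks = masks, T = T, out_scale = out_scale)
  }
  spike_sum <- stats::setNames(numeric(length(lnames)), lnames)
  rec_max <- -Inf
  rec_vals <- if (record_values) vector("list", T)

  # one IF layer update (fused integrate/fire/reset); returns the transmitted
  # (dropout-masked) spikes
  step_if <- function(nm, z, t) {
    r <- .if_fused_step(u[[nm]], z, thresholds[[nm]], masks[[nm]])
    u[[nm]] <<- r$u
    if (record_rates) spike_sum[[nm]] <<- spike_sum[[nm]] + r$nspikes
    if (store_trace) {
      trace$m[[nm]][[t]] <<- r$m
      trace$s[[nm]][[t]] <<- r$s
    }
    if (!is.null(record_layer) && record_layer == nm) {
      if (record_values) rec_vals[[t]] <<- as.numeric(z) else
        rec_max <<- max(rec_max, max(z))
    }
    r$s
  }

  sgn <- if (mode == "ternary") sign(images) else 1
  tgt <- abs(images)
  for (t in seq_len(T)) {
    xt <- (stats::runif(length(images)) < tgt) * sgn
    dim(xt) <- d
    if (store_trace) trace$x[[t]] <- xt
    s <- xt
    enc_s <- vector("list", L)
    for (l in seq_len(L)) {
      nm <- paste0("enc", l)
      s_post <- step_if(nm, conv2d(s, params[[nm]]), t)
      enc_s[[l]] <- s_post
      s <- avgpool2(s_post)
    }
    s <- step_if("bott", conv2d(s, params$bott), t)
    for (l in L:1) {
      un <- paste0("up", l); dn <- paste0("dec", l)
      su <- step_if(un, upconv2(s, params[[un]]), t)
      s <- step_if(dn, conv2d(channel_cat(su, enc_s[[l]]), params[[dn]]), t)
    }
    u_out <- u_out + conv2d(s, params$out, pad = 0L)
  }

  res <- list(prob = sigmoid(u_out / out_scale), u_out = u_out,
              out_scale = out_scale, trace = trace)
  if (record_rates)
    res$rates <- spike_sum / (vapply(sh[lnames], prod, 1) * N * T)
  if (!is.null(record_layer))
    res$layer_stat <- if (record_values) unlist(rec_vals) else rec_max
  res
}

# BPTT through the stored trace. dlogit = dLoss/d(u_out/out_scale), shape
# (H, W, 1, N). Returns weight gradients keyed like params.
snn_unet_backward <- function(params, spec, thresholds, trace, dlogit,
                              alpha = 0.3) {
  L <- spec$levels
  T <- trace$T
  masks <- trace$masks
  lnames <- spiking_layer_names(spec)
  du_out <- dlogit / trace$out_scale
  grads <- lapply(params, function(w) array(0, dim(w)))
  dcarry <- lapply(trace$s, function(a) array(0, dim(a[[1L]])))

  # grad through one IF layer at time t: ds is dL/d(transmitted spikes)
  back_if <- function(nm, ds, t) {
    dm <- .if_fused_back(trace$m[[nm]][[t]], ds, dcarry[[nm]],
                         thresholds[[nm]], alpha, masks[[nm]])
    dcarry[[nm]] <<- dm
    dm
  }
  sp_t <- function(nm, t) trace$s[[nm]][[t]]

  for (t in T:1) {
    bw <- conv2d_bwd(sp_t("dec1", t), params$out, du_out, pad = 0L)
    grads$out <- grads$out + bw$dw
    ds <- bw$dx
    denc <- vector("list", L)
    for (l in seq_len(L)) {
      dn <- paste0("dec", l); un <- paste0("up", l)
      dm <- back_if(dn, ds, t)
      ct <- channel_cat(sp_t(un, t), sp_t(paste0("enc", l), t))
      bw <- conv2d_bwd(ct, params[[dn]], dm)
      grads[[dn]] <- grads[[dn]] + bw$dw
      sp <- channel_split(bw$dx, spec$channels[l])
      denc[[l]] <- sp[[2]]
      dmu <- back_if(un, sp[[1]], t)
      prev <- if (l == L) sp_t("bott", t) else sp_t(paste0("dec", l + 1L), t)
      bw <- upconv2_bwd(prev, params[[un]], dmu)
      grads[[un]] <- grads[[un]] + bw$dw
      ds <- bw$dx
    }
    dm <- back_if("bott", ds, t)
    bw <- conv2d_bwd(avgpool2(sp_t(paste0("enc", L), t)), params$bott, dm)
    grads$bott <- grads$bott + bw$dw
    ds <- avgpool2_bwd(bw$dx) + denc[[L]]
    for (l in L:1) {
      nm <- paste0("enc", l)
      dm <- back_if(nm, ds, t)
      inp <- if (l == 1L) trace$x[[t]] else
        avgpool2(sp_t(paste0("enc", l - 1L), t))
      bw <- conv2d_bwd(inp, params[[nm]], dm)
      grads[[nm]] <- grads[[nm]] + bw$dw
      if (l > 1L) ds <- avgpool2_bwd(bw$dx) + denc[[l - 1L]]
    }
  }
  grads
}

#' Per-layer firing-frequency report
#'
#' Simulates the SNN on a batch (dropout off) and reports, for every spiking
#' layer, the mean absolute spike value per neuron per time step together with
#' the layer threshold. Comparing reports before and after fine-tuning shows
#' how the weight updates re-activate neurons silenced by conservative
#' balancing.
#'
#' @param snn a `spikeseg_snn`.
#' @param images input batch `(H, W, 1, N)`.
#' @param T simulation steps; defaults to the network's.
#' @param label optional label (e.g. `"converted"`, `"fine-tuned"`) stored in
#'   the report.
#' @return A `data.frame` (class `firing_report`) with columns `layer`,
#'   `threshold`, `rate`, `label`.
#' @export
firing_frequencies <- function(snn, images, T = snn$T, label = NA_character_) {
  images <- as_image_batch(images)
  fwd <- snn_unet_forward(snn$params, snn$spec, snn$thresholds, images, T = T,
                          mode = snn$encoder_mode, record_rates = TRUE)
  out <- data.frame(layer = names(fwd$rates),
                    threshold = as.numeric(snn$thresholds[names(fwd$rates)]),
                    rate = as.numeric(fwd$rates),
                    label = label, stringsAsFactors = FALSE)
  class(out) <- c("firing_report", "data.frame")
  out
}
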