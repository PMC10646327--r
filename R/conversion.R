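#' Conversion configuration
#'
#' Settings of the early-stop ANN-SNN conversion. "Early stop" means the
#' balancing simulation runs for a deliberately small, fixed budget of
#' `T_balance` time steps (default 200) rather than to convergence; the
#' imperfect SNN it produces is the intended starting point for spike-based
#' fine-tuning.
#'
#' @param T_balance time steps of the balancing simulation (>= 1), default 200.
#' @param threshold_scale multiplicative factor applied to every balanced
#'   threshold (> 0), default 1.
#' @param calibration_size number of calibration samples drawn from the batch
#'   passed to [convert] (default: one training batch, 26).
#' @param statistic `"max"` (SpikeNorm: maximum weighted input seen by any
#'   neuron at any time step) or `"percentile"`.
#' @param percentile probability used when `statistic = "percentile"`.
#' @param encoder_mode,T_infer encoder and default inference/fine-tuning time
#'   steps stamped on the converted network.
#' @return An object of class `conversion_config`.
#' @export
conversion_config <- function(T_balance = 200L, threshold_scale = 1,
                              calibration_size = 26L,
                              statistic = c("max", "percentile"),
                              percentile = 0.999,
                              encoder_mode = c("ternary", "binary"),
                              T_infer = T_balance) {
  statistic <- match.arg(statistic)
  encoder_mode <- match.arg(encoder_mode)
  if (T_balance < 1) stop("'T_balance' must be >= 1")
  if (threshold_scale <= 0) stop("'threshold_scale' must be > 0")
  structure(list(T_balance = as.integer(T_balance),
                 threshold_scale = threshold_scale,
                 calibration_size = as.integer(calibration_size),
                 statistic = statistic, percentile = percentile,
                 encoder_mode = encoder_mode, T_infer = as.integer(T_infer)),
            class = "conversion_config")
}

#' Copy trained ANN weights into an SNN
#'
#' Every weight tensor is copied unchanged (conversion is a pure copy because
#' both builds share tensor shapes by construction) and all firing thresholds
#' are reset to 1, the canonical pre-balancing state.
#'
#' @param ann a trained `spikeseg_ann`.
#' @param snn a `spikeseg_snn` built from a matching [network_spec].
#' @return The SNN with transferred weights and unit thresholds.
#' @export
transfer_weights <- function(ann, snn) {
  stopifnot(inherits(ann, "spikeseg_ann"), inherits(snn, "spikeseg_snn"))
  a <- ann$params; s <- snn$params
  if (!setequal(names(a), names(s)))
    stop("layer mismatch: ", paste(symdiff_names(a, s), collapse = ", "))
  bad <- names(a)[!vapply(names(a), function(nm)
    identical(dim(a[[nm]]), dim(s[[nm]])), TRUE)]
  if (length(bad))
    stop("weight shape mismatch in layer(s): ", paste(bad, collapse = ", "))
  snn$params <- a
  snn$thresholds[] <- 1
  snn
}

symdiff_names <- function(a, b) {
  union(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
}

#' Balance per-layer firing thresholds (SpikeNorm)
#'
#' Sequential threshold balancing: spiking layers are processed in topological
#' order; for each layer the network is simulated for `T_balance` steps on the
#' calibration batch with all earlier thresholds already balanced (later layers
#' still at their pre-balancing value, which cannot influence the statistic),
#' and the layer threshold is set to the chosen statistic of the weighted input
#' received by any of its neurons at any time step, times `threshold_scale`.
#' A layer whose maximum weighted input is not positive keeps threshold 1 with
#' a warning (dead layer).
#'
#' @param snn a `spikeseg_snn` with transferred weights.
#' @param calibration array `(H, W, 1, N)` of calibration inputs, normalized
#'   exactly as in training.
#' @param config a [conversion_config].
#' @return Named numeric vector of balanced thresholds.
#' @export
balance_thresholds <- function(snn, calibration, config = conversion_config()) {
  stopifnot(inherits(snn, "spikeseg_snn"))
  calibration <- as_image_batch(calibration)
  n <- min(dim(calibration)[4L], config$calibration_size)
  calibration <- calibration[, , , seq_len(n), drop = FALSE]
  v <- snn$thresholds
  scaled <- logical(length(v))
  names(scaled) <- names(v)
  for (nm in spiking_layer_names(snn$spec)) {
    fwd <- snn_unet_forward(snn$params, snn$spec, v, calibration,
                            T = config$T_balance, mode = config$encoder_mode,
                            record_layer = nm,
                            record_values = config$statistic == "percentile")
    stat <- if (config$statistic == "percentile") {
      as.numeric(stats::quantile(fwd$layer_stat, config$percentile))
    } else max(fwd$layer_stat)
    if (!is.finite(stat) || stat <= 0) {
      warning("layer '", nm, "' received no positive drive during balancing; ",
              "keeping threshold 1 (dead layer)")
      v[[nm]] <- 1
    } else {
      v[[nm]] <- stat
      scaled[[nm]] <- TRUE
    }
  }
  # the scale factor is a final, uniform rescaling (the sweep knob); applying
  # it inside the sequential loop would perturb the statistics of later layers
  v[scaled] <- v[scaled] * config$threshold_scale
  v
}

#' Early-stop ANN-SNN conversion
#'
#' Composition of [transfer_weights] and [balance_thresholds]: builds the
#' spiking twin of the trained ANN, copies the weights, initializes all
#' thresholds to 1 and balances them on the calibration batch. The returned
#' SNN is ready for inference or surrogate-gradient fine-tuning. Thresholds are
#' a pure function of (weights, calibration batch, RNG seed, config).
#'
#' @param ann a trained `spikeseg_ann`.
#' @param calibration calibration inputs `(H, W, 1, N)`.
#' @param config a [conversion_config].
#' @param seed optional seed fixing the Poisson encodings used for balancing.
#' @return A converted `spikeseg_snn` (with `$thresholds` balanced and
#'   `$converted = TRUE`).
#' @export
convert <- function(ann, calibration, config = conversion_config(),
                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  snn <- build_snn(ann$spec, encoder_mode = config$encoder_mode,
                   T = config$T_infer)
  snn <- transfer_weights(ann, snn)
  snn$thresholds <- balance_thresholds(snn, calibration, config)
  snn$converted <- TRUE
  snn
}
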