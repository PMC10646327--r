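# Desk-scale experiment harnesses tying the three stages together. The sizes
# here are the package's reference study conditions for synthetic experiments:
# 256 single-slice 32x48 subjects, a 2-level U-Net (channels 4/8, bottleneck
# 16), 32 simulation time steps, batch size 26, ternary encoding of zero-mean
# inputs. The methods vignette discusses the choices.

#' Configuration of the toy 2D segmentation task
#'
#' Single-slice 32 x 48 volumes (so slice-wise and subject-wise scores
#' coincide), zero-mean normalization for ternary encoding.
#'
#' @param n_subjects number of subjects; default 256.
#' @param seed RNG seed.
#' @param ... overrides passed to [synth_config].
#' @return A [synth_config].
#' @export
toy_segmentation_config <- function(n_subjects = 256L, seed = 1L, ...) {
  args <- list(n_subjects = n_subjects, shape = c(1L, 32L, 48L),
               fg_scale = 0.16, noise_sd = 0.12, bias_amp = 0.1,
               contrast = 0.5, normalization = "zero_mean", folds = 4L,
               seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(synth_config, args)
}

#' Run the full three-stage pipeline on the toy task
#'
#' Generates the synthetic dataset, trains the ANN, converts it with the
#' early-stop balancing procedure, evaluates the converted network, fine-tunes
#' it with surrogate-gradient BPTT, trains the direct baseline with the same
#' spike-based loop from random weights, and records per-layer firing
#' frequencies before and after fine-tuning. Both SNN runs evaluate the 2D
#' Dice on the test fold at aligned batch checkpoints, which feeds
#' [convergence_compare].
#'
#' @param seed master seed of the run.
#' @param T time steps for conversion, fine-tuning and inference (one knob).
#' @param ann_epochs,finetune_epochs,direct_epochs stage lengths.
#' @param eval_every checkpoint cadence (batches) of the SNN runs.
#' @param synth overrides for [toy_segmentation_config].
#' @param dropout dropout rate of the network spec.
#' @param direct_train run the direct-training baseline too.
#' @param firing record firing-frequency reports.
#' @return A list with the trained models, `dice_report`s per stage, traces,
#'   and firing reports.
#' @export
run_three_stage_experiment <- function(seed = 1L, T = 32L, ann_epochs = 25L,
                                       finetune_epochs = 3L,
                                       direct_epochs = 8L, eval_every = 8L,
                                       synth = list(), dropout = 0.1,
                                       direct_train = TRUE, firing = TRUE) {
  cfg <- do.call(toy_segmentation_config,
                 c(list(seed = seed), synth))
  ds <- generate_dataset(cfg)
  test_ix <- ds$folds == 1L
  train <- stack_slices(ds$volumes[!test_ix])
  test_vols <- ds$volumes[test_ix]
  test <- stack_slices(test_vols)

  spec <- network_spec(dim(train$x)[1:2], levels = 2L, channels = c(4L, 8L),
                       bottleneck = 16L, dropout = dropout)
  ann <- build_ann(spec, seed = seed)
  ann <- train_ann(ann, train$x, train$y,
                   run_config("ann", epochs = ann_epochs, seed = seed))
  ann_report <- evaluate_model(ann, test_vols)

  conv_cfg <- conversion_config(T_balance = T, T_infer = T,
                                encoder_mode = "ternary")
  calib <- train$x[, , , seq_len(min(26L, dim(train$x)[4L])), drop = FALSE]
  snn0 <- convert(ann, calib, conv_cfg, seed = seed)
  conv_report <- evaluate_model(snn0, test_vols)

  eval_fn <- local({
    tx <- test$x; spec_ <- spec
    function(params, thresholds) {
      fwd_probs <- array(0, dim(tx))
      for (ix in batch_indices(dim(tx)[4L], 32L)) {
        fwd_probs[, , , ix] <- snn_unet_forward(
          params, spec_, thresholds, tx[, , , ix, drop = FALSE],
          T = T, mode = "ternary")$prob
      }
      report_from_probs(fwd_probs, test, 0.5)$dice_2d_mean
    }
  })

  ft_cfg <- run_config("finetune", epochs = finetune_epochs, T_train = T,
                       eval_every = eval_every, seed = seed)
  snn_ft <- finetune_snn(snn0, train$x, train$y, ft_cfg, eval_fn = eval_fn)
  ft_report <- evaluate_model(snn_ft, test_vols)

  res <- list(seed = seed, spec = spec, ann = ann, converted = snn0,
              finetuned = snn_ft, ann_report = ann_report,
              converted_report = conv_report, finetuned_report = ft_report,
              test_volumes = test_vols)

  if (firing) {
    fb <- test$x[, , , seq_len(min(26L, dim(test$x)[4L])), drop = FALSE]
    res$firing_before <- firing_frequencies(snn0, fb, T = T,
                                            label = "converted")
    res$firing_after <- firing_frequencies(snn_ft, fb, T = T,
                                           label = "fine-tuned")
  }
  if (direct_train) {
    dt_cfg <- run_config("direct", epochs = direct_epochs, T_train = T,
                         eval_every = eval_every, seed = seed)
    snn_dt <- direct_train_snn(spec, train$x, train$y, dt_cfg,
                               eval_fn = eval_fn)
    res$direct <- snn_dt
    res$direct_report <- evaluate_model(snn_dt, test_vols)
    res$convergence <- convergence_compare(snn_ft$trace, snn_dt$trace,
                                           target = 0.8)
  }
  res
}

#' Binary vs ternary encoder comparison on the toy classification task
#'
#' Trains the same dense classifier on the `[0, 1]`-normalized and the
#' zero-mean variants of one underlying sample set, converts both with
#' SpikeNorm balancing (the first becomes a binary SNN, the second a ternary
#' SNN) and compares test accuracies.
#'
#' @param seed RNG seed.
#' @param n_per_class,noise_sd toy set size/noise.
#' @param hidden hidden-layer widths of the classifier.
#' @param epochs ANN training epochs.
#' @param T_balance,T_infer conversion and inference time steps.
#' @return A list with ANN and converted-SNN accuracies for both encoders.
#' @export
run_encoder_comparison <- function(seed = 1L, n_per_class = 100L,
                                   noise_sd = 0.2, hidden = c(48L, 24L),
                                   epochs = 40L, T_balance = 200L,
                                   T_infer = 200L) {
  data <- generate_toy_classification(n_per_class = n_per_class,
                                      noise_sd = noise_sd, seed = seed)
  N <- length(data$y)
  set.seed(seed)
  test_ix <- sample.int(N, size = round(0.25 * N))
  tr <- setdiff(seq_len(N), test_ix)
  k <- max(data$y)
  sizes <- c(ncol(data$x01), hidden, k)

  run_variant <- function(X, mode) {
    mlp <- build_mlp(sizes, seed = seed)
    mlp <- train_mlp_classifier(mlp, X[tr, ], data$y[tr], epochs = epochs,
                                seed = seed)
    ann_pred <- max.col(mlp_forward(mlp, X[test_ix, ])$out)
    cfg <- conversion_config(T_balance = T_balance, encoder_mode = mode,
                             T_infer = T_infer)
    v <- balance_mlp_thresholds(mlp, X[tr[seq_len(min(64L, length(tr)))], ,
                                       drop = FALSE], cfg, seed = seed)
    fwd <- snn_mlp_forward(mlp$W, v, X[test_ix, ], T = T_infer, mode = mode)
    snn_pred <- max.col(fwd$u_out)
    list(ann_accuracy = mean(ann_pred == data$y[test_ix]),
         snn_accuracy = mean(snn_pred == data$y[test_ix]),
         thresholds = v)
  }

  list(binary = run_variant(data$x01, "binary"),
       ternary = run_variant(data$xzm, "ternary"),
       n_test = length(test_ix), seed = seed)
}
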