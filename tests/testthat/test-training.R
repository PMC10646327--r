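test_that("dense BPTT equals forward-mode differentiation of the unrolled graph", {
  set.seed(11)
  mlp <- build_mlp(c(4, 5, 3), seed = 11)
  W <- mlp$W
  v <- 0.8
  T <- 5; N <- 2
  X <- matrix(stats::runif(N * 4), N, 4)
  target <- matrix(stats::rbinom(N * 3, 1, 0.5), N, 3)
  set.seed(99)
  fw <- spikeseg:::snn_mlp_forward(W, v, X, T = T, mode = "binary",
                                   store_trace = TRUE)
  prob <- 1 / (1 + exp(-fw$u_out / T))
  du_out <- (prob - target) / length(prob) / T
  gr <- spikeseg:::snn_mlp_backward(W, v, fw$trace, du_out, alpha = 0.3)
  xs <- lapply(seq_len(T), function(t) {
    a <- fw$trace$x[, , t, drop = FALSE]; dim(a) <- dim(a)[-3]; a
  })
  for (li in seq_along(W))
    for (idx in sample(length(W[[li]]), 4)) {
      ref <- fwdmode_grad_mlp(W, v, xs, target, 0.3, li, idx)
      expect_equal(gr[[li]][idx], ref, tolerance = 1e-6)
    }
})

test_that("convolutional BPTT equals forward-mode differentiation", {
  spec <- network_spec(c(4, 4), levels = 1, channels = 2, bottleneck = 3,
                       dropout = 0)
  params <- spikeseg:::init_unet_params(spec, seed = 3)
  v <- stats::setNames(c(0.9, 1.2, 0.8, 1.0), spiking_layer_names(spec))
  img <- array(stats::runif(4 * 4 * 2), c(4, 4, 1, 2))
  targ <- array(stats::rbinom(4 * 4 * 2, 1, 0.4), c(4, 4, 1, 2))
  set.seed(123)
  # the forward-mode reference reads out sigmoid(u_out / T): pin that scale
  fw <- spikeseg:::snn_unet_forward(params, spec, v, img, T = 4,
                                    mode = "binary", store_trace = TRUE,
                                    out_scale = 4)
  dlogit <- (fw$prob - targ) / length(fw$prob)
  gr <- spikeseg:::snn_unet_backward(params, spec, v, fw$trace, dlogit,
                                     alpha = 0.3)
  for (nm in names(params))
    for (idx in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      ref <- fwdmode_grad_unet(params, spec, v, fw$trace$x, targ, 0.3, nm, idx)
      expect_equal(gr[[nm]][idx], ref, tolerance = 1e-6)
    }
})

test_that("ANN training reduces the loss and is seed-reproducible", {
  dat <- tiny_seg_data(n = 16, seed = 2)
  spec <- network_spec(c(32, 48), levels = 2, channels = c(2, 4),
                       bottleneck = 8, dropout = 0)
  cfg <- run_config("ann", epochs = 3, batch_size = 8, seed = 5)
  ann1 <- train_ann(build_ann(spec, seed = 5), dat$x, dat$y, cfg)
  ann2 <- train_ann(build_ann(spec, seed = 5), dat$x, dat$y, cfg)
  expect_identical(ann1$trace$loss, ann2$trace$loss)
  nb <- length(ann1$trace$loss) / 3
  expect_lt(mean(ann1$trace$loss[(2 * nb + 1):(3 * nb)]),
            mean(ann1$trace$loss[1:nb]))
})

test_that("fine-tuning requires conversion, freezes thresholds, learns", {
  dat <- tiny_seg_data(n = 16, seed = 3)
  spec <- network_spec(c(32, 48), levels = 2, channels = c(2, 4),
                       bottleneck = 8, dropout = 0)
  ann <- train_ann(build_ann(spec, seed = 1), dat$x, dat$y,
                   run_config("ann", epochs = 4, batch_size = 8, seed = 1))
  raw <- build_snn(spec)
  expect_error(finetune_snn(raw, dat$x, dat$y), "convert")

  snn <- convert(ann, dat$x[, , , 1:8, drop = FALSE],
                 conversion_config(T_balance = 8, T_infer = 8), seed = 1)
  v0 <- snn$thresholds
  cfg <- run_config("finetune", epochs = 1, batch_size = 8, T_train = 8,
                    seed = 1)
  ft <- finetune_snn(snn, dat$x, dat$y, cfg)
  expect_identical(ft$thresholds, v0)          # no threshold drift
  expect_true(all(is.finite(ft$trace$loss)))
  changed <- any(vapply(names(ft$params), function(nm)
    any(ft$params[[nm]] != snn$params[[nm]]), TRUE))
  expect_true(changed)
})

test_that("direct training runs the same loop from scratch, deterministically", {
  dat <- tiny_seg_data(n = 8, seed = 4)
  spec <- network_spec(c(32, 48), levels = 2, channels = c(2, 4),
                       bottleneck = 8, dropout = 0.1)
  cfg <- run_config("direct", epochs = 1, batch_size = 8, T_train = 6,
                    seed = 9)
  a <- direct_train_snn(spec, dat$x, dat$y, cfg)
  b <- direct_train_snn(spec, dat$x, dat$y, cfg)
  expect_identical(a$trace$loss, b$trace$loss)
  expect_true(all(a$thresholds == 1))
})

test_that("initialization advantage: fine-tuning starts from a lower loss", {
  dat <- tiny_seg_data(n = 16, seed = 6)
  spec <- network_spec(c(32, 48), levels = 2, channels = c(2, 4),
                       bottleneck = 8, dropout = 0)
  start_losses <- sapply(1:2, function(s) {
    ann <- train_ann(build_ann(spec, seed = s), dat$x, dat$y,
                     run_config("ann", epochs = 4, batch_size = 8, seed = s))
    snn <- convert(ann, dat$x[, , , 1:8, drop = FALSE],
                   conversion_config(T_balance = 8, T_infer = 8), seed = s)
    ft <- finetune_snn(snn, dat$x, dat$y,
                       run_config("finetune", epochs = 1, batch_size = 8,
                                  T_train = 8, seed = s))
    dt <- direct_train_snn(spec, dat$x, dat$y,
                           run_config("direct", epochs = 1, batch_size = 8,
                                      T_train = 8, seed = s))
    c(ft$trace$loss[1], dt$trace$loss[1])
  })
  expect_lt(mean(start_losses[1, ]), mean(start_losses[2, ]))
})

test_that("plateau scheduler reduces the rate only after sustained stalls", {
  sch <- spikeseg:::plateau_init(lr = 0.1, patience = 2, factor = 0.1,
                                 min_lr = 1e-6)
  sch <- spikeseg:::plateau_update(sch, 1.0)   # improves (from Inf)
  sch <- spikeseg:::plateau_update(sch, 1.1)   # stall 1
  expect_equal(sch$lr, 0.1)
  sch <- spikeseg:::plateau_update(sch, 1.05)  # stall 2 -> reduce
  expect_equal(sch$lr, 0.01)
  sch <- spikeseg:::plateau_update(sch, 0.5)   # improvement resets the wait
  expect_equal(sch$wait, 0)
})

test_that("non-finite losses abort with a diagnostic", {
  dat <- tiny_seg_data(n = 8, seed = 7)
  spec <- network_spec(c(32, 48), levels = 2, channels = c(2, 4),
                       bottleneck = 8, dropout = 0)
  ann <- build_ann(spec, seed = 1)
  ann$params$out[] <- NaN
  expect_error(train_ann(ann, dat$x, dat$y,
                         run_config("ann", epochs = 1, batch_size = 8)),
               "non-finite")
})

test_that("traces export as a delimited log table", {
  tr <- spikeseg:::new_trace()
  tr$batch <- 1:3; tr$loss <- c(1, 0.5, 0.4); tr$lr <- rep(1e-3, 3)
  tr$eval_batch <- 2L; tr$eval_dice <- 0.7
  p <- tempfile(fileext = ".tsv")
  write_trace(tr, p)
  tab <- utils::read.delim(p)
  expect_identical(names(tab), c("batch", "loss", "lr", "dice"))
  expect_equal(tab$dice[2], 0.7)
  expect_true(all(is.na(tab$dice[c(1, 3)])))
  unlink(p)
})
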