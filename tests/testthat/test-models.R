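test_that("network spec enforces the conversion constraints", {
  expect_error(network_spec(pooling = "max"), "average")
  expect_error(network_spec(bias = TRUE), "bias")
  expect_error(network_spec(batch_norm = TRUE), "normalization")
  expect_error(network_spec(upsample = "nearest"), "transposed")
  expect_error(network_spec(input_shape = c(30, 48), levels = 2), "divisible")
  expect_error(network_spec(channels = c(4, 8, 16), levels = 2), "per level")
  expect_error(network_spec(kernel = 4), "odd")
  expect_s3_class(network_spec(), "network_spec")
})

test_that("ANN and SNN builds share weight tensor shapes", {
  spec <- network_spec(c(16, 16), levels = 2, channels = c(3, 5),
                       bottleneck = 7)
  ann <- build_ann(spec, seed = 1)
  snn <- build_snn(spec, seed = 2)
  expect_identical(names(ann$params), names(snn$params))
  for (nm in names(ann$params))
    expect_identical(dim(ann$params[[nm]]), dim(snn$params[[nm]]))
  expect_identical(names(snn$thresholds), spiking_layer_names(spec))
  expect_true(all(snn$thresholds == 1))
  expect_error(build_snn(spec, thresholds = c(enc1 = 1)), "threshold")
  expect_error(build_snn(spec, thresholds = stats::setNames(
    rep(-1, 7), spiking_layer_names(spec))), "> 0")
})

test_that("zero-weight networks output probability one half everywhere", {
  spec <- network_spec(c(8, 8), levels = 1, channels = 2, bottleneck = 3,
                       dropout = 0)
  ann <- build_ann(spec, seed = 1)
  ann$params <- lapply(ann$params, function(w) w * 0)
  x <- array(0, c(8, 8, 1, 2))
  expect_equal(predict(ann, x), array(0.5, c(8, 8, 1, 2)))

  snn <- build_snn(spec, seed = 1, encoder_mode = "binary", T = 5)
  snn$params <- lapply(snn$params, function(w) w * 0)
  expect_equal(predict(snn, array(stats::runif(128), c(8, 8, 1, 2))),
               array(0.5, c(8, 8, 1, 2)))
})

test_that("hidden SNN spikes stay binary even under ternary encoding", {
  spec <- network_spec(c(8, 8), levels = 1, channels = 2, bottleneck = 3,
                       dropout = 0)
  params <- spikeseg:::init_unet_params(spec, seed = 4)
  v <- stats::setNames(rep(0.7, 4), spiking_layer_names(spec))
  img <- array(stats::runif(8 * 8 * 3) * 2 - 1, c(8, 8, 1, 3))
  set.seed(9)
  fw <- spikeseg:::snn_unet_forward(params, spec, v, img, T = 6,
                                    mode = "ternary", store_trace = TRUE)
  for (nm in spiking_layer_names(spec))
    for (t in 1:6)
      expect_true(all(fw$trace$s[[nm]][[t]] %in% c(0, 1)))
})

test_that("silent hidden layers leave the output at one half", {
  spec <- network_spec(c(8, 8), levels = 1, channels = 2, bottleneck = 3,
                       dropout = 0)
  params <- spikeseg:::init_unet_params(spec, seed = 4)
  v <- stats::setNames(rep(1e9, 4), spiking_layer_names(spec))
  fw <- spikeseg:::snn_unet_forward(params, spec, v,
                                    array(stats::runif(64), c(8, 8, 1, 1)),
                                    T = 8, mode = "binary")
  expect_equal(fw$prob, array(0.5, c(8, 8, 1, 1)))
})

test_that("segmentation losses follow their closed forms", {
  r <- array(c(1, 0, 1, 0, 0, 0, 1, 1), c(2, 2, 1, 2))
  eps <- 1e-5
  s <- pmin(pmax(r, eps), 1 - eps)
  expect_lt(bce_loss(s, r), 1e-4)
  expect_lt(dice_loss(r, r), 1e-5)
  expect_equal(bce_loss(array(0.5, dim(r)), r), log(2), tolerance = 1e-12)
  # symmetry of the cross-entropy
  p <- array(stats::runif(8), dim(r))
  expect_equal(bce_loss(p, r), bce_loss(1 - p, 1 - r))
  # empty prediction vs empty target: smoothing resolves 0/0 to zero loss
  z <- array(0, c(2, 2, 1, 1))
  expect_equal(dice_loss(z, z), 0)
  # empty prediction against k foreground pixels is maximally wrong
  expect_gt(dice_loss(array(0, dim(r)), r), 0.999)
  # combined loss weights
  expect_equal(combined_loss(r, r), 0.3 * bce_loss(r, r) + 0.7 * dice_loss(r, r))
  lc <- loss_config("bce_dice")
  expect_equal(lc$bce_weight, 0.3)
  expect_equal(lc$dice_weight, 0.7)
  expect_error(loss_config(bce_weight = 0.5, dice_weight = 0.6), "sum to 1")
  expect_error(bce_loss(array(0.5, c(2, 2)), array(1, c(2, 3))), "mismatch")
})

test_that("dice loss ignores added true-negative background", {
  p <- array(0, c(4, 4, 1, 1)); p[2:3, 2:3, 1, 1] <- 1
  big_p <- array(0, c(8, 8, 1, 1)); big_p[2:3, 2:3, 1, 1] <- 1
  expect_equal(dice_loss(p, p), dice_loss(big_p, big_p))
})

test_that("loss gradients match numerical differentiation", {
  set.seed(3)
  logit <- array(stats::rnorm(2 * 3 * 1 * 2), c(2, 3, 1, 2))
  targ <- array(stats::rbinom(12, 1, 0.5), c(2, 3, 1, 2))
  for (kind in c("bce", "dice", "bce_dice")) {
    cfg <- loss_config(kind)
    f <- function(lg) segmentation_loss(1 / (1 + exp(-lg)), targ, cfg)
    g <- spikeseg:::loss_grad_logit(1 / (1 + exp(-logit)), targ, cfg)
    eps <- 1e-6
    for (i in sample(length(logit), 5)) {
      lp <- logit; lp[i] <- lp[i] + eps
      lm <- logit; lm[i] <- lm[i] - eps
      expect_equal(g[i], (f(lp) - f(lm)) / (2 * eps), tolerance = 1e-5)
    }
  }
})

test_that("ANN backward matches finite differences on a tiny U-Net", {
  spec <- network_spec(c(8, 8), levels = 2, channels = c(2, 3),
                       bottleneck = 4, dropout = 0)
  params <- spikeseg:::init_unet_params(spec, seed = 7)
  set.seed(7)
  x <- array(stats::runif(8 * 8 * 2), c(8, 8, 1, 2))
  y <- array(stats::rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 1, 2))
  lc <- loss_config("bce_dice")
  lossfun <- function(p) {
    fw <- spikeseg:::unet_forward(p, spec, x)
    segmentation_loss(fw$prob, y, lc)
  }
  fw <- spikeseg:::unet_forward(params, spec, x, keep_cache = TRUE)
  gr <- spikeseg:::unet_backward(params, spec, fw$cache,
                                 spikeseg:::loss_grad_logit(fw$prob, y, lc))
  eps <- 1e-6
  for (nm in names(params)) {
    for (i in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      expect_equal(gr[[nm]][i], (lossfun(pp) - lossfun(pm)) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})

test_that("ANN forward/backward on a 32x48 image is finite", {
  spec <- network_spec(c(32, 48), levels = 2, channels = c(4, 8),
                       bottleneck = 16, dropout = 0)
  params <- spikeseg:::init_unet_params(spec, seed = 1)
  x <- array(stats::runif(32 * 48), c(32, 48, 1, 1))
  y <- array(stats::rbinom(32 * 48, 1, 0.1), c(32, 48, 1, 1))
  fw <- spikeseg:::unet_forward(params, spec, x, keep_cache = TRUE)
  expect_true(all(is.finite(fw$prob)))
  gr <- spikeseg:::unet_backward(params, spec, fw$cache,
                                 spikeseg:::loss_grad_logit(fw$prob, y,
                                                            loss_config()))
  expect_true(all(vapply(gr, function(g) all(is.finite(g)), TRUE)))
})
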