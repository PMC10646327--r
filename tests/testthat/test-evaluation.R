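test_that("dice coefficient counts overlap correctly", {
  m <- matrix(0, 4, 4)
  a <- m; a[1:2, 1:2] <- 1                      # 4-pixel square
  b <- m; b[2:3, 1:3] <- 0; b[1:2, 2:3] <- 1    # overlaps a in 2 pixels
  expect_equal(dice_coefficient(a, a), 1, tolerance = 1e-5)
  expect_equal(dice_coefficient(a, b), 2 * 2 / (4 + 4), tolerance = 1e-4)
  disj <- m; disj[3:4, 3:4] <- 1
  expect_lt(dice_coefficient(a, disj), 1e-4)
  expect_error(dice_coefficient(matrix(0, 2, 2), matrix(0, 2, 3)), "mismatch")
})

make_single_slice_volumes <- function(n = 3, seed = 1) {
  cfg <- toy_segmentation_config(n_subjects = n, seed = seed, folds = 1L)
  generate_dataset(cfg)$volumes
}

test_that("evaluation aggregates slice-wise and subject-wise scores", {
  vols <- make_single_slice_volumes(3)
  sl <- spikeseg:::stack_slices(vols)
  # perfect probabilistic predictor
  rep_perfect <- spikeseg:::report_from_probs(sl$y * 0.98 + 0.01, sl, 0.5)
  expect_equal(rep_perfect$dice_2d_mean, 1, tolerance = 1e-4)
  expect_equal(rep_perfect$dice_3d_mean, 1, tolerance = 1e-4)
  # single-slice subjects: 2D and 3D scores coincide
  expect_equal(rep_perfect$per_slice$dice[rep_perfect$per_slice$scored],
               rep_perfect$per_subject$dice, tolerance = 1e-6)
  # strict threshold: an all-0.5 map predicts background everywhere
  rep_half <- spikeseg:::report_from_probs(array(0.5, dim(sl$y)), sl, 0.5)
  expect_lt(rep_half$dice_2d_mean, 1e-3)
  expect_error(evaluate_model(build_ann(network_spec()), list()), "empty")
})

test_that("empty-empty slices are excluded from the 2D mean", {
  sl <- list(x = array(0, c(4, 4, 1, 2)), y = array(0, c(4, 4, 1, 2)),
             subject = c("a", "b"), slice = c(1L, 1L))
  sl$y[1:2, 1:2, 1, 1] <- 1
  probs <- sl$y * 0.9 + 0.05
  rep <- spikeseg:::report_from_probs(probs, sl, 0.5)
  expect_identical(sum(rep$per_slice$scored), 1L)
  expect_equal(rep$dice_2d_mean, 1, tolerance = 1e-4)
})

test_that("threshold sweep covers the fine grid and the scaling identity holds", {
  vols <- make_single_slice_volumes(2, seed = 9)
  spec <- network_spec(c(32, 48), levels = 2, channels = c(2, 4),
                       bottleneck = 8, dropout = 0)
  ann <- build_ann(spec, seed = 2)
  tab <- threshold_sweep(ann, vols)
  expect_equal(tab$threshold, seq(0.43, 0.54, by = 0.01))
  expect_true(all(tab$dice_2d >= 0 & tab$dice_2d <= 1))
  expect_true(all(tab$dice_3d >= 0 & tab$dice_3d <= 1))
  coarse <- threshold_sweep(ann, vols, coarse = TRUE)
  expect_equal(coarse$threshold, seq(0.1, 0.6, by = 0.1))
  expect_error(threshold_sweep(ann, vols, thresholds = c(0, 0.5)), "in \\(0, 1\\)")
  # thresholding at t is the same labeling as scaling outputs by 0.5/t and
  # thresholding at 0.5
  p <- predict(ann, spikeseg:::stack_slices(vols)$x)
  for (t in c(0.2, 0.43, 0.5, 0.54))
    expect_identical(p > t, (p * (0.5 / t)) > 0.5)
})

test_that("firing reports are bounded, silent when silent, and track rates", {
  spec <- network_spec(c(8, 8), levels = 1, channels = 2, bottleneck = 3,
                       dropout = 0)
  snn <- build_snn(spec, seed = 1, encoder_mode = "binary", T = 10)
  snn$thresholds[] <- 1e9
  img <- array(stats::runif(64 * 2), c(8, 8, 1, 2))
  rep_silent <- firing_frequencies(snn, img, label = "silent")
  expect_true(all(rep_silent$rate == 0))
  snn$thresholds[] <- 0.5
  rep_live <- firing_frequencies(snn, img)
  expect_true(all(rep_live$rate >= 0 & rep_live$rate <= 1))
  # the encoder itself realizes the rate law on a constant input
  p <- 0.37
  st <- poisson_encode(array(p, c(5, 5)), 4000, mode = "binary", seed = 3)
  expect_lt(abs(mean(abs(st)) - p), 4 * sqrt(p * (1 - p) / (4000 * 25)))
})

test_that("convergence comparison aligns checkpoints and finds crossings", {
  tr <- function(b, d) {
    t <- spikeseg:::new_trace(); t$eval_batch <- b; t$eval_dice <- d; t
  }
  cc <- convergence_compare(tr(c(10L, 20L, 30L), c(0.5, 0.85, 0.9)),
                            tr(c(10L, 20L, 30L), c(0.1, 0.4, 0.82)),
                            target = 0.8)
  expect_equal(cc$crossing[["finetune"]], 20L)
  expect_equal(cc$crossing[["direct"]], 30L)
  expect_identical(names(cc$table), c("batch", "finetune", "direct"))
  same <- tr(c(5L, 10L), c(0.81, 0.9))
  cc2 <- convergence_compare(same, same)
  expect_equal(cc2$crossing[["finetune"]], cc2$crossing[["direct"]])
  never <- tr(c(10L, 20L), c(0.1, 0.2))
  expect_true(is.na(convergence_compare(tr(c(10L, 20L), c(0.9, 0.9)),
                                        never)$crossing[["direct"]]))
  expect_error(convergence_compare(tr(c(10L, 20L), c(0.1, 0.2)),
                                   tr(c(15L, 25L), c(0.1, 0.2))),
               "misaligned")
})
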