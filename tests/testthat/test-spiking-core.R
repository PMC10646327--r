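test_that("integrate-and-fire step follows the subtractive-reset recurrence", {
  st <- if_step(0.5, 1.0, 0.7)
  expect_equal(st$spikes, 1)
  expect_equal(st$u, 0.2)

  st <- if_step(0.0, 1.0, 0.0)
  expect_equal(st$spikes, 0)
  expect_equal(st$u, 0)

  # sub-threshold accumulation: the potential never decays without a spike
  st <- if_step(0.9, 1.0, 0.05)
  expect_equal(st$spikes, 0)
  expect_equal(st$u, 0.95)

  # firing requires strictly exceeding the threshold
  st <- if_step(0.5, 1.0, 0.5)
  expect_equal(st$spikes, 0)

  expect_error(if_step(0, 1, NaN, layer = "enc1"), "enc1")
  expect_error(if_step(0, -1, 0.1), "positive")
})

test_that("output-layer accumulation is plain summation without reset", {
  u <- accumulate_output(0, 1.0)
  u <- accumulate_output(u, -0.5)
  expect_equal(u, 0.5)
  expect_equal(accumulate_output(numeric(4), rep(0.25, 4)) * 8,
               rep(0.25 * 8, 4))
  expect_equal(accumulate_output(c(1, 2), c(0, 0)), c(1, 2))
  u <- 0
  for (t in 1:7) u <- accumulate_output(u, 0.3)
  expect_equal(u, 0.3 * 7)
})

test_that("surrogate gradient is the linear hat around the threshold", {
  expect_equal(surrogate_grad(1, 1, alpha = 0.3), 0.3)
  expect_equal(surrogate_grad(2.0, 1, alpha = 0.3), 0)
  expect_equal(surrogate_grad(-0.5, 0.5, alpha = 0.7), 0)
  expect_equal(surrogate_grad(1.5, 1, alpha = 0.3), 0.15)
  u <- seq(-2, 4, by = 0.01)
  g <- surrogate_grad(u, 1, alpha = 0.4)
  expect_true(all(g >= 0))
  expect_equal(g, rev(g))                       # symmetric about u = v
  expect_true(all(g[abs(u - 1) >= 1] == 0))     # support is |u - v| < 1
  expect_lt(max(abs(diff(g))), 0.4 * 0.011)     # continuity (Lipschitz)
  expect_error(surrogate_grad(1, 1, alpha = -1), "positive")
})

test_that("poisson encoder enforces ranges and realizes the rate code", {
  expect_error(poisson_encode(-0.1, 10, mode = "binary"), "negative")
  expect_error(poisson_encode(1.4, 10, mode = "binary"), "range")
  expect_error(poisson_encode(-1.2, 10, mode = "ternary"), "range")

  expect_true(all(unclass(poisson_encode(0, 500, mode = "binary")) == 0))
  expect_true(all(unclass(poisson_encode(1, 500, mode = "binary")) == 1))

  st <- poisson_encode(c(0.3, -0.6), 2000, mode = "ternary", seed = 4)
  expect_s3_class(st, "spike_train")
  expect_true(all(unclass(st) %in% c(-1, 0, 1)))
  expect_true(all(st[, 2] <= 0))             # negative value, negative spikes
  expect_lt(abs(mean(abs(st[, 1])) - 0.3), 4 * sqrt(0.3 * 0.7 / 2000))
  expect_lt(abs(mean(abs(st[, 2])) - 0.6), 4 * sqrt(0.6 * 0.4 / 2000))

  a <- poisson_encode(matrix(runif(6), 2), 7, mode = "binary", seed = 11)
  expect_identical(dim(a), c(7L, 2L, 3L))
})

test_that("encoding with a fixed seed is bit-reproducible", {
  v <- matrix(runif(8), 2)
  a <- poisson_encode(v, 25, mode = "binary", seed = 99)
  b <- poisson_encode(v, 25, mode = "binary", seed = 99)
  expect_identical(unclass(a), unclass(b))
})

test_that("spike trains reject values outside the declared set", {
  expect_error(spike_train(matrix(c(0, 2), 1), mode = "binary"), "declared set")
  expect_error(spike_train(matrix(-1, 1), mode = "binary"), "declared set")
  expect_silent(spike_train(matrix(c(-1, 0, 1), 1), mode = "ternary"))
})

test_that("vectorized spiking layer matches the scalar reference", {
  set.seed(21)
  for (rep in 1:10) {
    n_in <- sample(2:10, 1); n_out <- sample(2:10, 1); T <- sample(5:30, 1)
    W <- matrix(rnorm(n_out * n_in), n_out, n_in)
    X <- matrix(rbinom(T * n_in, 1, 0.4), T, n_in)
    v <- runif(1, 0.3, 2)
    fast <- run_spiking_layer(W, spike_train(X, "binary"), v)
    ref <- scalar_spiking_layer(W, X, v)
    expect_identical(unclass(fast$train)[, ], ref$S)
    expect_identical(fast$u, ref$u)
    # subtractive-reset conservation: u_T = sum(inputs) - v * spike count
    Z <- X %*% t(W)
    expect_equal(fast$u, colSums(Z) - v * fast$spike_count, tolerance = 1e-10)
  }
  z <- run_spiking_layer(matrix(rnorm(6), 2), spike_train(matrix(0, 10, 3),
                                                          "binary"), 1)
  expect_true(all(unclass(z$train) == 0))
})

test_that("spike-train dumps round-trip through the compressed format", {
  st <- poisson_encode(matrix(runif(12) * 2 - 1, 3), 9, mode = "ternary",
                       seed = 2)
  p <- tempfile(fileext = ".spk.gz")
  write_spike_train(st, p)
  back <- read_spike_train(p)
  expect_equal(unclass(back)[, , ], unclass(st)[, , ], ignore_attr = TRUE)
  expect_identical(attr(back, "mode"), "ternary")
  unlink(p)
})
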