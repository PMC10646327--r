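# Independent reference implementations used as oracles. These are written as
# plainly as possible -- scalar loops, forward-mode tangents -- and must stay
# independent of the vectorized package code paths they check.

# Naive dense spiking layer: if_step applied neuron by neuron, step by step.
# The weighted input is precomputed exactly as the vectorized driver computes
# it (one matrix product); the scalar reference is the IF recurrence itself,
# which must reproduce the vectorized dynamics bit for bit.
scalar_spiking_layer <- function(W, X, v) {
  Z <- X %*% t(W)
  T <- nrow(X); n_out <- nrow(W)
  S <- matrix(0, T, n_out)
  u <- numeric(n_out)
  for (t in seq_len(T)) {
    for (i in seq_len(n_out)) {
      st <- if_step(u[i], v, Z[t, i])
      u[i] <- st$u
      S[t, i] <- st$spikes
    }
  }
  list(S = S, u = u)
}

# Forward-mode (dual-number) gradient of the unrolled dense SNN with the spike
# derivative DEFINED as the linear surrogate. One call per scalar parameter.
fwdmode_grad_mlp <- function(W, v, xs, target, alpha, li, idx) {
  T <- length(xs)
  nh <- length(W) - 1L
  N <- nrow(xs[[1]])
  dW <- lapply(W, function(w) array(0, dim(w)))
  dW[[li]][idx] <- 1
  u <- lapply(W[seq_len(nh)], function(w) matrix(0, N, nrow(w)))
  du <- lapply(W[seq_len(nh)], function(w) matrix(0, N, nrow(w)))
  u_out <- matrix(0, N, nrow(W[[nh + 1L]]))
  du_out <- matrix(0, N, nrow(W[[nh + 1L]]))
  for (t in seq_len(T)) {
    A <- xs[[t]]; dA <- matrix(0, nrow(A), ncol(A))
    for (i in seq_len(nh)) {
      Z <- A %*% t(W[[i]])
      dZ <- dA %*% t(W[[i]]) + A %*% t(dW[[i]])
      m <- u[[i]] + Z
      dm <- du[[i]] + dZ
      s <- (m > v[i]) * 1
      g <- alpha * pmax(0, 1 - abs(m - v[i]))
      ds <- g * dm
      u[[i]] <- m - v[i] * s
      du[[i]] <- dm - v[i] * ds
      A <- s; dA <- ds
    }
    u_out <- u_out + A %*% t(W[[nh + 1L]])
    du_out <- du_out + dA %*% t(W[[nh + 1L]]) + A %*% t(dW[[nh + 1L]])
  }
  prob <- 1 / (1 + exp(-u_out / T))
  dL_duout <- (prob - target) / length(prob) / T
  sum(dL_duout * du_out)
}

# Forward-mode gradient through the unrolled convolutional SNN (U-Net wiring),
# driven by the recorded input spike trains so both sides see the same draws.
fwdmode_grad_unet <- function(params, spec, v, xtrace, target, alpha, lname, idx) {
  conv2d <- spikeseg:::conv2d; avgpool2 <- spikeseg:::avgpool2
  upconv2 <- spikeseg:::upconv2; channel_cat <- spikeseg:::channel_cat
  T <- length(xtrace)
  L <- spec$levels
  d <- dim(xtrace[[1]])
  dparams <- lapply(params, function(w) array(0, dim(w)))
  dparams[[lname]][idx] <- 1
  sh <- spikeseg:::unet_shapes(spec)$act
  lnames <- spiking_layer_names(spec)
  u <- lapply(sh[lnames], function(s) array(0, c(s, d[4])))
  du <- lapply(sh[lnames], function(s) array(0, c(s, d[4])))
  u_out <- array(0, c(spec$input_shape, 1, d[4]))
  du_out <- array(0, c(spec$input_shape, 1, d[4]))
  ifstep <- function(nm, z, dz) {
    m <- u[[nm]] + z; dm <- du[[nm]] + dz
    s <- (m > v[[nm]]) * 1
    g <- alpha * pmax(0, 1 - abs(m - v[[nm]]))
    ds <- g * dm
    u[[nm]] <<- m - v[[nm]] * s
    du[[nm]] <<- dm - v[[nm]] * ds
    list(s = s, ds = ds)
  }
  for (t in seq_len(T)) {
    s <- xtrace[[t]]
    ds <- array(0, d)
    enc_s <- list(); enc_ds <- list()
    for (l in seq_len(L)) {
      nm <- paste0("enc", l)
      r <- ifstep(nm, conv2d(s, params[[nm]]),
                  conv2d(ds, params[[nm]]) + conv2d(s, dparams[[nm]]))
      enc_s[[l]] <- r$s; enc_ds[[l]] <- r$ds
      s <- avgpool2(r$s); ds <- avgpool2(r$ds)
    }
    r <- ifstep("bott", conv2d(s, params$bott),
                conv2d(ds, params$bott) + conv2d(s, dparams$bott))
    s <- r$s; ds <- r$ds
    for (l in L:1) {
      un <- paste0("up", l); dn <- paste0("dec", l)
      r <- ifstep(un, upconv2(s, params[[un]]),
                  upconv2(ds, params[[un]]) + upconv2(s, dparams[[un]]))
      ct <- channel_cat(r$s, enc_s[[l]])
      dct <- channel_cat(r$ds, enc_ds[[l]])
      r <- ifstep(dn, conv2d(ct, params[[dn]]),
                  conv2d(dct, params[[dn]]) + conv2d(ct, dparams[[dn]]))
      s <- r$s; ds <- r$ds
    }
    u_out <- u_out + conv2d(s, params$out, pad = 0L)
    du_out <- du_out + conv2d(ds, params$out, pad = 0L) +
      conv2d(s, dparams$out, pad = 0L)
  }
  prob <- 1 / (1 + exp(-u_out / T))
  dL <- (prob - target) / length(prob) / T
  sum(dL * du_out)
}

# tiny training set of separable 2D blobs, used for sanity training tests
tiny_seg_data <- function(n = 12, seed = 1) {
  cfg <- toy_segmentation_config(n_subjects = n, seed = seed)
  ds <- generate_dataset(cfg)
  spikeseg:::stack_slices(ds$volumes)
}
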