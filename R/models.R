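#' Declarative U-Net architecture shared by the ANN and the SNN
#'
#' Describes the conversion-friendly modified U-Net: an encoder of
#' convolution + average-pooling blocks, a bottleneck, and a decoder of
#' 2x2/stride-2 transposed convolutions with skip connections concatenating the
#' matching encoder feature maps, closed by a 1x1 convolution and a sigmoid
#' producing one probability per input pixel. Constraints required for
#' ANN-SNN conversion are enforced at construction: no bias terms, no
#' normalization layers, average pooling only (max-pooling has no faithful
#' rate-coded equivalent).
#'
#' @param input_shape `c(H, W)` of the single-channel input; both must be
#'   divisible by `2^levels`.
#' @param levels number of encoder levels.
#' @param channels integer vector of `levels` channel counts.
#' @param bottleneck channels of the bottleneck block.
#' @param kernel odd convolution kernel size (same-padding).
#' @param dropout dropout rate applied after each encoder/bottleneck/decoder
#'   activation during training.
#' @param pooling,upsample,bias,batch_norm conversion constraints; any value
#'   other than `"average"` / `"transposed"` / `FALSE` / `FALSE` is rejected.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(input_shape = c(32L, 48L), levels = 2L,
                         channels = c(4L, 8L), bottleneck = 16L, kernel = 3L,
                         dropout = 0.1, pooling = "average",
                         upsample = "transposed", bias = FALSE,
                         batch_norm = FALSE) {
  if (!identical(pooling, "average"))
    stop("only average pooling is supported: max-pooling breaks rate-coded conversion")
  if (isTRUE(bias))
    stop("bias terms are not supported: they interfere with firing thresholds after conversion")
  if (isTRUE(batch_norm))
    stop("batch normalization is not supported in the conversion-friendly architecture")
  if (!identical(upsample, "transposed"))
    stop("only transposed-convolution upsampling is supported")
  if (length(channels) != levels) stop("'channels' must have one entry per level")
  if (kernel %% 2L != 1L) stop("'kernel' must be odd (same-padding convolutions)")
  if (any(input_shape %% 2L^levels != 0L))
    stop("input dimensions must be divisible by 2^levels for pooling")
  if (dropout < 0 || dropout >= 1) stop("'dropout' must be in [0, 1)")
  structure(list(input_shape = as.integer(input_shape), levels = as.integer(levels),
                 channels = as.integer(channels), bottleneck = as.integer(bottleneck),
                 kernel = as.integer(kernel), dropout = dropout),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(
    "<network_spec> %dx%d input, %d levels (channels %s), bottleneck %d,\n  %dx%d kernels, avg-pool, transposed-conv upsampling, dropout %.2f,\n  no bias / no batch-norm, sigmoid pixel head\n",
    x$input_shape[1], x$input_shape[2], x$levels,
    paste(x$channels, collapse = "/"), x$bottleneck, x$kernel, x$kernel,
    x$dropout))
  invisible(x)
}

# Names of the weight tensors, in topological (forward) order. All but "out"
# are spiking layers in the SNN build.
unet_layer_names <- function(spec) {
  L <- spec$levels
  c(paste0("enc", seq_len(L)), "bott",
    as.vector(rbind(paste0("up", L:1), paste0("dec", L:1))), "out")
}

#' @rdname build_ann
#' @export
spiking_layer_names <- function(spec) {
  nm <- unet_layer_names(spec)
  nm[nm != "out"]
}

# He-style initialization (gain sqrt(2/fan_in)), no biases anywhere.
init_unet_params <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- spec$kernel
  L <- spec$levels
  ch <- spec$channels
  mk <- function(kh, kw, cin, cout) {
    array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
          c(kh, kw, cin, cout))
  }
  p <- list()
  cin <- 1L
  for (l in seq_len(L)) {
    p[[paste0("enc", l)]] <- mk(k, k, cin, ch[l])
    cin <- ch[l]
  }
  p$bott <- mk(k, k, ch[L], spec$bottleneck)
  cin <- spec$bottleneck
  for (l in L:1) {
    p[[paste0("up", l)]] <- mk(2L, 2L, cin, ch[l])
    p[[paste0("dec", l)]] <- mk(k, k, 2L * ch[l], ch[l])
    cin <- ch[l]
  }
  p$out <- mk(1L, 1L, ch[1], 1L)
  p
}

#' Build the ANN or the SNN realization of a network spec
#'
#' `build_ann` instantiates the spec as a ReLU network trainable by gradient
#' descent; `build_snn` instantiates the identical topology with
#' integrate-and-fire neurons in place of every hidden ReLU and a non-firing
#' accumulator + sigmoid at the output. Both carry weight tensors of identical
#' shapes, which is what makes conversion a pure weight copy.
#'
#' @param spec a [network_spec].
#' @param seed optional seed for the weight initialization.
#' @param thresholds named list/vector of positive per-layer firing thresholds,
#'   one per spiking layer (see `spiking_layer_names`); defaults to 1 for every
#'   layer, the state a freshly converted network starts from.
#' @param encoder_mode how inputs are rate-coded in the SNN forward pass.
#' @param T default number of simulation time steps for the SNN.
#' @return An object of class `spikeseg_ann` or `spikeseg_snn`.
#' @export
build_ann <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  structure(list(spec = spec, params = init_unet_params(spec, seed),
                 trace = NULL),
            class = "spikeseg_ann")
}

#' @rdname build_ann
#' @export
build_snn <- function(spec, thresholds = NULL, seed = NULL,
                      encoder_mode = c("ternary", "binary"), T = 32L) {
  stopifnot(inherits(spec, "network_spec"))
  encoder_mode <- match.arg(encoder_mode)
  nm <- spiking_layer_names(spec)
  if (is.null(thresholds)) {
    thresholds <- stats::setNames(rep(1, length(nm)), nm)
  } else {
    thresholds <- unlist(thresholds)
    if (!setequal(names(thresholds), nm))
      stop("threshold count mismatch: need one per spiking layer (",
           paste(nm, collapse = ", "), ")")
    thresholds <- thresholds[nm]
  }
  if (any(thresholds <= 0)) stop("all firing thresholds must be > 0")
  structure(list(spec = spec, params = init_unet_params(spec, seed),
                 thresholds = thresholds, encoder_mode = encoder_mode,
                 T = as.integer(T), trace = NULL),
            class = "spikeseg_snn")
}

#' @export
print.spikeseg_ann <- function(x, ...) {
  cat("ReLU U-Net (conversion-friendly ANN)\n")
  print(x$spec)
  cat(sprintf("  parameters: %d tensors, %d weights\n", length(x$params),
              sum(vapply(x$params, length, 1L))))
  if (!is.null(x$trace))
    cat(sprintf("  trained: %d batches, final loss %.4f\n",
                length(x$trace$loss), utils::tail(x$trace$loss, 1)))
  invisible(x)
}

#' @export
print.spikeseg_snn <- function(x, ...) {
  cat(sprintf("Spiking U-Net (IF neurons, %s encoder, T=%d)\n",
              x$encoder_mode, x$T))
  print(x$spec)
  cat("  thresholds: ",
      paste(sprintf("%s=%.3g", names(x$thresholds), x$thresholds),
            collapse = ", "), "\n")
  invisible(x)
}

# ---- ANN forward / backward -------------------------------------------------

sample_dropout_masks <- function(spec, n) {
  p <- spec$dropout
  if (p <= 0) return(NULL)
  sh <- unet_shapes(spec)
  masks <- list()
  for (nm in names(sh$act)) {
    if (!nm %in% c(paste0("enc", seq_len(spec$levels)), "bott",
                   paste0("dec", seq_len(spec$levels)))) next
    d <- c(sh$act[[nm]], n)
    masks[[nm]] <- array((stats::runif(prod(d)) >= p) * 1, d)
  }
  masks
}

# spatial/channel shape of each activation, keyed by layer name
unet_shapes <- function(spec) {
  L <- spec$levels
  hw <- spec$input_shape
  act <- list()
  for (l in seq_len(L)) {
    act[[paste0("enc", l)]] <- c(hw, spec$channels[l])
    hw <- hw %/% 2L
  }
  act$bott <- c(hw, spec$bottleneck)
  for (l in L:1) {
    hw <- hw * 2L
    act[[paste0("up", l)]] <- c(hw, spec$channels[l])
    act[[paste0("dec", l)]] <- c(hw, spec$channels[l])
  }
  list(act = act)
}

# Forward pass of the ReLU network. x: (H, W, 1, N). Returns logits,
# probabilities and (optionally) everything the backward pass needs.
unet_forward <- function(params, spec, x, masks = NULL, keep_cache = FALSE) {
  L <- spec$levels
  cache <- if (keep_cache) list(x = x, masks = masks, pre = list(), act = list())
  s <- x
  enc_act <- list()
  for (l in seq_len(L)) {
    nm <- paste0("enc", l)
    z <- conv2d(s, params[[nm]])
    a <- relu(z)
    if (!is.null(masks[[nm]])) a <- a * masks[[nm]]
    if (keep_cache) { cache$pre[[nm]] <- z; cache$act[[nm]] <- a }
    enc_act[[l]] <- a
    s <- avgpool2(a)
  }
  z <- conv2d(s, params$bott)
  a <- relu(z)
  if (!is.null(masks$bott)) a <- a * masks$bott
  if (keep_cache) { cache$pre$bott <- z; cache$act$bott <- a }
  s <- a
  for (l in L:1) {
    un <- paste0("up", l); dn <- paste0("dec", l)
    zu <- upconv2(s, params[[un]])
    au <- relu(zu)
    if (keep_cache) { cache$pre[[un]] <- zu; cache$act[[un]] <- au }
    ct <- channel_cat(au, enc_act[[l]])
    zd <- conv2d(ct, params[[dn]])
    ad <- relu(zd)
    if (!is.null(masks[[dn]])) ad <- ad * masks[[dn]]
    if (keep_cache) { cache$pre[[dn]] <- zd; cache$act[[dn]] <- ad }
    s <- ad
  }
  logit <- conv2d(s, params$out, pad = 0L)
  list(prob = sigmoid(logit), logit = logit, cache = cache)
}

# Backward pass; dlogit is dLoss/dlogit. Returns gradients keyed like params.
unet_backward <- function(params, spec, cache, dlogit) {
  L <- spec$levels
  masks <- cache$masks
  grads <- list()
  bw <- conv2d_bwd(cache$act[[paste0("dec", 1L)]], params$out, dlogit, pad = 0L)
  grads$out <- bw$dw
  ds <- bw$dx
  denc <- vector("list", L)
  for (l in seq_len(L)) {
    dn <- paste0("dec", l); un <- paste0("up", l)
    if (!is.null(masks[[dn]])) ds <- ds * masks[[dn]]
    dz <- ds * (cache$pre[[dn]] > 0)
    au <- relu(cache$pre[[un]])
    ct <- channel_cat(au, cache$act[[paste0("enc", l)]])
    bw <- conv2d_bwd(ct, params[[dn]], dz)
    grads[[dn]] <- bw$dw
    sp <- channel_split(bw$dx, spec$channels[l])
    denc[[l]] <- sp[[2]]
    dzu <- sp[[1]] * (cache$pre[[un]] > 0)
    prev <- if (l == L) cache$act$bott else cache$act[[paste0("dec", l + 1L)]]
    bw <- upconv2_bwd(prev, params[[un]], dzu)
    grads[[un]] <- bw$dw
    ds <- bw$dx
  }
  if (!is.null(masks$bott)) ds <- ds * masks$bott
  dz <- ds * (cache$pre$bott > 0)
  bw <- conv2d_bwd(avgpool2(cache$act[[paste0("enc", L)]]), params$bott, dz)
  grads$bott <- bw$dw
  ds <- avgpool2_bwd(bw$dx) + denc[[L]]
  for (l in L:1) {
    nm <- paste0("enc", l)
    if (!is.null(masks[[nm]])) ds <- ds * masks[[nm]]
    dz <- ds * (cache$pre[[nm]] > 0)
    inp <- if (l == 1L) cache$x else avgpool2(cache$act[[paste0("enc", l - 1L)]])
    bw <- conv2d_bwd(inp, params[[nm]], dz)
    grads[[nm]] <- bw$dw
    if (l > 1L) ds <- avgpool2_bwd(bw$dx) + denc[[l - 1L]]
  }
  grads
}

#' Predict per-pixel probabilities from a trained network
#'
#' For the ANN this is a deterministic ReLU forward pass. For the SNN the input
#' is Poisson rate-coded over `T` time steps, hidden IF layers emit spikes, the
#' non-firing output layer accumulates its weighted input, and the sigmoid of
#' the time-averaged accumulated potential gives the probability map. Dropout
#' is inactive at prediction time.
#'
#' @param object a `spikeseg_ann` or `spikeseg_snn`.
#' @param images array `(H, W, 1, N)` (a single `(H, W)` slice is accepted), in
#'   the normalization the network was trained with.
#' @param T,encoder_mode SNN simulation length / encoder; default to the values
#'   stored in the object.
#' @param batch_size maximum samples simulated at once.
#' @param ... unused.
#' @return Probability array `(H, W, 1, N)`.
#' @export
predict.spikeseg_ann <- function(object, images, batch_size = 64L, ...) {
  images <- as_image_batch(images)
  out <- array(0, dim(images))
  for (ix in batch_indices(dim(images)[4L], batch_size)) {
    out[, , , ix] <- unet_forward(object$params, object$spec,
                                  images[, , , ix, drop = FALSE])$prob
  }
  out
}

#' @rdname predict.spikeseg_ann
#' @export
predict.spikeseg_snn <- function(object, images, T = object$T,
                                 encoder_mode = object$encoder_mode,
                                 batch_size = 32L, ...) {
  images <- as_image_batch(images)
  out <- array(0, dim(images))
  for (ix in batch_indices(dim(images)[4L], batch_size)) {
    fwd <- snn_unet_forward(object$params, object$spec, object$thresholds,
                            images[, , , ix, drop = FALSE], T = T,
                            mode = encoder_mode)
    out[, , , ix] <- fwd$prob
  }
  out
}

as_image_batch <- function(images) {
  d <- dim(images)
  if (is.null(d)) stop("'images' must be an array")
  if (length(d) == 2L) dim(images) <- c(d, 1L, 1L)
  if (length(d) == 3L) dim(images) <- c(d[1:2], 1L, d[3L])
  if (length(dim(images)) != 4L) stop("'images' must be (H, W, 1, N)")
  images
}

batch_indices <- function(n, size) {
  split(seq_len(n), ceiling(seq_len(n) / size))
}
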