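#' Spike trains
#'
#' A spike train is a time-major numeric array whose first dimension indexes
#' simulation time steps and whose remaining dimensions index neurons. Entries
#' are restricted to `{0, 1}` (binary mode) or `{-1, 0, 1}` (ternary mode);
#' ternary trains arise from rate-coding zero-mean-normalized inputs, where a
#' negative target value emits negative spikes.
#'
#' @param values numeric array; first dimension is time.
#' @param mode `"binary"` or `"ternary"`.
#' @return An object of class `spike_train`: the values array with attributes
#'   `mode` and `T` (number of time steps).
#' @export
spike_train <- function(values, mode = c("binary", "ternary")) {
  mode <- match.arg(mode)
  values <- as.array(values)
  if (length(dim(values)) < 2L) dim(values) <- c(length(values), 1L)
  T <- dim(values)[1L]
  if (T < 1L) stop("a spike train needs at least one time step")
  allowed <- if (mode == "binary") c(0, 1) else c(-1, 0, 1)
  if (!all(values %in% allowed)) {
    stop("spike values outside the declared set {", paste(allowed, collapse = ", "), "}")
  }
  structure(values, mode = mode, T = T, class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<spike_train> mode=%s, T=%d, neurons=%s, firing rate=%.4f\n",
              attr(x, "mode"), attr(x, "T"),
              paste(d[-1], collapse = "x"), mean(abs(x))))
  invisible(x)
}

#' Single integrate-and-fire step with subtractive reset
#'
#' Implements one step of the IF recurrence: the weighted input is integrated
#' into the membrane potential, a spike is emitted wherever the potential
#' strictly exceeds the layer threshold, and the threshold is subtracted from
#' the potential of the neurons that fired (soft reset). The potential never
#' decays on its own: a silent neuron holds its charge.
#'
#' @param u numeric vector/array of membrane potentials.
#' @param v positive scalar firing threshold for the layer.
#' @param input weighted input per neuron, same shape as `u`.
#' @param layer optional layer name used in error messages.
#' @return `list(spikes, u)` with the emitted `{0,1}` spikes and the updated
#'   potentials.
#' @export
if_step <- function(u, v, input, layer = "IF layer") {
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
    stop(layer, ": firing threshold must be a positive finite scalar")
  if (!all(is.finite(input)))
    stop(layer, ": non-finite weighted input")
  u <- u + input
  s <- (u > v) * 1
  list(spikes = s, u = u - v * s)
}

#' Non-firing output-layer accumulation
#'
#' Output-layer neurons integrate their weighted input without ever firing or
#' resetting, so after `T` steps the potential is the plain sum of the inputs.
#' A sigmoid over the (scaled) final potential yields per-pixel probabilities.
#'
#' @param u current accumulated potentials.
#' @param input weighted input, same shape.
#' @return Updated potentials.
#' @export
accumulate_output <- function(u, input) {
  if (!all(is.finite(input))) stop("output layer: non-finite weighted input")
  u + input
}

#' Linear surrogate derivative of the spike nonlinearity
#'
#' The spike function is a step and has zero derivative almost everywhere; for
#' gradient-based training its derivative is replaced by the linear hat
#' `alpha * max(0, 1 - |u - v|)`, centred on the firing threshold.
#'
#' @param u membrane potential(s) at which to evaluate.
#' @param v firing threshold (scalar, recycled).
#' @param alpha positive scale constant of the hat; the source model leaves it
#'   a free constant, default 0.3.
#' @return Pseudo-derivative values, same shape as `u`.
#' @export
surrogate_grad <- function(u, v, alpha = 0.3) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be a positive scalar")
  alpha * pmax(0, 1 - abs(u - v))
}

#' Poisson rate-coding encoder
#'
#' Encodes real values as spike trains: at every time step a uniform draw on
#' `[0, 1)` is compared with the absolute target value and a spike is emitted
#' when the draw falls below it, so the expected firing rate equals `|value|`.
#' In ternary mode the emitted spike carries the sign of the value, which is
#' how zero-mean-normalized (negative) inputs are represented; binary mode
#' rejects negative values. Inputs outside the declared range are rejected
#' rather than clipped, so normalization bugs surface immediately.
#'
#' @param values numeric array of target values; `[0, 1]` for binary mode,
#'   `[-1, 1]` for ternary mode.
#' @param T number of time steps (>= 1).
#' @param mode `"binary"` or `"ternary"`.
#' @param seed optional integer seed for a reproducible train (restores the
#'   caller's RNG state afterwards).
#' @return A [spike_train] with dimensions `c(T, dim(values))`.
#' @export
poisson_encode <- function(values, T, mode = c("binary", "ternary"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(T) || length(T) != 1L || T < 1) stop("'T' must be >= 1")
  T <- as.integer(T)
  if (!all(is.finite(values))) stop("encoder input must be finite")
  if (mode == "binary") {
    if (any(values < 0)) stop("binary encoder rejects negative values; use ternary mode")
    if (any(values > 1)) stop("encoder input out of range [0, 1]")
  } else {
    if (any(abs(values) > 1)) stop("encoder input out of range [-1, 1]")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  dv <- if (is.null(dim(values))) length(values) else dim(values)
  tgt <- rep(abs(as.numeric(values)), each = T)
  sgn <- if (mode == "ternary") rep(sign(as.numeric(values)), each = T) else 1
  xi <- stats::runif(T * length(values))
  sp <- (xi < tgt) * sgn
  dim(sp) <- c(T, dv)
  spike_train(sp, mode = mode)
}

#' Run a fully-connected spiking layer over a spike train
#'
#' Vectorized driver for a dense layer of IF neurons: the weighted input at
#' every step is `W %*% x_t`, integrated by [if_step]. Membrane potentials are
#' zero-initialized and the whole membrane trace is returned. Results are
#' identical to applying `if_step` neuron-by-neuron, step-by-step.
#'
#' @param W weight matrix, `n_out x n_in`.
#' @param input_train a [spike_train] (or time-major matrix) with `n_in` neurons.
#' @param v positive firing threshold of the layer.
#' @return `list(train, u, u_trace, spike_count)`: the `{0,1}` output train, the
#'   final membrane potentials, the per-step potential trace (`T x n_out`,
#'   after reset), and per-neuron spike counts.
#' @export
run_spiking_layer <- function(W, input_train, v) {
  W <- as.matrix(W)
  X <- unclass(input_train)
  if (length(dim(X)) != 2L) dim(X) <- c(dim(X)[1L], prod(dim(X)[-1L]))
  if (ncol(X) != ncol(W))
    stop("shape mismatch: train has ", ncol(X), " neurons, weights expect ", ncol(W))
  T <- nrow(X)
  Z <- X %*% t(W)
  u <- numeric(nrow(W))
  S <- matrix(0, T, nrow(W))
  U <- matrix(0, T, nrow(W))
  for (t in seq_len(T)) {
    st <- if_step(u, v, Z[t, ])
    u <- st$u
    S[t, ] <- st$spikes
    U[t, ] <- u
  }
  list(train = spike_train(S, mode = "binary"), u = u,
       u_trace = U, spike_count = colSums(S))
}

#' Write / read a spike train debugging dump
#'
#' Compact gzip-compressed integer dump with a small self-describing header
#' (time steps, mode, shape). Intended for debugging, not as an exchange
#' format.
#'
#' @param x a [spike_train].
#' @param path file path.
#' @return `write_spike_train` returns `path` invisibly; `read_spike_train`
#'   returns the reconstructed [spike_train].
#' @export
write_spike_train <- function(x, path) {
  stopifnot(inherits(x, "spike_train"))
  con <- gzfile(path, "wb")
  on.exit(close(con))
  d <- dim(x)
  writeBin(c(length(d), d), con, size = 4L)
  writeBin(if (attr(x, "mode") == "binary") 0L else 1L, con, size = 4L)
  writeBin(as.integer(unclass(x)), con, size = 1L)
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  nd <- readBin(con, "integer", 1L, size = 4L)
  d <- readBin(con, "integer", nd, size = 4L)
  mode <- if (readBin(con, "integer", 1L, size = 4L) == 0L) "binary" else "ternary"
  vals <- readBin(con, "integer", prod(d), size = 1L, signed = TRUE)
  dim(vals) <- d
  spike_train(vals, mode = mode)
}
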