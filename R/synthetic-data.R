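#' Synthetic MRI-like volume generator configuration
#'
#' The generator emulates cropped hippocampus volumes: a bright, smooth,
#' roughly ellipsoidal foreground structure at a jittered but consistent
#' position inside a noisy background, with a low-frequency multiplicative
#' intensity bias field mimicking MR inhomogeneity. The default geometry
#' matches the 24 x 56 x 48 crop of the segmentation protocol; toy 2D runs use
#' single-slice volumes (`shape = c(1, H, W)`).
#'
#' @param n_subjects number of subjects (default 110).
#' @param shape volume dimensions, default `c(24, 56, 48)`.
#' @param contrast intensity difference between foreground and background
#'   (> 0), on a background level of 0.25.
#' @param noise_sd standard deviation of the additive i.i.d. Gaussian noise.
#' @param bias_amp amplitude of the smooth multiplicative bias field.
#' @param fg_scale relative ellipsoid semi-axis (fraction of each dimension);
#'   the default keeps the foreground fraction within roughly 2-8%.
#' @param deform_amp amplitude of the smooth boundary deformation field.
#' @param normalization `"zero_mean"` (to `[-1, 1]`, for ternary encoders) or
#'   `"unit_range"` (to `[0, 1]`, for binary encoders).
#' @param folds number of cross-validation folds (default 5).
#' @param seed RNG seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 110L, shape = c(24L, 56L, 48L),
                         contrast = 0.5, noise_sd = 0.12, bias_amp = 0.1,
                         fg_scale = 0.2, deform_amp = 0.15,
                         normalization = c("zero_mean", "unit_range"),
                         folds = 5L, seed = 1L) {
  normalization <- match.arg(normalization)
  if (contrast <= 0) stop("'contrast' must be > 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (any(shape < 1)) stop("degenerate volume shape")
  structure(list(n_subjects = as.integer(n_subjects), shape = as.integer(shape),
                 contrast = contrast, noise_sd = noise_sd, bias_amp = bias_amp,
                 fg_scale = fg_scale, deform_amp = deform_amp,
                 normalization = normalization, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# smooth random low-frequency field over the voxel grid, values in ~[-1, 1]
smooth_field <- function(shape) {
  ax <- lapply(shape, function(d) {
    if (d == 1L) return(rep(stats::runif(1, -1, 1), d))
    f <- stats::runif(1, 0.5, 1.5)
    ph <- stats::runif(1, 0, 2 * pi)
    sin(2 * pi * f * seq(0, 1, length.out = d) + ph)
  })
  o <- outer(ax[[1]], ax[[2]])
  array(outer(o, ax[[3]]), shape)
}

#' Generate one labeled synthetic volume
#'
#' @param config a [synth_config].
#' @param id subject identifier stored in the result.
#' @return An object of class `labeled_volume`: `list(intensities, mask, id,
#'   normalization)` with equal-shaped 3D arrays, `mask` in `{0,1}`.
#' @export
generate_volume <- function(config = synth_config(), id = "S001") {
  sh <- config$shape
  if (any(sh < 1)) stop("degenerate volume shape")
  ctr <- (sh + 1) / 2 + stats::runif(3, -0.06, 0.06) * (sh - 1)
  semi <- pmax(config$fg_scale * sh * stats::runif(3, 0.9, 1.1), 0.45)
  g <- list(seq_len(sh[1]), seq_len(sh[2]), seq_len(sh[3]))
  q1 <- (g[[1]] - ctr[1]) / semi[1]
  q2 <- (g[[2]] - ctr[2]) / semi[2]
  q3 <- (g[[3]] - ctr[3]) / semi[3]
  r2 <- outer(outer(q1^2, q2^2, `+`), q3^2, `+`)
  deform <- config$deform_amp * smooth_field(sh)
  mask <- (sqrt(r2) <= 1 + deform) * 1
  frac <- mean(mask)
  if (frac <= 0.005 || frac >= 0.20)
    stop(sprintf("foreground fraction %.3f outside the plausible band (0.5%%, 20%%)", frac))
  x <- 0.25 + config$contrast * mask
  if (config$bias_amp > 0) x <- x * (1 + config$bias_amp * smooth_field(sh))
  if (config$noise_sd > 0) x <- x + stats::rnorm(length(x), sd = config$noise_sd)
  dim(x) <- sh
  rng <- range(x)
  x <- (x - rng[1]) / (rng[2] - rng[1])
  if (config$normalization == "zero_mean") x <- 2 * x - 1
  structure(list(intensities = x, mask = mask, id = id,
                 normalization = config$normalization),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume> %s: %s, foreground %.1f%%, %s-normalized\n",
              x$id, paste(dim(x$intensities), collapse = "x"),
              100 * mean(x$mask), x$normalization))
  invisible(x)
}

#' Generate a labeled dataset with subject-level folds
#'
#' Subjects (not slices) are partitioned into `config$folds` disjoint folds so
#' that slices from one subject never straddle a train/test boundary.
#'
#' @param config a [synth_config].
#' @return `list(volumes, folds)`: a list of [generate_volume] results and an
#'   integer fold assignment per subject.
#' @export
generate_dataset <- function(config = synth_config()) {
  if (config$n_subjects < config$folds)
    stop("need at least as many subjects as folds")
  set.seed(config$seed)
  volumes <- lapply(seq_len(config$n_subjects), function(i)
    generate_volume(config, id = sprintf("S%03d", i)))
  folds <- sample(rep(seq_len(config$folds),
                      length.out = config$n_subjects))
  list(volumes = volumes, folds = folds)
}

#' Deterministic 2D slice loader
#'
#' Slices every volume along an axis and yields batches of 2D (image, mask)
#' pairs. Order is deterministic given a seed.
#'
#' @param volumes list of `labeled_volume`s.
#' @param axis slicing axis (1, 2 or 3), default 1.
#' @param batch_size slices per batch.
#' @param shuffle randomize slice order.
#' @param seed seed used when shuffling.
#' @return List of batches: each `list(x, y, subject, slice)` with `x`, `y` of
#'   dim `(H, W, 1, B)`.
#' @export
slice_loader <- function(volumes, axis = 1L, batch_size = 26L, shuffle = FALSE,
                         seed = 1L) {
  if (!length(volumes)) stop("empty dataset")
  sl <- stack_slices(volumes, axis)
  n <- dim(sl$x)[4L]
  ord <- seq_len(n)
  if (shuffle) {
    set.seed(seed)
    ord <- sample.int(n)
  }
  lapply(batch_indices(n, batch_size), function(ix) {
    b <- ord[ix]
    list(x = sl$x[, , , b, drop = FALSE], y = sl$y[, , , b, drop = FALSE],
         subject = sl$subject[b], slice = sl$slice[b])
  })
}

# flatten volumes into (H, W, 1, n_slices) arrays + subject/slice bookkeeping
stack_slices <- function(volumes, axis = 1L) {
  slices_per <- vapply(volumes, function(v) dim(v$intensities)[axis], 1L)
  hw <- dim(volumes[[1]]$intensities)[-axis]
  n <- sum(slices_per)
  x <- array(0, c(hw, 1L, n))
  y <- array(0, c(hw, 1L, n))
  subject <- character(n); slice <- integer(n)
  k <- 0L
  for (v in volumes) {
    d <- dim(v$intensities)
    for (s in seq_len(d[axis])) {
      k <- k + 1L
      idx <- switch(axis,
                    `1` = list(s, TRUE, TRUE),
                    `2` = list(TRUE, s, TRUE),
                    `3` = list(TRUE, TRUE, s))
      x[, , 1L, k] <- do.call(`[`, c(list(v$intensities), idx))
      y[, , 1L, k] <- do.call(`[`, c(list(v$mask), idx))
      subject[k] <- v$id; slice[k] <- s
    }
  }
  list(x = x, y = y, subject = subject, slice = slice)
}

#' Toy multi-class image set in paired normalizations
#'
#' Small oriented-bar images for the binary-vs-ternary encoder comparison:
#' `k` classes of bars at distinct orientations, each image min-max normalized
#' to `[0, 1]` and emitted a second time under the affine map `x -> 2x - 1`
#' (zero-mean variant) from the identical underlying sample. Classes are
#' linearly separable at zero noise.
#'
#' @param n_per_class images per class.
#' @param shape image size, default `c(12, 12)`.
#' @param k number of classes (bar orientations), default 4.
#' @param noise_sd additive Gaussian noise before normalization.
#' @param seed RNG seed.
#' @return `list(x01, xzm, y)`: flattened image matrices (`N x prod(shape)`)
#'   in `[0,1]` and `[-1,1]` normalization, and integer labels in `1..k`.
#' @export
generate_toy_classification <- function(n_per_class = 100L, shape = c(12L, 12L),
                                        k = 4L, noise_sd = 0.2, seed = 1L) {
  set.seed(seed)
  angles <- pi * (seq_len(k) - 1L) / k
  h <- shape[1]; w <- shape[2]
  ctr <- (shape + 1) / 2
  gx <- matrix(rep(seq_len(h) - ctr[1], w), h, w)
  gy <- matrix(rep(seq_len(w) - ctr[2], each = h), h, w)
  N <- n_per_class * k
  X <- matrix(0, N, h * w)
  y <- integer(N)
  for (i in seq_len(N)) {
    cls <- ((i - 1L) %% k) + 1L
    a <- angles[cls] + stats::rnorm(1, sd = 0.05)
    dist <- abs(-sin(a) * gx + cos(a) * gy)
    img <- (dist < 1.2) * 1
    if (noise_sd > 0) img <- img + stats::rnorm(length(img), sd = noise_sd)
    rng <- range(img)
    X[i, ] <- (img - rng[1]) / (rng[2] - rng[1])
    y[i] <- cls
  }
  list(x01 = X, xzm = 2 * X - 1, y = y)
}

#' Write / read a labeled volume as NIfTI
#'
#' Intensities and mask are written as a `.nii.gz` pair (`<stem>.nii.gz`,
#' `<stem>_mask.nii.gz`) with identity orientation and 1 mm isotropic spacing;
#' the mask is stored as unsigned 8-bit.
#'
#' @param volume a `labeled_volume`.
#' @param stem path stem (without extension).
#' @return `write_labeled_volume` returns the two paths invisibly;
#'   `read_labeled_volume` returns the reconstructed `labeled_volume`.
#' @export
write_labeled_volume <- function(volume, stem) {
  pi_ <- paste0(stem, ".nii.gz")
  pm <- paste0(stem, "_mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(volume$intensities, pixdim = c(1, 1, 1)), pi_)
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(volume$mask),
                                           dim(volume$mask)),
                                     pixdim = c(1, 1, 1), datatype = "uint8"), pm)
  invisible(c(pi_, pm))
}

#' @rdname write_labeled_volume
#' @param id,normalization metadata restored onto the read volume.
#' @export
read_labeled_volume <- function(stem, id = basename(stem),
                                normalization = "unknown") {
  x <- as.array(RNifti::readNifti(paste0(stem, ".nii.gz")))
  m <- as.array(RNifti::readNifti(paste0(stem, "_mask.nii.gz")))
  structure(list(intensities = x, mask = (m > 0) * 1, id = id,
                 normalization = normalization),
            class = "labeled_volume")
}
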