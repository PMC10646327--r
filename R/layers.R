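# Thin R wrappers over the compiled layer kernels. All feature maps are
# numeric arrays dim (H, W, C, N); weights are (kh, kw, Cin, Cout); no layer
# carries a bias term (a conversion constraint, see network_spec()).

conv2d <- function(x, w, pad = (dim(w)[1L] - 1L) %/% 2L) {
  .conv2d_fwd(x, w, as.integer(pad))
}

conv2d_bwd <- function(x, w, dy, pad = (dim(w)[1L] - 1L) %/% 2L) {
  .conv2d_bwd(x, w, dy, as.integer(pad))
}

avgpool2 <- function(x) .avgpool2_fwd(x)
avgpool2_bwd <- function(dy) .avgpool2_bwd(dy)

upconv2 <- function(x, w) .upconv2_fwd(x, w)
upconv2_bwd <- function(x, w, dy) .upconv2_bwd(x, w, dy)

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# concatenate / split (H, W, C, N) maps along the channel axis
channel_cat <- function(a, b) .channel_cat(a, b)
channel_split <- function(x, c1) .channel_split(x, as.integer(c1))
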