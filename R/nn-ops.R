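# Layer primitives. Tensors are numeric arrays of dim (H, W, C, N);
# convolution weights are (kh, kw, Cin, Cout). Each *_fwd returns
# list(out, cache); each *_bwd consumes the cache and the upstream gradient.
# Transposed convolutions reuse the convolution kernels with input/output
# roles exchanged, so the two stay consistent by construction.

conv_fwd <- function(x, W, b, stride = 1L, pad = 0L) {
  out <- cpp_conv_fwd(x, W, b, as.integer(stride), as.integer(pad))
  list(out = out, cache = list(x = x, W = W, stride = stride, pad = pad))
}

conv_bwd <- function(cache, gy, want_gx = TRUE) {
  cpp_conv_bwd(cache$x, cache$W, gy, as.integer(cache$stride),
               as.integer(cache$pad), want_gx)
}

# Transposed convolution: weight dim (kh, kw, Cout, Cin), i.e. stored as the
# weight of the dual (downsampling) convolution. Output spatial size is
# (n - 1) * stride + k - 2 * pad.
tconv_fwd <- function(x, W, b, stride = 2L, pad = 1L) {
  d <- dim(x); wd <- dim(W)
  Ho <- (d[1] - 1L) * stride + wd[1] - 2L * pad
  Wo <- (d[2] - 1L) * stride + wd[2] - 2L * pad
  out <- cpp_conv_bwd_data(x, W, as.integer(stride), as.integer(pad),
                           as.integer(Ho), as.integer(Wo))
  out <- cpp_add_bias(out, b)
  list(out = out, cache = list(x = x, W = W, stride = stride, pad = pad,
                               kh = wd[1], kw = wd[2]))
}

tconv_bwd <- function(cache, gy, want_gx = TRUE) {
  # forward was out = conv_bwd_data(x); so d out/d x = conv_fwd and the
  # weight gradient is im2col(out_grad) %*% x.
  gw <- cpp_conv_gw(gy, cache$x, as.integer(cache$kh), as.integer(cache$kw),
                    as.integer(cache$stride), as.integer(cache$pad))
  gb <- channel_sums(gy)
  if (!want_gx) return(list(gw = gw, gb = gb))
  zero_b <- numeric(dim(cache$x)[3])
  gx <- cpp_conv_fwd(gy, cache$W, zero_b, as.integer(cache$stride),
                     as.integer(cache$pad))
  list(gx = gx, gw = gw, gb = gb)
}

channel_sums <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  rowSums(matrix(colSums(m), d[3], d[4]))
}

# Instance normalisation with affine parameters: per image and channel,
# features are standardised over the spatial plane.
instnorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  r <- cpp_instnorm_fwd(x, gamma, beta, eps)
  list(out = r$out, cache = list(xhat = r$xhat, invstd = r$invstd,
                                 gamma = gamma))
}

instnorm_bwd <- function(cache, gy) {
  cpp_instnorm_bwd(cache$xhat, cache$invstd, cache$gamma, gy)
}

lrelu_fwd <- function(x, slope = 0.2) {
  list(out = cpp_lrelu_fwd(x, slope), cache = list(x = x, slope = slope))
}

lrelu_bwd <- function(cache, gy) {
  cpp_lrelu_bwd(cache$x, gy, cache$slope)
}

linear_fwd <- function(x, W, b) {
  # x: (N, in); W: (in, out)
  y <- x %*% W
  y <- sweep(y, 2, b, "+")
  list(out = y, cache = list(x = x, W = W))
}

linear_bwd <- function(cache, gy, want_gx = TRUE) {
  gw <- crossprod(cache$x, gy)
  gb <- colSums(gy)
  gx <- if (want_gx) tcrossprod(gy, cache$W) else NULL
  list(gx = gx, gw = gw, gb = gb)
}

maxpool_fwd <- function(x, k = 3L, stride = 2L, pad = 1L) {
  r <- cpp_maxpool_fwd(x, as.integer(k), as.integer(stride), as.integer(pad))
  list(out = r$out, cache = list(idx = r$idx, H = dim(x)[1], W = dim(x)[2]))
}

maxpool_bwd <- function(cache, gy) {
  cpp_maxpool_bwd(cache$idx, gy, as.integer(cache$H), as.integer(cache$W))
}

# Channel-wise softmax over dim 3 of an (H, W, K, N) logit array.
softmax_channels <- function(x) cpp_softmax_channels(x)

# ---- parameter initialisation and Adam ----

init_conv_w <- function(kh, kw, cin, cout, sd = 0.02) {
  array(rnorm(kh * kw * cin * cout, 0, sd), c(kh, kw, cin, cout))
}

init_linear_w <- function(cin, cout, sd = 0.02) {
  matrix(rnorm(cin * cout, 0, sd), cin, cout)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# Elementwise sum of two named gradient lists (missing entries allowed).
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

zero_grads <- function(params) lapply(params, function(p) p * 0)
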