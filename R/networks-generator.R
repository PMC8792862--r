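#' Generator specification
#'
#' Describes the noise-to-image generator. The generator projects a standard
#' normal noise vector to a `base_resolution` x `base_resolution` feature map
#' and then applies one generator block per schedule entry. Each block is a
#' pointwise (1x1) convolution that reduces channel width, followed by two
#' 4x4 fractionally strided (transposed) convolutions of stride 2, so every
#' block multiplies the spatial resolution by 4. Instance normalisation and
#' LeakyReLU follow every layer; the output head is a 3x3 convolution to one
#' channel with a tanh squashed to the unit interval.
#'
#' With `pointwise_reduction = FALSE` the 1x1 layers are omitted and the
#' transposed convolutions carry the full channel width of the incoming
#' feature map (the ablated, parameter-heavy baseline).
#'
#' @param output_resolution side length of the generated image; must equal
#'   `base_resolution * 4^B` where `B = length(channel_schedule) - 1`.
#' @param channel_schedule integer vector `(c0, c1, ..., cB)`: channels of
#'   the initial projected map and after each of the `B` generator blocks.
#' @param pointwise_schedule channel widths after each block's 1x1 reduction;
#'   defaults to the shipped reduced widths for the full-scale model and to
#'   `ceiling(c_{b-1}/4)` otherwise.
#' @param noise_dim length of the input noise vector.
#' @param base_resolution spatial size of the first feature map.
#' @param pointwise_reduction logical; include the 1x1 reduction layers.
#' @return an object of class `usgan_generator_spec`.
#' @export
generator_spec <- function(output_resolution = 1024L,
                           channel_schedule = NULL,
                           pointwise_schedule = NULL,
                           noise_dim = 100L,
                           base_resolution = 4L,
                           pointwise_reduction = TRUE) {
  if (is.null(channel_schedule)) {
    channel_schedule <- if (output_resolution >= 1024L) {
      c(2032L, 1008L, 504L, 252L, 126L)
    } else if (output_resolution == 256L) {
      c(256L, 128L, 64L, 32L)[1:4]
    } else {
      c(64L, 32L, 16L)
    }
  }
  B <- length(channel_schedule) - 1L
  if (B < 1L)
    stop_validation("channel_schedule needs at least two entries (c0 and one block)")
  expected <- base_resolution * 4L^B
  if (output_resolution != expected)
    stop_validation(
      "output_resolution %d inconsistent with %d generator blocks (expected %d = %d * 4^%d)",
      output_resolution, B, expected, base_resolution, B)
  if (is.null(pointwise_schedule)) {
    pointwise_schedule <- if (identical(as.integer(channel_schedule),
                                        c(2032L, 1008L, 504L, 252L, 126L))) {
      c(328L, 164L, 82L, 41L)
    } else {
      as.integer(ceiling(channel_schedule[seq_len(B)] / 4))
    }
  }
  if (length(pointwise_schedule) != B)
    stop_validation("pointwise_schedule must have one entry per block (%d), got %d",
                    B, length(pointwise_schedule))
  structure(list(noise_dim = as.integer(noise_dim),
                 base_resolution = as.integer(base_resolution),
                 output_resolution = as.integer(output_resolution),
                 channel_schedule = as.integer(channel_schedule),
                 pointwise_schedule = as.integer(pointwise_schedule),
                 pointwise_reduction = isTRUE(pointwise_reduction)),
            class = "usgan_generator_spec")
}

#' Build a generator
#'
#' Instantiates the generator described by a [generator_spec()] with fresh
#' weights (convolutions N(0, 0.02), instance-norm gain 1 / bias 0), drawn
#' from the current RNG state.
#'
#' @param spec a `usgan_generator_spec`.
#' @return an object of class `usgan_generator` holding the spec, a flat
#'   named parameter list, and analytic layer descriptors used for FLOP
#'   accounting. Apply it to noise with [generate_images()].
#' @export
build_generator <- function(spec) {
  stopifnot(inherits(spec, "usgan_generator_spec"))
  cs <- spec$channel_schedule
  B <- length(cs) - 1L
  p <- list()
  arch <- list()
  res <- spec$base_resolution
  c0 <- cs[1]
  p[["proj.W"]] <- init_linear_w(spec$noise_dim, res * res * c0)
  p[["proj.b"]] <- numeric(res * res * c0)
  p[["proj_in.g"]] <- rep(1, c0); p[["proj_in.b"]] <- numeric(c0)
  arch[[length(arch) + 1L]] <- list(kind = "linear", cin = spec$noise_dim,
                                    cout = res * res * c0)
  cin <- c0
  for (b in seq_len(B)) {
    cb <- cs[b + 1L]
    if (spec$pointwise_reduction) {
      m <- spec$pointwise_schedule[b]
      p[[sprintf("blk%d.pw.W", b)]] <- init_conv_w(1, 1, cin, m)
      p[[sprintf("blk%d.pw.b", b)]] <- numeric(m)
      p[[sprintf("blk%d.pw_in.g", b)]] <- rep(1, m)
      p[[sprintf("blk%d.pw_in.b", b)]] <- numeric(m)
      arch[[length(arch) + 1L]] <- list(kind = "conv", k = 1L, cin = cin,
                                        cout = m, res = res)
    } else {
      m <- cin
    }
    # transposed conv weights stored as (kh, kw, cout, cin)
    p[[sprintf("blk%d.up1.W", b)]] <- init_conv_w(4, 4, m, m)
    p[[sprintf("blk%d.up1.b", b)]] <- numeric(m)
    p[[sprintf("blk%d.up1_in.g", b)]] <- rep(1, m)
    p[[sprintf("blk%d.up1_in.b", b)]] <- numeric(m)
    res <- res * 2L
    arch[[length(arch) + 1L]] <- list(kind = "conv", k = 4L, cin = m,
                                      cout = m, res = res)
    p[[sprintf("blk%d.up2.W", b)]] <- init_conv_w(4, 4, cb, m)
    p[[sprintf("blk%d.up2.b", b)]] <- numeric(cb)
    p[[sprintf("blk%d.up2_in.g", b)]] <- rep(1, cb)
    p[[sprintf("blk%d.up2_in.b", b)]] <- numeric(cb)
    res <- res * 2L
    arch[[length(arch) + 1L]] <- list(kind = "conv", k = 4L, cin = m,
                                      cout = cb, res = res)
    cin <- cb
  }
  p[["out.W"]] <- init_conv_w(3, 3, cin, 1)
  p[["out.b"]] <- numeric(1)
  arch[[length(arch) + 1L]] <- list(kind = "conv", k = 3L, cin = cin,
                                    cout = 1L, res = res)
  structure(list(spec = spec, params = p, arch = arch),
            class = "usgan_generator")
}

#' Sample noise vectors
#'
#' @param n number of vectors.
#' @param noise_dim dimension of each standard normal noise vector.
#' @return an `n x noise_dim` matrix.
#' @export
sample_noise <- function(n, noise_dim = 100L) {
  matrix(rnorm(n * noise_dim), n, noise_dim)
}

generator_forward <- function(gen, z, train = FALSE) {
  sp <- gen$spec; p <- gen$params
  cs <- sp$channel_schedule
  B <- length(cs) - 1L
  n <- nrow(z)
  cache <- list()

  lin <- linear_fwd(z, p[["proj.W"]], p[["proj.b"]])
  h <- array(t(lin$out), c(sp$base_resolution, sp$base_resolution, cs[1], n))
  inn <- instnorm_fwd(h, p[["proj_in.g"]], p[["proj_in.b"]])
  act <- lrelu_fwd(inn$out)
  h <- act$out
  cache$proj <- list(lin = lin$cache, inn = inn$cache, act = act$cache)

  cache$blocks <- vector("list", B)
  for (b in seq_len(B)) {
    bc <- list()
    if (sp$pointwise_reduction) {
      cv <- conv_fwd(h, p[[sprintf("blk%d.pw.W", b)]],
                     p[[sprintf("blk%d.pw.b", b)]], 1L, 0L)
      inn <- instnorm_fwd(cv$out, p[[sprintf("blk%d.pw_in.g", b)]],
                          p[[sprintf("blk%d.pw_in.b", b)]])
      act <- lrelu_fwd(inn$out)
      h <- act$out
      bc$pw <- list(cv = cv$cache, inn = inn$cache, act = act$cache)
    }
    up <- tconv_fwd(h, p[[sprintf("blk%d.up1.W", b)]],
                    p[[sprintf("blk%d.up1.b", b)]])
    inn <- instnorm_fwd(up$out, p[[sprintf("blk%d.up1_in.g", b)]],
                        p[[sprintf("blk%d.up1_in.b", b)]])
    act <- lrelu_fwd(inn$out)
    h <- act$out
    bc$up1 <- list(up = up$cache, inn = inn$cache, act = act$cache)
    up <- tconv_fwd(h, p[[sprintf("blk%d.up2.W", b)]],
                    p[[sprintf("blk%d.up2.b", b)]])
    inn <- instnorm_fwd(up$out, p[[sprintf("blk%d.up2_in.g", b)]],
                        p[[sprintf("blk%d.up2_in.b", b)]])
    act <- lrelu_fwd(inn$out)
    h <- act$out
    bc$up2 <- list(up = up$cache, inn = inn$cache, act = act$cache)
    cache$blocks[[b]] <- bc
  }
  cv <- conv_fwd(h, p[["out.W"]], p[["out.b"]], 1L, 1L)
  th <- tanh(cv$out)
  out <- (th + 1) / 2
  cache$out <- list(cv = cv$cache, th = th)
  list(out = out, cache = if (train) cache else NULL)
}

generator_backward <- function(gen, cache, gout) {
  sp <- gen$spec
  B <- length(sp$channel_schedule) - 1L
  g <- list()
  # out = (tanh(u) + 1) / 2
  gu <- gout * 0.5 * (1 - cache$out$th^2)
  cb <- conv_bwd(cache$out$cv, gu, want_gx = TRUE)
  g[["out.W"]] <- cb$gw; g[["out.b"]] <- cb$gb
  gh <- cb$gx
  for (b in rev(seq_len(B))) {
    bc <- cache$blocks[[b]]
    gh <- lrelu_bwd(bc$up2$act, gh)
    ib <- instnorm_bwd(bc$up2$inn, gh)
    g[[sprintf("blk%d.up2_in.g", b)]] <- ib$gg
    g[[sprintf("blk%d.up2_in.b", b)]] <- ib$gb
    tb <- tconv_bwd(bc$up2$up, ib$gx)
    g[[sprintf("blk%d.up2.W", b)]] <- tb$gw
    g[[sprintf("blk%d.up2.b", b)]] <- tb$gb
    gh <- tb$gx
    gh <- lrelu_bwd(bc$up1$act, gh)
    ib <- instnorm_bwd(bc$up1$inn, gh)
    g[[sprintf("blk%d.up1_in.g", b)]] <- ib$gg
    g[[sprintf("blk%d.up1_in.b", b)]] <- ib$gb
    tb <- tconv_bwd(bc$up1$up, ib$gx)
    g[[sprintf("blk%d.up1.W", b)]] <- tb$gw
    g[[sprintf("blk%d.up1.b", b)]] <- tb$gb
    gh <- tb$gx
    if (sp$pointwise_reduction) {
      gh <- lrelu_bwd(bc$pw$act, gh)
      ib <- instnorm_bwd(bc$pw$inn, gh)
      g[[sprintf("blk%d.pw_in.g", b)]] <- ib$gg
      g[[sprintf("blk%d.pw_in.b", b)]] <- ib$gb
      cbk <- conv_bwd(bc$pw$cv, ib$gx, want_gx = TRUE)
      g[[sprintf("blk%d.pw.W", b)]] <- cbk$gw
      g[[sprintf("blk%d.pw.b", b)]] <- cbk$gb
      gh <- cbk$gx
    }
  }
  gh <- lrelu_bwd(cache$proj$act, gh)
  ib <- instnorm_bwd(cache$proj$inn, gh)
  g[["proj_in.g"]] <- ib$gg; g[["proj_in.b"]] <- ib$gb
  d <- dim(ib$gx)
  gflat <- t(matrix(ib$gx, d[1] * d[2] * d[3], d[4]))
  lb <- linear_bwd(cache$proj$lin, gflat, want_gx = FALSE)
  g[["proj.W"]] <- lb$gw; g[["proj.b"]] <- lb$gb
  g
}

#' Generate images from noise
#'
#' Maps standard normal noise vectors through a built generator to
#' single-channel images with intensities in the unit interval.
#'
#' @param gen a `usgan_generator` from [build_generator()].
#' @param z an `n x noise_dim` matrix (see [sample_noise()]).
#' @return numeric array of dim `(res, res, 1, n)`, values in `[0, 1]`.
#' @export
generate_images <- function(gen, z) {
  stopifnot(inherits(gen, "usgan_generator"))
  if (ncol(z) != gen$spec$noise_dim)
    stop_validation("noise has dim %d, generator expects %d",
                    ncol(z), gen$spec$noise_dim)
  generator_forward(gen, z, train = FALSE)$out
}
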