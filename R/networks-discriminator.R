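#' Discriminator specification
#'
#' Describes the U-shaped discriminator: an encoder (a ResNet-50-style stack
#' of bottleneck blocks, or a light 4-stage CNN for desk-scale work), a
#' four-block decoder, and skip connections concatenating encoder features
#' into the decoder stage of matching resolution. Each decoder block is a
#' 3x3 convolution, a pointwise (1x1) connector that halves the channel
#' width, and a 4x4 fractionally strided convolution of stride 2; instance
#' normalisation and LeakyReLU follow every layer. The head is a pointwise
#' convolution to `n_classes` per-pixel logits; a channel softmax turns them
#' into a per-pixel probability map over (lung, background, fake).
#'
#' @param encoder `"small-cnn"` (four stride-2 stages, total stride 16) or
#'   `"resnet50"` (randomly initialised ResNet-50 stage layout, total stride
#'   32; pass `weights` to load saved parameters).
#' @param input_resolution side length of input images; must be divisible by
#'   the encoder's total stride.
#' @param encoder_channels stage widths of the small-cnn encoder.
#' @param decoder_channel_schedule output channels of the four decoder
#'   blocks.
#' @param n_classes number of per-pixel classes (3: lung, background, fake;
#'   the image-level ablation uses 2).
#' @param skip_connections logical; concatenate encoder features into the
#'   decoder.
#' @param cls_head logical; add an image-level real/fake head (global mean
#'   pool over the bottleneck plus a linear layer) used by the original,
#'   image-level adversarial training mode.
#' @return an object of class `usgan_discriminator_spec`.
#' @export
discriminator_spec <- function(encoder = c("small-cnn", "resnet50"),
                               input_resolution = 64L,
                               encoder_channels = c(4L, 8L, 16L, 32L),
                               decoder_channel_schedule = NULL,
                               n_classes = 3L,
                               skip_connections = TRUE,
                               cls_head = FALSE) {
  encoder <- match.arg(encoder)
  stride_total <- if (encoder == "small-cnn") 16L else 32L
  if (input_resolution %% stride_total != 0L)
    stop_validation("input_resolution %d not divisible by encoder stride %d",
                    input_resolution, stride_total)
  if (is.null(decoder_channel_schedule)) {
    decoder_channel_schedule <- if (encoder == "small-cnn") c(16L, 8L, 4L, 4L)
      else c(256L, 128L, 64L, 32L)
  }
  if (length(decoder_channel_schedule) != 4L)
    stop_validation("decoder_channel_schedule must have 4 entries")
  structure(list(encoder = encoder,
                 input_resolution = as.integer(input_resolution),
                 encoder_channels = as.integer(encoder_channels),
                 decoder_channel_schedule = as.integer(decoder_channel_schedule),
                 n_classes = as.integer(n_classes),
                 skip_connections = isTRUE(skip_connections),
                 cls_head = isTRUE(cls_head)),
            class = "usgan_discriminator_spec")
}

resnet50_stages <- function() {
  # (number of bottlenecks, inner width, output channels, stride of stage)
  list(list(n = 3L, w = 64L,  cout = 256L,  stride = 1L),
       list(n = 4L, w = 128L, cout = 512L,  stride = 2L),
       list(n = 6L, w = 256L, cout = 1024L, stride = 2L),
       list(n = 3L, w = 512L, cout = 2048L, stride = 2L))
}

#' Build a discriminator
#'
#' Instantiates the U-shaped discriminator described by a
#' [discriminator_spec()] with freshly drawn weights.
#'
#' @param spec a `usgan_discriminator_spec`.
#' @param weights optional path to an RDS checkpoint whose parameters
#'   (matching shapes) replace the random initialisation.
#' @return an object of class `usgan_discriminator`. Apply it with
#'   [predict_probs()] or [predict_mask()].
#' @export
build_discriminator <- function(spec, weights = NULL) {
  stopifnot(inherits(spec, "usgan_discriminator_spec"))
  p <- list()
  arch <- list()
  res <- 1  # spatial size as fraction of the input resolution
  add_arch <- function(k, cin, cout, res) {
    arch[[length(arch) + 1L]] <<- list(kind = "conv", k = k, cin = cin,
                                       cout = cout, res = res)
  }

  skip_ch <- integer(4)  # channels available for skips at /8, /4, /2, (/2 head)
  if (spec$encoder == "small-cnn") {
    cin <- 3L
    for (s in seq_len(4L)) {
      co <- spec$encoder_channels[s]
      p[[sprintf("enc.s%d.conv.W", s)]] <- init_conv_w(3, 3, cin, co)
      p[[sprintf("enc.s%d.conv.b", s)]] <- numeric(co)
      p[[sprintf("enc.s%d.in.g", s)]] <- rep(1, co)
      p[[sprintf("enc.s%d.in.b", s)]] <- numeric(co)
      res <- res / 2
      add_arch(3L, cin, co, res)
      cin <- co
    }
    bottleneck_ch <- cin
    skips <- spec$encoder_channels[c(3L, 2L, 1L)]  # at /8, /4, /2
    head_skip <- 0L
  } else {
    p[["enc.conv1.W"]] <- init_conv_w(7, 7, 3, 64)
    p[["enc.conv1.b"]] <- numeric(64)
    p[["enc.conv1_in.g"]] <- rep(1, 64); p[["enc.conv1_in.b"]] <- numeric(64)
    res <- res / 2
    add_arch(7L, 3L, 64L, res)
    res <- res / 2  # maxpool
    cin <- 64L
    st <- resnet50_stages()
    for (s in seq_along(st)) {
      sg <- st[[s]]
      if (s > 1L) res <- res / 2
      for (i in seq_len(sg$n)) {
        pre <- sprintf("enc.st%d.b%d", s, i)
        stride_i <- if (i == 1L) sg$stride else 1L
        p[[paste0(pre, ".c1.W")]] <- init_conv_w(1, 1, cin, sg$w)
        p[[paste0(pre, ".c1.b")]] <- numeric(sg$w)
        p[[paste0(pre, ".in1.g")]] <- rep(1, sg$w)
        p[[paste0(pre, ".in1.b")]] <- numeric(sg$w)
        p[[paste0(pre, ".c2.W")]] <- init_conv_w(3, 3, sg$w, sg$w)
        p[[paste0(pre, ".c2.b")]] <- numeric(sg$w)
        p[[paste0(pre, ".in2.g")]] <- rep(1, sg$w)
        p[[paste0(pre, ".in2.b")]] <- numeric(sg$w)
        p[[paste0(pre, ".c3.W")]] <- init_conv_w(1, 1, sg$w, sg$cout)
        p[[paste0(pre, ".c3.b")]] <- numeric(sg$cout)
        p[[paste0(pre, ".in3.g")]] <- rep(1, sg$cout)
        p[[paste0(pre, ".in3.b")]] <- numeric(sg$cout)
        add_arch(1L, cin, sg$w, res)
        add_arch(3L, sg$w, sg$w, res)
        add_arch(1L, sg$w, sg$cout, res)
        if (i == 1L) {
          p[[paste0(pre, ".sc.W")]] <- init_conv_w(1, 1, cin, sg$cout)
          p[[paste0(pre, ".sc.b")]] <- numeric(sg$cout)
          p[[paste0(pre, ".sc_in.g")]] <- rep(1, sg$cout)
          p[[paste0(pre, ".sc_in.b")]] <- numeric(sg$cout)
          add_arch(1L, cin, sg$cout, res)
        }
        cin <- sg$cout
      }
    }
    bottleneck_ch <- cin  # 2048 at /32
    skips <- c(1024L, 512L, 256L)  # at /16, /8, /4
    head_skip <- 64L               # conv1 features at /2
  }

  dc <- spec$decoder_channel_schedule
  cin <- bottleneck_ch
  for (b in seq_len(4L)) {
    if (b > 1L && spec$skip_connections) cin <- cin + skips[b - 1L]
    db <- dc[b]
    m <- max(2L, db %/% 2L)
    pre <- sprintf("dec.b%d", b)
    p[[paste0(pre, ".conv.W")]] <- init_conv_w(3, 3, cin, db)
    p[[paste0(pre, ".conv.b")]] <- numeric(db)
    p[[paste0(pre, ".in1.g")]] <- rep(1, db); p[[paste0(pre, ".in1.b")]] <- numeric(db)
    p[[paste0(pre, ".pw.W")]] <- init_conv_w(1, 1, db, m)
    p[[paste0(pre, ".pw.b")]] <- numeric(m)
    p[[paste0(pre, ".in2.g")]] <- rep(1, m); p[[paste0(pre, ".in2.b")]] <- numeric(m)
    p[[paste0(pre, ".up.W")]] <- init_conv_w(4, 4, db, m)  # tconv: (k,k,cout,cin)
    p[[paste0(pre, ".up.b")]] <- numeric(db)
    p[[paste0(pre, ".in3.g")]] <- rep(1, db); p[[paste0(pre, ".in3.b")]] <- numeric(db)
    add_arch(3L, cin, db, res)
    add_arch(1L, db, m, res)
    res <- res * 2
    add_arch(4L, m, db, res)
    cin <- db
  }
  if (spec$encoder == "resnet50") {
    # one more x2 stage to undo the stride-32 encoder (plus conv1 skip)
    if (spec$skip_connections) cin <- cin + head_skip
    m <- max(2L, dc[4] %/% 2L)
    p[["dec.h.pw.W"]] <- init_conv_w(1, 1, cin, m)
    p[["dec.h.pw.b"]] <- numeric(m)
    p[["dec.h.in1.g"]] <- rep(1, m); p[["dec.h.in1.b"]] <- numeric(m)
    p[["dec.h.up.W"]] <- init_conv_w(4, 4, dc[4], m)
    p[["dec.h.up.b"]] <- numeric(dc[4])
    p[["dec.h.in2.g"]] <- rep(1, dc[4]); p[["dec.h.in2.b"]] <- numeric(dc[4])
    add_arch(1L, cin, m, res)
    res <- res * 2
    add_arch(4L, m, dc[4], res)
    cin <- dc[4]
  }
  p[["head.W"]] <- init_conv_w(1, 1, cin, spec$n_classes)
  p[["head.b"]] <- numeric(spec$n_classes)
  add_arch(1L, cin, spec$n_classes, res)
  if (spec$cls_head) {
    p[["cls.W"]] <- init_linear_w(bottleneck_ch, 1L)
    p[["cls.b"]] <- numeric(1)
    arch[[length(arch) + 1L]] <- list(kind = "linear", cin = bottleneck_ch,
                                      cout = 1L)
  }
  disc <- structure(list(spec = spec, params = p, arch = arch,
                         skips = if (spec$encoder == "small-cnn") skips
                                 else c(skips, head_skip)),
                    class = "usgan_discriminator")
  if (!is.null(weights)) {
    w <- readRDS(weights)
    pw <- if (!is.null(w$params)) w$params else w
    for (nm in names(disc$params)) {
      if (is.null(pw[[nm]]))
        stop_validation("weights file lacks parameter '%s'", nm)
      if (!identical(dim(pw[[nm]]), dim(disc$params[[nm]])) ||
          length(pw[[nm]]) != length(disc$params[[nm]]))
        stop_validation("weights for '%s' have wrong shape", nm)
      disc$params[[nm]] <- pw[[nm]]
    }
  }
  disc
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_ch <- function(g, c1) {
  d <- dim(g)
  list(a = g[, , seq_len(c1), , drop = FALSE],
       b = g[, , (c1 + 1):d[3], , drop = FALSE])
}

# conv -> instance norm -> LeakyReLU unit
cin_fwd <- function(p, pre, x, stride, pad, conv_nm = "conv", in_nm = "in") {
  cv <- conv_fwd(x, p[[sprintf("%s.%s.W", pre, conv_nm)]],
                 p[[sprintf("%s.%s.b", pre, conv_nm)]], stride, pad)
  inn <- instnorm_fwd(cv$out, p[[sprintf("%s.%s.g", pre, in_nm)]],
                      p[[sprintf("%s.%s.b", pre, in_nm)]])
  act <- lrelu_fwd(inn$out)
  list(out = act$out, cache = list(cv = cv$cache, inn = inn$cache,
                                   act = act$cache, pre = pre,
                                   conv_nm = conv_nm, in_nm = in_nm))
}

cin_bwd <- function(cache, gy, g, want_gx = TRUE) {
  gy <- lrelu_bwd(cache$act, gy)
  ib <- instnorm_bwd(cache$inn, gy)
  g[[sprintf("%s.%s.g", cache$pre, cache$in_nm)]] <- ib$gg
  g[[sprintf("%s.%s.b", cache$pre, cache$in_nm)]] <- ib$gb
  cb <- conv_bwd(cache$cv, ib$gx, want_gx = want_gx)
  g[[sprintf("%s.%s.W", cache$pre, cache$conv_nm)]] <- cb$gw
  g[[sprintf("%s.%s.b", cache$pre, cache$conv_nm)]] <- cb$gb
  list(gx = if (want_gx) cb$gx else NULL, g = g)
}

encoder_forward_smallcnn <- function(p, x) {
  feats <- vector("list", 4L)
  caches <- vector("list", 4L)
  h <- x
  for (s in seq_len(4L)) {
    u <- cin_fwd(p, sprintf("enc.s%d", s), h, 2L, 1L)
    h <- u$out
    feats[[s]] <- h
    caches[[s]] <- u$cache
  }
  list(feats = feats, caches = caches)
}

encoder_backward_smallcnn <- function(caches, feat_grads, g, want_gx = FALSE) {
  gh <- NULL
  for (s in rev(seq_len(4L))) {
    gh <- add_arrays(gh, feat_grads[[s]])
    r <- cin_bwd(caches[[s]], gh, g, want_gx = s > 1L || want_gx)
    g <- r$g
    gh <- r$gx
  }
  list(g = g, gx = gh)
}

add_arrays <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  a + b
}

bottleneck_fwd <- function(p, pre, x, stride, project) {
  c1 <- conv_fwd(x, p[[paste0(pre, ".c1.W")]], p[[paste0(pre, ".c1.b")]], 1L, 0L)
  i1 <- instnorm_fwd(c1$out, p[[paste0(pre, ".in1.g")]], p[[paste0(pre, ".in1.b")]])
  a1 <- lrelu_fwd(i1$out)
  c2 <- conv_fwd(a1$out, p[[paste0(pre, ".c2.W")]], p[[paste0(pre, ".c2.b")]],
                 stride, 1L)
  i2 <- instnorm_fwd(c2$out, p[[paste0(pre, ".in2.g")]], p[[paste0(pre, ".in2.b")]])
  a2 <- lrelu_fwd(i2$out)
  c3 <- conv_fwd(a2$out, p[[paste0(pre, ".c3.W")]], p[[paste0(pre, ".c3.b")]], 1L, 0L)
  i3 <- instnorm_fwd(c3$out, p[[paste0(pre, ".in3.g")]], p[[paste0(pre, ".in3.b")]])
  if (project) {
    sc <- conv_fwd(x, p[[paste0(pre, ".sc.W")]], p[[paste0(pre, ".sc.b")]],
                   stride, 0L)
    si <- instnorm_fwd(sc$out, p[[paste0(pre, ".sc_in.g")]],
                       p[[paste0(pre, ".sc_in.b")]])
    short <- si$out
    sc_cache <- list(cv = sc$cache, inn = si$cache)
  } else {
    short <- x
    sc_cache <- NULL
  }
  s <- i3$out + short
  act <- lrelu_fwd(s)
  list(out = act$out,
       cache = list(pre = pre, c1 = c1$cache, i1 = i1$cache, a1 = a1$cache,
                    c2 = c2$cache, i2 = i2$cache, a2 = a2$cache,
                    c3 = c3$cache, i3 = i3$cache, sc = sc_cache,
                    act = act$cache, project = project))
}

bottleneck_bwd <- function(cache, gy, g, want_gx = TRUE) {
  pre <- cache$pre
  gs <- lrelu_bwd(cache$act, gy)
  # main branch
  ib <- instnorm_bwd(cache$i3, gs)
  g[[paste0(pre, ".in3.g")]] <- ib$gg; g[[paste0(pre, ".in3.b")]] <- ib$gb
  cb <- conv_bwd(cache$c3, ib$gx)
  g[[paste0(pre, ".c3.W")]] <- cb$gw; g[[paste0(pre, ".c3.b")]] <- cb$gb
  gh <- lrelu_bwd(cache$a2, cb$gx)
  ib <- instnorm_bwd(cache$i2, gh)
  g[[paste0(pre, ".in2.g")]] <- ib$gg; g[[paste0(pre, ".in2.b")]] <- ib$gb
  cb <- conv_bwd(cache$c2, ib$gx)
  g[[paste0(pre, ".c2.W")]] <- cb$gw; g[[paste0(pre, ".c2.b")]] <- cb$gb
  gh <- lrelu_bwd(cache$a1, cb$gx)
  ib <- instnorm_bwd(cache$i1, gh)
  g[[paste0(pre, ".in1.g")]] <- ib$gg; g[[paste0(pre, ".in1.b")]] <- ib$gb
  cb <- conv_bwd(cache$c1, ib$gx, want_gx = want_gx || TRUE)
  g[[paste0(pre, ".c1.W")]] <- cb$gw; g[[paste0(pre, ".c1.b")]] <- cb$gb
  gx <- cb$gx
  # shortcut branch
  if (cache$project) {
    ib <- instnorm_bwd(cache$sc$inn, gs)
    g[[paste0(pre, ".sc_in.g")]] <- ib$gg; g[[paste0(pre, ".sc_in.b")]] <- ib$gb
    cb <- conv_bwd(cache$sc$cv, ib$gx)
    g[[paste0(pre, ".sc.W")]] <- cb$gw; g[[paste0(pre, ".sc.b")]] <- cb$gb
    gx <- gx + cb$gx
  } else {
    gx <- gx + gs
  }
  list(gx = gx, g = g)
}

encoder_forward_resnet <- function(p, x) {
  u <- cin_fwd(p, "enc", x, 2L, 3L, conv_nm = "conv1", in_nm = "conv1_in")
  c1 <- u$out
  mp <- maxpool_fwd(c1, 3L, 2L, 1L)
  h <- mp$out
  st <- resnet50_stages()
  bl_caches <- list()
  stage_out <- vector("list", 4L)
  for (s in seq_along(st)) {
    sg <- st[[s]]
    for (i in seq_len(sg$n)) {
      r <- bottleneck_fwd(p, sprintf("enc.st%d.b%d", s, i), h,
                          stride = if (i == 1L) sg$stride else 1L,
                          project = i == 1L)
      h <- r$out
      bl_caches[[sprintf("st%d.b%d", s, i)]] <- r$cache
    }
    stage_out[[s]] <- h
  }
  list(feats = list(c1 = c1, s1 = stage_out[[1]], s2 = stage_out[[2]],
                    s3 = stage_out[[3]], s4 = stage_out[[4]]),
       caches = list(conv1 = u$cache, mp = mp$cache, blocks = bl_caches))
}

encoder_backward_resnet <- function(caches, feat_grads, g, want_gx = FALSE) {
  st <- resnet50_stages()
  gh <- NULL
  for (s in rev(seq_along(st))) {
    gh <- add_arrays(gh, feat_grads[[paste0("s", s)]])
    sg <- st[[s]]
    for (i in rev(seq_len(sg$n))) {
      r <- bottleneck_bwd(caches$blocks[[sprintf("st%d.b%d", s, i)]], gh, g)
      g <- r$g
      gh <- r$gx
    }
  }
  gc1 <- maxpool_bwd(caches$mp, gh)
  gc1 <- add_arrays(gc1, feat_grads$c1)
  r <- cin_bwd(caches$conv1, gc1, g, want_gx = want_gx)
  list(g = r$g, gx = r$gx)
}

discriminator_forward <- function(disc, x, train = FALSE) {
  sp <- disc$spec; p <- disc$params
  d <- dim(x)
  if (length(d) != 4L)
    stop_validation("discriminator input must be a (H, W, C, N) array")
  if (d[1] != sp$input_resolution || d[2] != sp$input_resolution)
    stop_validation("input is %dx%d but discriminator expects %dx%d",
                    d[1], d[2], sp$input_resolution, sp$input_resolution)
  replicated <- d[3] == 1L
  x3 <- if (replicated) x[, , c(1L, 1L, 1L), , drop = FALSE] else x

  if (sp$encoder == "small-cnn") {
    enc <- encoder_forward_smallcnn(p, x3)
    skip_feats <- list(enc$feats[[3]], enc$feats[[2]], enc$feats[[1]])
    bottleneck <- enc$feats[[4]]
  } else {
    enc <- encoder_forward_resnet(p, x3)
    skip_feats <- list(enc$feats$s3, enc$feats$s2, enc$feats$s1)
    bottleneck <- enc$feats$s4
  }

  h <- bottleneck
  dec_caches <- vector("list", 4L)
  concat_widths <- integer(4L)
  for (b in seq_len(4L)) {
    if (b > 1L && sp$skip_connections) {
      concat_widths[b] <- dim(h)[3]
      h <- concat_ch(h, skip_feats[[b - 1L]])
    }
    u1 <- cin_fwd(p, sprintf("dec.b%d", b), h, 1L, 1L, "conv", "in1")
    u2 <- cin_fwd(p, sprintf("dec.b%d", b), u1$out, 1L, 0L, "pw", "in2")
    up <- tconv_fwd(u2$out, p[[sprintf("dec.b%d.up.W", b)]],
                    p[[sprintf("dec.b%d.up.b", b)]])
    i3 <- instnorm_fwd(up$out, p[[sprintf("dec.b%d.in3.g", b)]],
                       p[[sprintf("dec.b%d.in3.b", b)]])
    a3 <- lrelu_fwd(i3$out)
    h <- a3$out
    dec_caches[[b]] <- list(u1 = u1$cache, u2 = u2$cache, up = up$cache,
                            i3 = i3$cache, a3 = a3$cache)
  }
  head_cache <- NULL
  if (sp$encoder == "resnet50") {
    hw <- dim(h)[3]
    if (sp$skip_connections) h <- concat_ch(h, enc$feats$c1)
    u2 <- cin_fwd(p, "dec.h", h, 1L, 0L, "pw", "in1")
    up <- tconv_fwd(u2$out, p[["dec.h.up.W"]], p[["dec.h.up.b"]])
    i2 <- instnorm_fwd(up$out, p[["dec.h.in2.g"]], p[["dec.h.in2.b"]])
    a2 <- lrelu_fwd(i2$out)
    h <- a2$out
    head_cache <- list(u2 = u2$cache, up = up$cache, i2 = i2$cache,
                       a2 = a2$cache, pre_w = hw)
  }
  hv <- conv_fwd(h, p[["head.W"]], p[["head.b"]], 1L, 0L)
  logits <- hv$out
  probs <- softmax_channels(logits)

  cls <- NULL; cls_cache <- NULL
  if (sp$cls_head) {
    bd <- dim(bottleneck)
    pooled <- t(matrix(colMeans(matrix(bottleneck, bd[1] * bd[2],
                                       bd[3] * bd[4])), bd[3], bd[4]))
    lf <- linear_fwd(pooled, p[["cls.W"]], p[["cls.b"]])
    cls <- as.numeric(lf$out)
    cls_cache <- list(lin = lf$cache, bd = bd)
  }

  cache <- NULL
  if (train) {
    cache <- list(enc = enc, dec = dec_caches, head = hv$cache,
                  head_extra = head_cache, concat_widths = concat_widths,
                  replicated = replicated, cls = cls_cache)
  }
  list(logits = logits, probs = probs, cls = cls, cache = cache)
}

discriminator_backward <- function(disc, cache, glogits, gcls = NULL,
                                   want_gx = FALSE) {
  sp <- disc$spec; p <- disc$params
  g <- list()
  cb <- conv_bwd(cache$head, glogits)
  g[["head.W"]] <- cb$gw; g[["head.b"]] <- cb$gb
  gh <- cb$gx
  feat_grads <- list()

  if (sp$encoder == "resnet50") {
    hc <- cache$head_extra
    gh <- lrelu_bwd(hc$a2, gh)
    ib <- instnorm_bwd(hc$i2, gh)
    g[["dec.h.in2.g"]] <- ib$gg; g[["dec.h.in2.b"]] <- ib$gb
    tb <- tconv_bwd(hc$up, ib$gx)
    g[["dec.h.up.W"]] <- tb$gw; g[["dec.h.up.b"]] <- tb$gb
    r <- cin_bwd(hc$u2, tb$gx, g)
    g <- r$g; gh <- r$gx
    if (sp$skip_connections) {
      parts <- split_ch(gh, hc$pre_w)
      gh <- parts$a
      feat_grads$c1 <- parts$b
    }
  }

  skip_names <- if (sp$encoder == "small-cnn") c(3L, 2L, 1L) else c("s3", "s2", "s1")
  for (b in rev(seq_len(4L))) {
    dc <- cache$dec[[b]]
    gh <- lrelu_bwd(dc$a3, gh)
    ib <- instnorm_bwd(dc$i3, gh)
    g[[sprintf("dec.b%d.in3.g", b)]] <- ib$gg
    g[[sprintf("dec.b%d.in3.b", b)]] <- ib$gb
    tb <- tconv_bwd(dc$up, ib$gx)
    g[[sprintf("dec.b%d.up.W", b)]] <- tb$gw
    g[[sprintf("dec.b%d.up.b", b)]] <- tb$gb
    r <- cin_bwd(dc$u2, tb$gx, g)
    g <- r$g
    r <- cin_bwd(dc$u1, r$gx, g)
    g <- r$g; gh <- r$gx
    if (b > 1L && sp$skip_connections) {
      parts <- split_ch(gh, cache$concat_widths[b])
      gh <- parts$a
      nm <- skip_names[b - 1L]
      feat_grads[[as.character(nm)]] <-
        add_arrays(feat_grads[[as.character(nm)]], parts$b)
    }
  }

  if (sp$cls_head && !is.null(gcls)) {
    lb <- linear_bwd(cache$cls$lin, matrix(gcls, ncol = 1L))
    g[["cls.W"]] <- lb$gw; g[["cls.b"]] <- lb$gb
    bd <- cache$cls$bd
    # gradient of the global mean pool spreads evenly over the plane;
    # lb$gx is (N, C), flatten to (c, n) order to match array layout
    gpool <- array(rep(as.vector(t(lb$gx)), each = bd[1] * bd[2]) /
                     (bd[1] * bd[2]), bd)
    gh <- gh + gpool
  }

  if (sp$encoder == "small-cnn") {
    fg <- vector("list", 4L)
    fg[[4]] <- gh
    for (s in 1:3) fg[[s]] <- feat_grads[[as.character(s)]]
    r <- encoder_backward_smallcnn(cache$enc$caches, fg, g, want_gx = want_gx)
  } else {
    fg <- list(c1 = feat_grads$c1, s1 = feat_grads$s1, s2 = feat_grads$s2,
               s3 = feat_grads$s3, s4 = gh)
    r <- encoder_backward_resnet(cache$enc$caches, fg, g, want_gx = want_gx)
  }
  g <- r$g
  gx <- NULL
  if (want_gx && !is.null(r$gx)) {
    gx <- r$gx
    if (cache$replicated) {
      d <- dim(gx)
      gx <- array(gx[, , 1, ] + gx[, , 2, ] + gx[, , 3, ],
                  c(d[1], d[2], 1L, d[4]))
    }
  }
  list(grads = g, gx = gx)
}
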