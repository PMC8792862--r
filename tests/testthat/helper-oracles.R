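# Independent oracles used across the suite. The loss oracles walk pixels
# with explicit double loops; the metric oracle works on explicit coordinate
# sets. They deliberately share no code with the implementation.

oracle_log <- function(p) log(max(p, 1e-8))

oracle_supervised <- function(probs, masks) {
  d <- dim(probs)
  tot <- 0; n <- 0
  for (img in seq_len(d[4])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    p <- if (masks[i, j, img] == 1) probs[i, j, 1, img] else probs[i, j, 2, img]
    tot <- tot - oracle_log(p); n <- n + 1
  }
  tot / n
}

oracle_unsup <- function(probs) {
  d <- dim(probs)
  tot <- 0; n <- 0
  for (img in seq_len(d[4])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    tot <- tot - oracle_log(1 - probs[i, j, 3, img]); n <- n + 1
  }
  tot / n
}

oracle_fake <- function(probs) {
  d <- dim(probs)
  tot <- 0; n <- 0
  for (img in seq_len(d[4])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    tot <- tot - oracle_log(probs[i, j, 3, img]); n <- n + 1
  }
  tot / n
}

oracle_gen <- function(probs) {
  d <- dim(probs)
  tot <- 0; n <- 0
  for (img in seq_len(d[4])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    tot <- tot + oracle_log(probs[i, j, 3, img]); n <- n + 1
  }
  tot / n
}

# random valid probability batch (H, W, 3, N)
random_probs <- function(h, w, n, concentrated = FALSE) {
  raw <- array(runif(h * w * 3 * n), c(h, w, 3, n))
  if (concentrated) raw <- raw^8
  tot <- array(rep(apply(raw, c(1, 2, 4), sum), each = 1), c(h, w, n))
  for (k in 1:3) raw[, , k, ] <- raw[, , k, ] / tot
  raw
}

random_mask <- function(h, w, n = 1, p = 0.5) {
  if (n == 1) matrix(rbinom(h * w, 1, p), h, w)
  else array(rbinom(h * w * n, 1, p), c(h, w, n))
}

# set-based Dice / Jaccard: masks as sets of "i,j" coordinate strings
set_metrics <- function(a, b) {
  sa <- which(a == 1); sb <- which(b == 1)
  coords <- function(s, nr) paste(((s - 1) %% nr) + 1, ((s - 1) %/% nr) + 1)
  ca <- coords(sa, nrow(a)); cb <- coords(sb, nrow(b))
  inter <- length(intersect(ca, cb)); uni <- length(union(ca, cb))
  list(jaccard = if (uni == 0) 1 else inter / uni,
       dice = if (length(ca) + length(cb) == 0) 1
              else 2 * inter / (length(ca) + length(cb)))
}

# tiny discriminator used widely in tests
tiny_disc_spec <- function(res = 32L, n_classes = 3L, skip = TRUE,
                           cls_head = FALSE) {
  discriminator_spec("small-cnn", res, encoder_channels = c(3L, 4L, 6L, 8L),
                     decoder_channel_schedule = c(6L, 4L, 4L, 4L),
                     n_classes = n_classes, skip_connections = skip,
                     cls_head = cls_head)
}

tiny_gen_spec <- function(res = 64L) {
  generator_spec(res, channel_schedule = c(8L, 6L, 4L))
}

# a discriminator that outputs fixed class probabilities everywhere:
# zero out the head weights and set its bias to the target logits
constant_disc <- function(probs3, res = 32L) {
  set.seed(1)
  d <- build_discriminator(tiny_disc_spec(res))
  d$params[["head.W"]][] <- 0
  d$params[["head.b"]] <- log(probs3)
  d
}

small_phantoms <- function(n, seed = 1, res = 64L) {
  generate_phantoms(phantom_config(resolution = res, n_images = n, seed = seed))
}
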