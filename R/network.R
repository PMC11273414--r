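# The hashing network: pluggable convolutional backbone, convolutional block
# attention (channel then spatial) on an intermediate "tap" feature map,
# inter-layer fusion producing class logits and a continuous hash code via a
# learnable steepened tanh quantizer.
#
# Parameters live in a flat named list of numeric arrays; gradients mirror the
# names. Everything is plain double-precision base R, so a forward pass with
# frozen parameters is bit-reproducible on CPU.

#' Model configuration
#'
#' Assembles the architecture configuration for [dafh_model()]. Defaults
#' follow the reference setup: 224x224 inputs replicated to 3 channels,
#' 32-bit codes, attention tapped at the penultimate backbone block.
#'
#' @param n_classes number of class labels C.
#' @param hash_length code length L in bits (16, 32, 48, ...).
#' @param side input image side length in pixels.
#' @param in_channels channels presented to the backbone; grayscale images are
#'   replicated at input time.
#' @param channels per-block channel widths of the tiny backbone.
#' @param reduction channel-attention bottleneck reduction ratio r.
#' @param spatial_kernel spatial-attention convolution kernel size (odd).
#' @param d_linear1 width of the first fusion linear layer.
#' @param classifier_relu interpose a ReLU before the classification layer.
#' @param separate_quant_bias use a quantizer bias distinct from the second
#'   linear layer's bias (by default the bias is shared, appearing both inside
#'   the linear map and inside the quantizer argument).
#' @param alpha_init initial quantizer steepness, must be > 1.
#' @param backbone backbone name; `"tiny"` is the built-in CPU backbone.
#' @param tap name of the backbone block whose output feeds attention;
#'   `"penultimate"` resolves per backbone.
#' @return a list of class `dafh_config`.
#' @export
dafh_model_config <- function(n_classes, hash_length = 32L, side = 224L,
                              in_channels = 3L, channels = c(8L, 16L, 32L, 32L),
                              reduction = 4L, spatial_kernel = 7L,
                              d_linear1 = 128L, classifier_relu = FALSE,
                              separate_quant_bias = FALSE, alpha_init = 1.1,
                              backbone = "tiny", tap = "penultimate") {
  stopifnot(n_classes >= 2, hash_length >= 1, side %% 2L^length(channels) == 0,
            alpha_init > 1, spatial_kernel %% 2L == 1L)
  structure(list(n_classes = as.integer(n_classes),
                 hash_length = as.integer(hash_length),
                 side = as.integer(side), in_channels = as.integer(in_channels),
                 channels = as.integer(channels), reduction = as.integer(reduction),
                 spatial_kernel = as.integer(spatial_kernel),
                 d_linear1 = as.integer(d_linear1),
                 classifier_relu = isTRUE(classifier_relu),
                 separate_quant_bias = isTRUE(separate_quant_bias),
                 alpha_init = alpha_init, backbone = backbone, tap = tap),
            class = "dafh_config")
}

# ---- tiny backbone -----------------------------------------------------------
# Four conv(3x3) -> ReLU -> avgpool(2x2) blocks. The tap is the output of the
# penultimate block. Any feature extractor exposing the same contract
# (init/forward/backward returning f_backbone + f_tap) can be registered.

tiny_backbone_init <- function(cfg) {
  ch <- c(cfg$in_channels, cfg$channels)
  p <- list()
  for (k in seq_along(cfg$channels)) {
    fan_in <- 9L * ch[k]
    p[[paste0("bk_conv", k, "_W")]] <-
      array(rnorm(9L * ch[k] * ch[k + 1L], 0, sqrt(2 / fan_in)),
            c(3L, 3L, ch[k], ch[k + 1L]))
    p[[paste0("bk_conv", k, "_b")]] <- numeric(ch[k + 1L])
  }
  p
}

tiny_backbone_fwd <- function(params, x, cfg) {
  nb <- length(cfg$channels)
  tap_block <- if (identical(cfg$tap, "penultimate")) nb - 1L else
    as.integer(sub("^block", "", cfg$tap))
  caches <- vector("list", nb)
  h <- x
  tap <- NULL
  for (k in seq_len(nb)) {
    cv <- conv2d_fwd(h, params[[paste0("bk_conv", k, "_W")]],
                     params[[paste0("bk_conv", k, "_b")]])
    rl <- relu_fwd(cv$out)
    pl <- avgpool2_fwd(rl$out)
    caches[[k]] <- list(conv = cv$cache, relu = rl$cache, pool = pl$cache)
    h <- pl$out
    if (k == tap_block) tap <- h
  }
  list(f_backbone = h, f_tap = tap,
       cache = list(caches = caches, tap_block = tap_block, nb = nb))
}

tiny_backbone_bwd <- function(params, cache, d_fb, d_tap, cfg) {
  g <- list()
  dh <- d_fb
  for (k in rev(seq_len(cache$nb))) {
    ck <- cache$caches[[k]]
    dh <- avgpool2_bwd(dh, ck$pool)
    dh <- relu_bwd(dh, ck$relu)
    cb <- conv2d_bwd(dh, params[[paste0("bk_conv", k, "_W")]], ck$conv)
    g[[paste0("bk_conv", k, "_W")]] <- cb$dW
    g[[paste0("bk_conv", k, "_b")]] <- cb$db
    dh <- cb$dx
    if (k - 1L == cache$tap_block) dh <- dh + d_tap
  }
  g
}

# resolved backbone spatial/channel geometry
backbone_geom <- function(cfg) {
  nb <- length(cfg$channels)
  tap_block <- if (identical(cfg$tap, "penultimate")) nb - 1L else
    as.integer(sub("^block", "", cfg$tap))
  side_tap <- cfg$side %/% 2L^tap_block
  side_fb <- cfg$side %/% 2L^nb
  list(tap_block = tap_block,
       c_tap = cfg$channels[tap_block], c_fb = cfg$channels[nb],
       side_tap = side_tap, side_fb = side_fb,
       d_flat = side_tap^2 * cfg$channels[tap_block])
}

# ---- attention ---------------------------------------------------------------

bc_channel <- function(a, dimf) {
  # broadcast (C,N) channel weights over space
  array(rep(as.vector(a), each = dimf[1] * dimf[2]), dimf)
}
bc_spatial <- function(s, dimf) {
  # broadcast (H,W,1,N) spatial weights over channels
  sv <- array(s, c(dimf[1] * dimf[2], dimf[4]))
  array(sv[, rep(seq_len(dimf[4]), each = dimf[3]), drop = FALSE], dimf)
}

ca_fwd <- function(f, W1, W2) {
  ga <- gap_fwd(f); gm <- gmp_fwd(f)
  pa <- W1 %*% ga$out; pm <- W1 %*% gm$out
  ha <- pa * (pa > 0); hm <- pm * (pm > 0)
  a <- sigmoid(W2 %*% ha + W2 %*% hm)
  list(out = a, cache = list(ga = ga, gm = gm, pa = pa, pm = pm,
                             ha = ha, hm = hm, a = a))
}
ca_bwd <- function(da, W1, W2, cache) {
  a <- cache$a
  dz <- da * a * (1 - a)
  dW2 <- tcrossprod(dz, cache$ha + cache$hm)
  dha <- crossprod(W2, dz) * (cache$pa > 0)
  dhm <- crossprod(W2, dz) * (cache$pm > 0)
  dW1 <- tcrossprod(dha, cache$ga$out) + tcrossprod(dhm, cache$gm$out)
  df <- gap_bwd(crossprod(W1, dha), cache$ga$cache) +
    gmp_bwd(crossprod(W1, dhm), cache$gm$cache)
  list(df = df, dW1 = dW1, dW2 = dW2)
}

sa_fwd <- function(f1, Ws) {
  cp <- chanpool_fwd(f1)
  d <- dim(f1)
  stack <- array(0, c(d[1], d[2], 2L, d[4]))
  stack[, , 1L, ] <- cp$mean
  stack[, , 2L, ] <- cp$max
  cv <- conv2d_fwd(stack, Ws)
  s <- sigmoid(cv$out)
  list(out = s, cache = list(cp = cp$cache, conv = cv$cache, s = s))
}
sa_bwd <- function(ds, Ws, cache) {
  s <- cache$s
  dz <- ds * s * (1 - s)
  cb <- conv2d_bwd(dz, Ws, cache$conv)
  dmean <- cb$dx[, , 1L, , drop = FALSE]
  dmax <- cb$dx[, , 2L, , drop = FALSE]
  list(df1 = chanpool_bwd(dmean, dmax, cache$cp), dWs = cb$dW)
}

cbam_fwd <- function(f, W1, W2, Ws) {
  ca <- ca_fwd(f, W1, W2)
  bca <- bc_channel(ca$out, dim(f))
  f1 <- f * bca
  sa <- sa_fwd(f1, Ws)
  bsa <- bc_spatial(sa$out, dim(f))
  out <- f1 * bsa
  list(out = out,
       cache = list(ca = ca$cache, sa = sa$cache, f = f, f1 = f1,
                    bca = bca, bsa = bsa))
}
cbam_bwd <- function(dout, W1, W2, Ws, cache) {
  d <- dim(dout); HW <- d[1] * d[2]
  df1 <- dout * cache$bsa
  # ds: sum over channels of dout * f1
  arr <- aperm(array(dout * cache$f1, c(HW, d[3], d[4])), c(1L, 3L, 2L))
  dim(arr) <- c(HW * d[4], d[3])
  ds <- array(rowSums(arr), c(d[1], d[2], 1L, d[4]))
  sb <- sa_bwd(ds, Ws, cache$sa)
  df1 <- df1 + sb$df1
  # da: sum over space of df1 * f
  da <- matrix(colSums(matrix(df1 * cache$f, HW, d[3] * d[4])), d[3], d[4])
  dfa <- df1 * cache$bca
  cb <- ca_bwd(da, W1, W2, cache$ca)
  list(df = dfa + cb$df, dW1 = cb$dW1, dW2 = cb$dW2, dWs = sb$dWs)
}

#' Channel attention weights
#'
#' Squeeze-style channel attention: global average- and max-pooled channel
#' descriptors pass through a shared two-layer bottleneck, are summed, and a
#' sigmoid yields one weight per channel in (0,1).
#'
#' @param f feature map, array `(H, W, C)` or `(H, W, C, N)`.
#' @param W1 bottleneck compression matrix `(C/r, C)`.
#' @param W2 bottleneck expansion matrix `(C, C/r)`.
#' @return channel weight matrix `(C, N)`.
#' @export
channel_attention <- function(f, W1, W2) {
  if (length(dim(f)) == 3L) dim(f) <- c(dim(f), 1L)
  ca_fwd(f, W1, W2)$out
}

#' Spatial attention map
#'
#' Channelwise mean and max maps are stacked and convolved with a `k x k`
#' kernel; a sigmoid yields one weight per spatial position in (0,1).
#'
#' @param f feature map `(H, W, C)` or `(H, W, C, N)` (already
#'   channel-reweighted in the full attention block).
#' @param Ws convolution kernel, array `(k, k, 2, 1)` with odd `k`.
#' @return spatial weight array `(H, W, 1, N)`.
#' @export
spatial_attention <- function(f, Ws) {
  if (length(dim(f)) == 3L) dim(f) <- c(dim(f), 1L)
  sa_fwd(f, Ws)$out
}

#' Convolutional block attention
#'
#' Applies channel attention then spatial attention multiplicatively:
#' `out = s(f1) * f1` with `f1 = a(f) * f`, where `a` and `s` are the channel
#' and spatial weight functions. Both gates lie in (0,1), so the output never
#' exceeds the input in absolute value.
#'
#' @inheritParams channel_attention
#' @param Ws spatial attention kernel `(k, k, 2, 1)`.
#' @return attention-refined feature map, same shape as `f`.
#' @export
cbam <- function(f, W1, W2, Ws) {
  squeeze <- length(dim(f)) == 3L
  if (squeeze) dim(f) <- c(dim(f), 1L)
  out <- cbam_fwd(f, W1, W2, Ws)$out
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}

# ---- quantizer ---------------------------------------------------------------

#' Learnable steepened tanh quantizer
#'
#' `tanh(alpha * x + b)` with steepness `alpha > 1`: a differentiable,
#' strictly increasing surrogate for the sign function. As `alpha` grows the
#' output saturates toward exact signs.
#'
#' @param x numeric vector/matrix of pre-activations.
#' @param alpha steepness, must exceed 1.
#' @param b additive bias (scalar or conformable vector), default 0.
#' @return values in (-1, 1), same shape as `x`.
#' @export
ptanh <- function(x, alpha, b = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !(alpha > 1))
    stop("quantizer steepness alpha must be a scalar > 1, got ", alpha)
  tanh(alpha * x + b)
}

#' Binarize continuous codes
#'
#' Elementwise sign with the deterministic tie rule that exact zero maps to
#' +1, giving codes in \{-1, +1\}.
#'
#' @param x numeric vector/matrix of continuous codes.
#' @return same shape, values in \{-1, +1\}.
#' @export
binarize <- function(x) {
  out <- ifelse(x >= 0, 1, -1)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

alpha_from_raw <- function(a_raw) 1 + softplus(a_raw)
raw_from_alpha <- function(alpha) {
  stopifnot(alpha > 1)
  log(expm1(alpha - 1))
}

# ---- model construction ------------------------------------------------------

#' Construct a hashing model
#'
#' Initializes all parameters of the attention-fusion hashing network (He/
#' Glorot-style normal init, zero biases, quantizer steepness at
#' `cfg$alpha_init`) under a fixed seed.
#'
#' @param cfg a [dafh_model_config()].
#' @param seed integer RNG seed for weight initialization.
#' @return object of class `dafh_model`: `list(cfg, params)`.
#' @export
dafh_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "dafh_config"))
  if (!identical(cfg$backbone, "tiny"))
    stop("unknown backbone '", cfg$backbone, "'; available: tiny")
  set.seed(as.integer(seed))
  p <- tiny_backbone_init(cfg)
  g <- backbone_geom(cfg)
  Cr <- max(1L, g$c_tap %/% cfg$reduction)
  p$ca_W1 <- matrix(rnorm(Cr * g$c_tap, 0, sqrt(2 / g$c_tap)), Cr, g$c_tap)
  p$ca_W2 <- matrix(rnorm(g$c_tap * Cr, 0, sqrt(2 / Cr)), g$c_tap, Cr)
  k <- cfg$spatial_kernel
  p$sa_W <- array(rnorm(k * k * 2, 0, sqrt(2 / (k * k * 2))), c(k, k, 2L, 1L))
  d_cat <- g$c_tap + g$c_fb
  p$W_L1 <- matrix(rnorm(cfg$d_linear1 * d_cat, 0, sqrt(2 / d_cat)),
                   cfg$d_linear1, d_cat)
  p$b_L1 <- numeric(cfg$d_linear1)
  p$W_cls <- matrix(rnorm(cfg$n_classes * cfg$d_linear1, 0, sqrt(1 / cfg$d_linear1)),
                    cfg$n_classes, cfg$d_linear1)
  p$b_cls <- numeric(cfg$n_classes)
  d_hash_in <- cfg$d_linear1 + g$d_flat
  p$W_L2 <- matrix(rnorm(cfg$hash_length * d_hash_in, 0, sqrt(1 / d_hash_in)),
                   cfg$hash_length, d_hash_in)
  p$b_L2 <- numeric(cfg$hash_length)
  if (cfg$separate_quant_bias) p$b_q <- numeric(cfg$hash_length)
  p$a_raw <- raw_from_alpha(cfg$alpha_init)
  structure(list(cfg = cfg, params = p), class = "dafh_model")
}

#' @export
print.dafh_model <- function(x, ...) {
  g <- backbone_geom(x$cfg)
  cat("<dafh_model> backbone=", x$cfg$backbone,
      " side=", x$cfg$side, " L=", x$cfg$hash_length,
      " C=", x$cfg$n_classes,
      " tap=block", g$tap_block,
      " alpha=", round(model_alpha(x), 4), "\n", sep = "")
  invisible(x)
}

#' Current quantizer steepness of a model
#' @param model a `dafh_model`.
#' @return scalar alpha (> 1 by construction).
#' @export
model_alpha <- function(model) alpha_from_raw(model$params$a_raw)

# stack a list of labeled images into a (side, side, in_channels, N) batch,
# replicating grayscale to the configured channel count at input time
images_to_batch <- function(images, cfg) {
  N <- length(images)
  x <- array(0, c(cfg$side, cfg$side, cfg$in_channels, N))
  for (i in seq_len(N)) {
    px <- images[[i]]$pixels
    if (!all(dim(px)[1:2] == cfg$side))
      stop("image ", images[[i]]$source_id, " is not ", cfg$side, "x", cfg$side)
    if (length(dim(px)) == 2L) {
      for (ch in seq_len(cfg$in_channels)) x[, , ch, i] <- px
    } else x[, , , i] <- px
  }
  x
}

# Full forward pass. x: (side, side, in_channels, N).
model_forward <- function(model, x, want_cache = FALSE) {
  p <- model$params; cfg <- model$cfg
  bk <- tiny_backbone_fwd(p, x, cfg)
  cb <- cbam_fwd(bk$f_tap, p$ca_W1, p$ca_W2, p$sa_W)
  g1 <- gap_fwd(cb$out)
  g2 <- gap_fwd(bk$f_backbone)
  Fcat <- rbind(g1$out, g2$out)
  L1 <- p$W_L1 %*% Fcat + p$b_L1
  cls_in <- if (cfg$classifier_relu) L1 * (L1 > 0) else L1
  logits <- p$W_cls %*% cls_in + p$b_cls
  probs <- softmax_cols(logits)
  dC <- dim(cb$out)
  Fflat <- matrix(cb$out, prod(dC[1:3]), dC[4])
  Fcat2 <- rbind(L1, Fflat)
  z2 <- p$W_L2 %*% Fcat2 + p$b_L2
  alpha <- alpha_from_raw(p$a_raw)
  bq <- if (cfg$separate_quant_bias) p$b_q else p$b_L2
  code <- tanh(alpha * z2 + bq)
  out <- list(code_cont = code, code_bin = binarize(code),
              logits = logits, probs = probs, alpha = alpha)
  if (want_cache)
    out$cache <- list(bk = bk, cb = cb, g1 = g1, g2 = g2, Fcat = Fcat, L1 = L1,
                      cls_in = cls_in, Fcat2 = Fcat2, z2 = z2, code = code,
                      dimC = dC)
  out
}

# Backward pass from gradients on logits and continuous codes to all params.
model_backward <- function(model, cache, dlogits, dcode) {
  p <- model$params; cfg <- model$cfg
  g <- list()
  alpha <- alpha_from_raw(p$a_raw)
  dpre <- dcode * (1 - cache$code^2)
  g$a_raw <- sum(dpre * cache$z2) * sigmoid(p$a_raw)
  dz2 <- alpha * dpre
  dbq <- rowSums(dpre)
  g$W_L2 <- tcrossprod(dz2, cache$Fcat2)
  g$b_L2 <- rowSums(dz2)
  if (cfg$separate_quant_bias) g$b_q <- dbq else g$b_L2 <- g$b_L2 + dbq
  dFcat2 <- crossprod(p$W_L2, dz2)
  d1 <- cfg$d_linear1
  dL1 <- dFcat2[seq_len(d1), , drop = FALSE]
  dFflat <- dFcat2[-seq_len(d1), , drop = FALSE]
  dF_cbam <- array(dFflat, cache$dimC)
  dcls_in <- crossprod(p$W_cls, dlogits)
  g$W_cls <- tcrossprod(dlogits, cache$cls_in)
  g$b_cls <- rowSums(dlogits)
  if (cfg$classifier_relu) dcls_in <- dcls_in * (cache$L1 > 0)
  dL1 <- dL1 + dcls_in
  g$W_L1 <- tcrossprod(dL1, cache$Fcat)
  g$b_L1 <- rowSums(dL1)
  dFcat <- crossprod(p$W_L1, dL1)
  c_tap <- nrow(cache$g1$out)
  dF_cbam <- dF_cbam + gap_bwd(dFcat[seq_len(c_tap), , drop = FALSE],
                               cache$g1$cache)
  dfb <- gap_bwd(dFcat[-seq_len(c_tap), , drop = FALSE], cache$g2$cache)
  cbb <- cbam_bwd(dF_cbam, p$ca_W1, p$ca_W2, p$sa_W, cache$cb$cache)
  g$ca_W1 <- cbb$dW1; g$ca_W2 <- cbb$dW2; g$sa_W <- cbb$dWs
  gbk <- tiny_backbone_bwd(p, cache$bk$cache, dfb, cbb$df, cfg)
  c(g, gbk)
}

#' Forward pass over a batch of labeled images
#'
#' Encodes images with a frozen model, returning continuous codes in
#' (-1,1)^L, their binarization in \{-1,+1\}^L, class logits and softmax
#' probabilities.
#'
#' @param model a `dafh_model`.
#' @param images list of labeled images (see [generate_synthetic()]).
#' @param batch_size forward-pass batch size.
#' @return list with `code_cont`, `code_bin` (L x N matrices), `logits`,
#'   `probs` (C x N), `labels`, `ids`, `alpha`.
#' @export
encode_images <- function(model, images, batch_size = 64L) {
  N <- length(images)
  stopifnot(N >= 1)
  L <- model$cfg$hash_length
  code_cont <- matrix(0, L, N)
  logits <- matrix(0, model$cfg$n_classes, N)
  i <- 1L
  while (i <= N) {
    j <- min(i + batch_size - 1L, N)
    x <- images_to_batch(images[i:j], model$cfg)
    fw <- model_forward(model, x)
    code_cont[, i:j] <- fw$code_cont
    logits[, i:j] <- fw$logits
    i <- j + 1L
  }
  list(code_cont = code_cont, code_bin = binarize(code_cont),
       logits = logits, probs = softmax_cols(logits),
       labels = vapply(images, function(im) im$label, integer(1)),
       ids = vapply(images, function(im) im$source_id, character(1)),
       alpha = model_alpha(model))
}

# ---- checkpointing -----------------------------------------------------------

#' Save / load model checkpoints
#'
#' A checkpoint is a serialized parameter archive plus a JSON sidecar
#' (`<path>.json`) recording the architecture configuration and the current
#' quantizer steepness.
#'
#' @param model a `dafh_model`.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `dafh_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(cfg = unclass(model$cfg), params = model$params), path)
  side <- c(unclass(model$cfg), list(alpha = model_alpha(model)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  structure(list(cfg = structure(obj$cfg, class = "dafh_config"),
                 params = obj$params), class = "dafh_model")
}

#' Write a code table for a set of images
#'
#' Encodes images and writes a CSV with columns
#' `source_id,label,bit_0..bit_{L-1}`, bits in \{0,1\} mapped from \{-1,+1\}
#' by `(b+1)/2`.
#'
#' @inheritParams encode_images
#' @param path output CSV path.
#' @return the data frame written, invisibly.
#' @export
write_code_table <- function(model, images, path) {
  enc <- encode_images(model, images)
  bits <- t((enc$code_bin + 1) / 2)
  colnames(bits) <- paste0("bit_", seq_len(ncol(bits)) - 1L)
  df <- data.frame(source_id = enc$ids, label = enc$labels,
                   bits, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a code table written by [write_code_table()]
#'
#' @param path CSV path.
#' @return list with `codes` (N x L matrix in \{-1,+1\}), `labels`, `ids`.
#' @export
read_code_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  bitcols <- grep("^bit_", names(df), value = TRUE)
  codes <- unname(as.matrix(df[, bitcols, drop = FALSE])) * 2 - 1
  list(codes = codes, labels = as.integer(df$label),
       ids = as.character(df$source_id))
}
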