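# Low-level neural-network primitives on dense arrays.
#
# Feature maps are stored as 4-D arrays (H, W, C, N) in column-major order;
# vector features as matrices (d, N) with one column per sample. Every forward
# function returns list(out, cache); the matching *_bwd consumes the cache and
# the upstream gradient and returns gradients for inputs and parameters.
# Convolutions use im2col + BLAS matmul; stride is always 1 with "same"
# padding, and downsampling is a separate 2x2 average pool.

im2col_index <- function(H, W, kh, kw, Cin, pad) {
  key <- paste(H, W, kh, kw, Cin, pad, sep = "_")
  idx <- .dafh_cache[[key]]
  if (!is.null(idx)) return(idx)
  Hp <- H + 2L * pad
  slab <- Hp * (W + 2L * pad)
  ii <- rep(seq_len(H), times = W)
  jj <- rep(seq_len(W), each = H)
  di <- rep(seq_len(kh), times = kw)
  dj <- rep(seq_len(kw), each = kh)
  # M0[o, p]: linear index inside one (Hp x Wp) slab of patch pixel o for
  # output position p (output positions enumerated column-major, i fastest)
  M0 <- outer(di, ii, "+") - 1L + Hp * (outer(dj, jj, "+") - 2L)
  kk <- kh * kw
  idx <- M0[rep(seq_len(kk), Cin), , drop = FALSE] +
    slab * rep(0:(Cin - 1L), each = kk)
  storage.mode(idx) <- "integer"
  .dafh_cache[[key]] <- idx
  idx
}

pad_spatial <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

# x: (H,W,Cin,N); W: (kh,kw,Cin,Cout); b: NULL or length Cout
conv2d_fwd <- function(x, W, b = NULL, pad = NULL) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cin <- d[3]; N <- d[4]
  kd <- dim(W); kh <- kd[1]; kw <- kd[2]; Cout <- kd[4]
  stopifnot(kd[3] == Cin)
  if (is.null(pad)) pad <- (kh - 1L) %/% 2L
  xp <- pad_spatial(x, pad)
  idx1 <- im2col_index(H, Wd, kh, kw, Cin, pad)
  slabN <- prod(dim(xp)[1:3])
  HW <- H * Wd
  rows <- kh * kw * Cin
  full <- rep(as.vector(idx1), N) +
    rep.int(slabN * (0:(N - 1L)), rep.int(rows * HW, N))
  col <- matrix(xp[full], nrow = rows)
  Wmat <- matrix(W, rows, Cout)
  out_mat <- crossprod(Wmat, col)
  if (!is.null(b)) out_mat <- out_mat + b
  y <- aperm(array(out_mat, c(Cout, HW, N)), c(2L, 1L, 3L))
  dim(y) <- c(H, Wd, Cout, N)
  list(out = y,
       cache = list(col = col, dimx = d, kdim = kd, pad = pad, has_b = !is.null(b)))
}

conv2d_bwd <- function(dy, W, cache) {
  d <- cache$dimx; H <- d[1]; Wd <- d[2]; Cin <- d[3]; N <- d[4]
  kd <- cache$kdim; kh <- kd[1]; kw <- kd[2]; Cout <- kd[4]
  pad <- cache$pad
  HW <- H * Wd
  rows <- kh * kw * Cin
  dy_mat <- matrix(aperm(array(dy, c(HW, Cout, N)), c(2L, 1L, 3L)), Cout, HW * N)
  dWmat <- tcrossprod(cache$col, dy_mat)           # (rows x Cout)
  dW <- array(dWmat, kd)
  db <- if (cache$has_b) rowSums(dy_mat) else NULL
  Wmat <- matrix(W, rows, Cout)
  dcol <- Wmat %*% dy_mat                          # (rows x HW*N)
  dxp <- array(0, c(H + 2L * pad, Wd + 2L * pad, Cin, N))
  kk <- kh * kw
  for (o in seq_len(kk)) {
    di <- (o - 1L) %% kh + 1L
    dj <- (o - 1L) %/% kh + 1L
    sl <- dcol[o + kk * (0:(Cin - 1L)), , drop = FALSE]      # (Cin x HW*N)
    arr <- aperm(array(sl, c(Cin, HW, N)), c(2L, 1L, 3L))
    dim(arr) <- c(H, Wd, Cin, N)
    ri <- di:(di + H - 1L); rj <- dj:(dj + Wd - 1L)
    dxp[ri, rj, , ] <- dxp[ri, rj, , , drop = FALSE] + arr
  }
  dx <- if (pad > 0L) dxp[pad + seq_len(H), pad + seq_len(Wd), , , drop = FALSE] else dxp
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}
relu_bwd <- function(dy, mask) dy * mask

# 2x2 average pooling, stride 2; spatial dims must be even
avgpool2_fwd <- function(x) {
  d <- dim(x)
  o1 <- seq(1L, d[1], 2L); e1 <- o1 + 1L
  o2 <- seq(1L, d[2], 2L); e2 <- o2 + 1L
  y <- (x[o1, o2, , , drop = FALSE] + x[e1, o2, , , drop = FALSE] +
        x[o1, e2, , , drop = FALSE] + x[e1, e2, , , drop = FALSE]) / 4
  list(out = y, cache = d)
}
avgpool2_bwd <- function(dy, dimx) {
  dx <- array(0, dimx)
  o1 <- seq(1L, dimx[1], 2L); e1 <- o1 + 1L
  o2 <- seq(1L, dimx[2], 2L); e2 <- o2 + 1L
  g <- dy / 4
  dx[o1, o2, , ] <- g; dx[e1, o2, , ] <- g
  dx[o1, e2, , ] <- g; dx[e1, e2, , ] <- g
  dx
}

# global average pool (H,W,C,N) -> (C,N)
gap_fwd <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  list(out = matrix(colMeans(m), d[3], d[4]), cache = d)
}
gap_bwd <- function(dy, dimx) {
  HW <- dimx[1] * dimx[2]
  dx <- array(rep(as.vector(dy) / HW, each = HW), dimx)
  dx
}

# global max pool over space (H,W,C,N) -> (C,N); argmax cached for backward
gmp_fwd <- function(x) {
  d <- dim(x)
  HW <- d[1] * d[2]
  m <- matrix(x, HW, d[3] * d[4])
  am <- max.col(t(m), ties.method = "first")
  vals <- m[cbind(am, seq_along(am))]
  list(out = matrix(vals, d[3], d[4]), cache = list(dimx = d, am = am))
}
gmp_bwd <- function(dy, cache) {
  d <- cache$dimx
  HW <- d[1] * d[2]
  dm <- matrix(0, HW, d[3] * d[4])
  dm[cbind(cache$am, seq_along(cache$am))] <- as.vector(dy)
  array(dm, d)
}

# channel-wise mean and max maps (H,W,C,N) -> (H,W,1,N) each
chanpool_fwd <- function(x) {
  d <- dim(x)
  HW <- d[1] * d[2]
  m <- aperm(array(x, c(HW, d[3], d[4])), c(2L, 1L, 3L))     # (C, HW, N)
  dim(m) <- c(d[3], HW * d[4])
  mn <- colMeans(m)
  am <- max.col(t(m), ties.method = "first")
  mx <- m[cbind(am, seq_along(am))]
  mean_map <- array(mn, c(d[1], d[2], 1L, d[4]))
  max_map <- array(mx, c(d[1], d[2], 1L, d[4]))
  list(mean = mean_map, max = max_map, cache = list(dimx = d, am = am))
}
chanpool_bwd <- function(dmean, dmax, cache) {
  d <- cache$dimx
  HW <- d[1] * d[2]
  C <- d[3]
  dm <- matrix(0, C, HW * d[4])
  dm[cbind(cache$am, seq_along(cache$am))] <- as.vector(dmax)
  dm <- dm + matrix(as.vector(dmean) / C, C, HW * d[4], byrow = TRUE)
  dx <- aperm(array(dm, c(C, HW, d[4])), c(2L, 1L, 3L))
  array(dx, d)
}

linear_fwd <- function(x, W, b) {
  list(out = W %*% x + b, cache = x)
}
linear_bwd <- function(dy, W, x) {
  list(dx = crossprod(W, dy), dW = tcrossprod(dy, x), db = rowSums(dy))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
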