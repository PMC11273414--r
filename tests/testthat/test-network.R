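test_that("channel attention: zero parameters give 0.5, outputs stay in (0,1)", {
  set.seed(1)
  f <- array(runif(6 * 6 * 8), c(6, 6, 8))
  W1z <- matrix(0, 4, 8); W2z <- matrix(0, 8, 4)
  expect_equal(channel_attention(f, W1z, W2z), matrix(0.5, 8, 1))
  W1 <- matrix(rnorm(32), 4, 8); W2 <- matrix(rnorm(32), 8, 4)
  a <- channel_attention(f, W1, W2)
  expect_true(all(a > 0 & a < 1))
})

test_that("channel attention is equivariant under channel permutation", {
  set.seed(2)
  f <- array(runif(5 * 5 * 6), c(5, 5, 6))
  W1 <- matrix(rnorm(18), 3, 6); W2 <- matrix(rnorm(18), 6, 3)
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  a <- channel_attention(f, W1, W2)
  a_perm <- channel_attention(f[, , perm, drop = FALSE],
                              W1[, perm], W2[perm, ])
  expect_equal(a_perm, a[perm, , drop = FALSE], tolerance = 1e-12)
})

test_that("spatial attention: zero kernel gives uniform 0.5, constant input gives constant map", {
  set.seed(3)
  f <- array(runif(6 * 6 * 4), c(6, 6, 4))
  Wz <- array(0, c(3, 3, 2, 1))
  expect_equal(spatial_attention(f, Wz), array(0.5, c(6, 6, 1, 1)))
  Ws <- array(rnorm(18), c(3, 3, 2, 1))
  s <- spatial_attention(f, Ws)
  expect_equal(dim(s)[1:2], dim(f)[1:2])
  fconst <- array(0.3, c(6, 6, 4))
  sc <- spatial_attention(fconst, Ws)
  # away from the zero-padded border the map is spatially constant
  expect_lt(diff(range(sc[2:5, 2:5, 1, 1])), 1e-12)
})

test_that("block attention: zero parameters scale by 0.25; gating is contractive", {
  set.seed(4)
  f <- array(runif(6 * 6 * 4, -1, 1), c(6, 6, 4))
  W1z <- matrix(0, 2, 4); W2z <- matrix(0, 4, 2); Wsz <- array(0, c(3, 3, 2, 1))
  expect_equal(cbam(f, W1z, W2z, Wsz), 0.25 * f, tolerance = 1e-12)
  W1 <- matrix(rnorm(8), 2, 4); W2 <- matrix(rnorm(8), 4, 2)
  Ws <- array(rnorm(18), c(3, 3, 2, 1))
  out <- cbam(f, W1, W2, Ws)
  expect_identical(dim(out), dim(f))
  expect_true(all(abs(out) <= abs(f) + 1e-12))
  expect_equal(cbam(f * 0, W1, W2, Ws), f * 0)
})

test_that("ptanh is a monotone sign surrogate with alpha > 1 enforced", {
  expect_equal(ptanh(0, alpha = 2), 0)
  expect_equal(ptanh(0.5, alpha = 2), tanh(1), tolerance = 1e-12)
  expect_error(ptanh(0.5, alpha = 1), "alpha")
  expect_error(ptanh(0.5, alpha = 0.3), "alpha")
  x <- sort(runif(100, -2, 2))
  expect_true(all(diff(ptanh(x, alpha = 1.5)) > 0))
  # saturation limit toward the sign function
  x2 <- c(-0.5, -0.1, 0.1, 0.5)
  expect_lt(max(abs(ptanh(x2, alpha = 1e3) - sign(x2))), 1e-6)
})

test_that("binarization uses the +1 tie rule and commutes with ptanh at b = 0", {
  expect_equal(binarize(c(-0.9, 0.2, 0)), c(-1, 1, 1))
  x <- rnorm(200)
  expect_equal(binarize(binarize(x)), binarize(x))
  expect_equal(binarize(ptanh(x, alpha = 3)), binarize(x))
  # raising alpha never flips a bit when the quantizer bias is zero
  expect_equal(binarize(ptanh(x, alpha = 50)), binarize(ptanh(x, alpha = 1.01)))
})

test_that("a zeroed fusion head yields the zero code and uniform probabilities", {
  cfg <- tiny_cfg(n_classes = 4)
  model <- dafh_model(cfg, seed = 1)
  for (nm in names(model$params))
    if (nm != "a_raw") model$params[[nm]] <- model$params[[nm]] * 0
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  fw <- dafh:::model_forward(model, x)
  expect_equal(fw$code_cont, matrix(0, 8, 2))
  expect_equal(fw$probs, matrix(0.25, 4, 2))
})

test_that("code length follows the configured number of bits", {
  for (L in c(16L, 32L, 48L)) {
    m <- dafh_model(tiny_cfg(hash_length = L), seed = 1)
    enc <- encode_images(m, random_images(3, side = 16))
    expect_equal(nrow(enc$code_cont), L)
    expect_true(all(abs(enc$code_cont) < 1))
    expect_true(all(enc$code_bin %in% c(-1, 1)))
    expect_equal(colSums(enc$probs), rep(1, 3), tolerance = 1e-6)
  }
})

test_that("the frozen forward pass is deterministic", {
  m <- dafh_model(tiny_cfg(), seed = 5)
  imgs <- random_images(4, side = 16)
  expect_identical(encode_images(m, imgs), encode_images(m, imgs))
})
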