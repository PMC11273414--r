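test_that("focal loss matches closed-form evaluations", {
  expect_equal(focal_loss(c(0, 1), 1L, gamma = 1.5), 0)
  expect_equal(focal_loss(c(0.5, 0.5), 0L, gamma = 0), -log(0.5),
               tolerance = 1e-12)
  expect_equal(focal_loss(c(0.9, 0.1), 0L, gamma = 1.5),
               0.1^1.5 * -log(0.9), tolerance = 1e-9)
  expect_error(focal_loss(c(0.5, 0.5), 2L), "out of range")
})

test_that("focal loss at gamma 0 is cross-entropy; it decreases in p_y", {
  py <- seq(0.01, 0.99, by = 0.01)
  for (p in py) {
    expect_equal(focal_loss(c(p, 1 - p), 0L, gamma = 0), -log(p),
                 tolerance = 1e-9)
  }
  l <- vapply(py, function(p) focal_loss(c(p, 1 - p), 0L, gamma = 1.5),
              numeric(1))
  expect_true(all(l >= 0))
  expect_true(all(diff(l) < 0))
})

test_that("triplet loss matches direct arithmetic on anchored distances", {
  mk <- function(dap, dan) {
    # codes on one axis give exact prescribed distances
    a <- c(0, 0); p <- c(dap, 0); n <- c(dan, 0)
    triplet_loss(a, p, n, margin = 0.5)
  }
  expect_equal(mk(0.2, 0.9), 0)
  expect_equal(mk(0.8, 0.4), 0.9, tolerance = 1e-12)
  v <- rnorm(8)
  expect_equal(triplet_loss(v, v, v, margin = 0.5), 0.5)
  expect_error(triplet_loss(1:4, 1:4, 1:3), "identical dimensions")
})

test_that("triplet loss is permutation invariant and clamps at the margin", {
  set.seed(5)
  a <- matrix(rnorm(16 * 6), 16); p <- matrix(rnorm(16 * 6), 16)
  n <- matrix(rnorm(16 * 6), 16)
  perm <- sample(16)
  expect_equal(triplet_loss(a, p, n, 0.5),
               triplet_loss(a[perm, ], p[perm, ], n[perm, ], 0.5),
               tolerance = 1e-12)
  # far negatives: exact zero
  expect_equal(triplet_loss(a, a, a + 100, 0.5), 0)
})

test_that("total loss composes the weighted terms exactly", {
  set.seed(6)
  C <- 4L; L <- 8L; N <- 5L
  mk_out <- function() {
    z <- matrix(rnorm(C * N), C)
    list(probs = apply(exp(z), 2, function(c) c / sum(c)),
         code_cont = matrix(tanh(rnorm(L * N)), L))
  }
  oa <- mk_out(); op <- mk_out(); on_ <- mk_out()
  la <- sample(0:(C - 1), N, TRUE); lp <- la
  ln <- (la + 1L) %% C
  w0 <- loss_weights(lam = 0, beta = 1)
  expect_equal(total_loss(oa, op, on_, la, lp, ln, w0)$total,
               triplet_loss(oa$code_cont, op$code_cont, on_$code_cont, 0.5))
  w <- loss_weights()  # lam = 1/3, beta = 1
  tl <- total_loss(oa, op, on_, la, lp, ln, w)
  expect_equal(tl$total,
               (tl$focal_a + tl$focal_p + tl$focal_n) / 3 + tl$triplet,
               tolerance = 1e-12)
})

test_that("triplet sampling honors label constraints and determinism", {
  tr <- sample_triplets(c(0L, 0L, 1L, 1L), 3)
  expect_length(tr$anchor, 4)
  expect_equal(tr$positive, c(2L, 1L, 4L, 3L))  # forced class twins
  labs <- c(0L, 0L, 1L, 1L)
  expect_true(all(labs[tr$anchor] == labs[tr$positive]))
  expect_true(all(labs[tr$anchor] != labs[tr$negative]))
  expect_true(all(tr$anchor != tr$positive))

  none <- sample_triplets(c(0L, 1L, 2L, 3L), 1)
  expect_length(none$anchor, 0)
  expect_equal(none$n_skipped, 4L)

  expect_identical(sample_triplets(c(0L, 0L, 0L, 1L), 5),
                   sample_triplets(c(0L, 0L, 0L, 1L), 5))
  expect_warning(one <- sample_triplets(c(2L, 2L, 2L), 1), "single class")
  expect_length(one$anchor, 0)
})
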