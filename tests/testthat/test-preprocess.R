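test_that("min-max scaling maps constant images to zeros", {
  expect_equal(minmax_scale(matrix(0.7, 4, 4)), matrix(0, 4, 4))
  m <- matrix(c(2, 4, 6, 10), 2, 2)
  expect_equal(range(minmax_scale(m)), c(0, 1))
})

test_that("IQR cleaning removes exactly the hand-computed outliers", {
  # 20 mid-gray images plus one all-white image; constant pixels make the
  # variance fence vacuous, so only the mean fence acts
  set.seed(1)
  vals <- seq(0.45, 0.55, length.out = 20)
  imgs <- c(lapply(seq_along(vals), function(i)
              constant_image(vals[i], id = paste0("mid_", i))),
            list(constant_image(1, id = "white")))
  means <- c(vals, 1)
  q <- unname(quantile(means, c(0.25, 0.75)))
  fence <- c(q[1] - 1.5 * (q[2] - q[1]), q[2] + 1.5 * (q[2] - q[1]))
  expect_identical(which(means < fence[1] | means > fence[2]), 21L)
  cl <- iqr_clean(imgs, factor = 1.5)
  expect_length(cl$kept, 20)
  expect_length(cl$removed, 1)
  expect_equal(cl$removed[[1]]$source_id, "white")
  # partition with order preserved
  expect_identical(vapply(cl$kept, `[[`, "", "source_id"),
                   paste0("mid_", 1:20))
})

test_that("IQR cleaning keeps everything for identical inputs and infinite fences", {
  same <- lapply(1:6, function(i) constant_image(0.4, id = paste0("s", i)))
  expect_length(iqr_clean(same)$removed, 0)
  mixed <- random_images(10)
  expect_length(iqr_clean(mixed, factor = Inf)$removed, 0)
  expect_error(iqr_clean(mixed[1:3]), "at least 4")
})

test_that("IQR cleaning partitions its input exactly", {
  imgs <- random_images(25, seed = 3)
  cl <- iqr_clean(imgs, factor = 0.5)
  ids <- function(x) vapply(x, `[[`, "", "source_id")
  expect_setequal(c(ids(cl$kept), ids(cl$removed)), ids(imgs))
  expect_length(intersect(ids(cl$kept), ids(cl$removed)), 0)
})

test_that("augmentation identities and determinism hold", {
  im <- random_images(1, side = 24)[[1]]
  expect_identical(augment(im, character(0)), im)
  ident <- augment(im, list(rotation = 0, scaling = 1))
  expect_lt(max(abs(ident$pixels - im$pixels)), 1e-6)
  a <- augment(im, "noise", rng_seed = 7)
  b <- augment(im, "noise", rng_seed = 7)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, augment(im, "noise", rng_seed = 8)$pixels))
})

test_that("augmentation validates ops and preserves shape, label and range", {
  im <- random_images(1, side = 24)[[1]]
  expect_error(augment(im, c("noise", "sharpen")), "sharpen.*valid ops")
  out <- augment(im, c("noise", "blur", "brightness", "rotation", "scaling"),
                 rng_seed = 2)
  expect_identical(dim(out$pixels), dim(im$pixels))
  expect_identical(out$label, im$label)
  expect_true(min(out$pixels) >= 0 && max(out$pixels) <= 1)
})

test_that("stratified split hits exact per-class counts", {
  imgs <- c(random_images(100, n_classes = 4))
  sp <- stratified_split(imgs, 0.8, seed = 1)
  db_labs <- table(vapply(sp$database, `[[`, 0L, "label"))
  q_labs <- table(vapply(sp$query, `[[`, 0L, "label"))
  expect_true(all(db_labs == 20))
  expect_true(all(q_labs == 5))

  imb <- c(lapply(1:50, function(i) constant_image(i / 100, label = 0L,
                                                   id = paste0("a", i))),
           lapply(1:10, function(i) constant_image(i / 20, label = 1L,
                                                   id = paste0("b", i))))
  sp2 <- stratified_split(imb, 0.8, seed = 2)
  expect_equal(as.integer(table(vapply(sp2$database, `[[`, 0L, "label"))),
               c(40L, 8L))
  expect_equal(as.integer(table(vapply(sp2$query, `[[`, 0L, "label"))),
               c(10L, 2L))
})

test_that("stratified split is deterministic and validates class sizes", {
  imgs <- random_images(30, n_classes = 3, seed = 5)
  a <- stratified_split(imgs, 0.8, seed = 9)
  b <- stratified_split(imgs, 0.8, seed = 9)
  expect_identical(a, b)
  bad <- c(imgs, list(constant_image(0.2, label = 7L, id = "lonely")))
  expect_error(stratified_split(bad, 0.8, seed = 1), "7")
})

test_that("split marks images and preserves class proportions within 1 image", {
  set.seed(11)
  counts <- c(13L, 29L, 8L)
  imgs <- unlist(lapply(seq_along(counts), function(c)
    lapply(seq_len(counts[c]), function(i)
      constant_image(runif(1), label = c - 1L,
                     id = paste0("c", c, "_", i)))), recursive = FALSE)
  sp <- stratified_split(imgs, 0.8, seed = 4)
  expect_true(all(vapply(sp$database, `[[`, "", "split") == "database"))
  for (c in 0:2) {
    n_db <- sum(vapply(sp$database, `[[`, 0L, "label") == c)
    expect_lte(abs(n_db - 0.8 * counts[c + 1]), 1)
  }
})
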