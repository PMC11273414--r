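test_that("average precision matches hand evaluations", {
  expect_equal(average_precision(c(1, 1), 2), 1)
  expect_equal(average_precision(c(0, 1), 1), 0.5)
  expect_equal(average_precision(c(1, 0, 1), 2), (1 + 2 / 3) / 2)
  expect_equal(average_precision(c(0, 0, 0), 3), 0)
  expect_error(average_precision(c(1, 0), 0), "n_gt = 0")
  expect_error(average_precision(c(1, 1, 1), 2), "more relevant")
})

test_that("moving a relevant item earlier never decreases AP (exhaustive n <= 6)", {
  for (n in 2:6) {
    grids <- expand.grid(rep(list(c(0, 1)), n))
    for (g in seq_len(nrow(grids))) {
      rel <- as.numeric(grids[g, ])
      n_gt <- max(1, sum(rel))
      ap <- average_precision(rel, n_gt)
      for (i in seq_len(n - 1)) {
        if (rel[i] == 0 && rel[i + 1] == 1) {
          swapped <- rel
          swapped[c(i, i + 1)] <- rel[c(i + 1, i)]
          expect_gte(average_precision(swapped, n_gt), ap)
        }
      }
    }
  }
})

test_that("MAP reduces to AP for one query and truncates correctly", {
  rel <- c(1, 0, 1, 0)
  expect_equal(mean_average_precision(list(rel), 2), average_precision(rel, 2))
  # clamped normalization: a perfect truncated list scores 1
  expect_equal(mean_average_precision(list(c(1, 1)), n_gts = 5, k = 2), 1)
  # raw normalization keeps the full ground-truth denominator
  expect_equal(mean_average_precision(list(c(1, 1)), n_gts = 5, k = 2,
                                      normalize = "gt"), 0.4)
  expect_error(mean_average_precision(list(), integer(0)), "empty")
})

test_that("MAP@1 equals top-1 accuracy", {
  set.seed(8)
  rels <- lapply(1:50, function(i) sample(c(0, 1), 10, TRUE))
  n_gts <- vapply(rels, function(r) max(1, sum(r)), 0)
  expect_equal(mean_average_precision(rels, n_gts, k = 1),
               mean(vapply(rels, function(r) r[1], 0)))
})

test_that("MAP agrees with the brute-force oracle on random rankings", {
  set.seed(9)
  rels <- lapply(1:100, function(i) sample(c(0, 1), sample(3:12, 1), TRUE))
  n_gts <- vapply(rels, function(r) sum(r) + sample(0:3, 1), 0)
  n_gts <- pmax(n_gts, 1)
  got <- mean_average_precision(rels, n_gts, Inf)
  want <- mean(mapply(oracle_ap, rels, n_gts))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("the rank-1 confusion matrix is row-normalized with MAP@1 on its diagonal", {
  q <- c(0L, 0L, 0L, 1L, 1L, 2L)
  t1 <- c(0L, 0L, 1L, 1L, 1L, 0L)
  M <- map1_confusion(q, t1, 3L)
  expect_equal(unname(M[1, ]), c(2 / 3, 1 / 3, 0))
  expect_equal(unname(M[2, ]), c(0, 1, 0))
  expect_equal(unname(M[3, ]), c(1, 0, 0))
  expect_equal(unname(rowSums(M)), c(1, 1, 1))
  map1 <- mean(q == t1)
  counts <- as.vector(table(factor(q, 0:2)))
  expect_equal(sum(diag(M) * counts) / sum(counts), map1)
  # perfect retrieval: identity
  expect_equal(unname(map1_confusion(0:2, 0:2, 3L)), diag(3))
})

test_that("end-to-end evaluation ties the pieces together", {
  # two well-separated code clusters: retrieval must be perfect
  set.seed(10)
  base <- rbind(rep(1, 16), rep(-1, 16))
  flip <- function(v, k) { i <- sample(16, k); v[i] <- -v[i]; v }
  db_codes <- do.call(rbind, lapply(1:10, function(i) flip(base[i %% 2 + 1, ], 2)))
  db_labs <- rep(c(1L, 0L), 5)
  q_codes <- rbind(flip(base[1, ], 1), flip(base[2, ], 1))
  idx <- retrieval_index(db_codes, db_labs)
  rep_ <- evaluate_retrieval(idx, q_codes, c(0L, 1L), k = 3)
  expect_equal(rep_$map_at_k, 1)
  expect_equal(rep_$map_at_1, 1)
  expect_equal(rep_$map, 1)
  expect_equal(unname(rep_$confusion_map1), diag(2))
  expect_error(evaluate_retrieval(idx, q_codes[0, , drop = FALSE], integer(0)),
               "empty")
})
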