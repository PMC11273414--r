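# Trainer behavior on small synthetic corpora (side 32, tiny class counts)
# so the whole file runs in seconds-to-a-minute on one CPU.

make_split <- function(n_classes = 3L, per_class = 10L, side = 32L,
                       noise_sd = 0, seed = 1L) {
  imgs <- small_corpus(n_classes, per_class, side, noise_sd, seed)
  stratified_split(imgs, 0.8, seed = seed)
}

test_that("zero epochs return the model unchanged with empty history", {
  sp <- make_split()
  cfg <- dafh_model_config(n_classes = 3, hash_length = 8, side = 32)
  model <- dafh_model(cfg, seed = 2)
  fit <- dafh_train(sp$database, sp$query, model,
                    train_config(epochs = 0, seed = 1))
  expect_identical(fit$model$params, model$params)
  expect_equal(nrow(fit$state$history), 0)
})

test_that("training is bit-reproducible under a fixed seed", {
  sp <- make_split()
  cfg <- dafh_model_config(n_classes = 3, hash_length = 8, side = 32)
  tc <- train_config(epochs = 2, learning_rate = 1e-3, batch_size = 16,
                     seed = 7)
  f1 <- dafh_train(sp$database, sp$query, dafh_model(cfg, seed = 3), tc)
  f2 <- dafh_train(sp$database, sp$query, dafh_model(cfg, seed = 3), tc)
  expect_identical(f1$state$history, f2$state$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("the quantizer steepness stays above 1 throughout training", {
  sp <- make_split()
  cfg <- dafh_model_config(n_classes = 3, hash_length = 8, side = 32)
  fit <- dafh_train(sp$database, sp$query, dafh_model(cfg, seed = 4),
                    train_config(epochs = 3, learning_rate = 1e-3,
                                 batch_size = 16, seed = 1))
  expect_true(all(fit$state$history$alpha > 1))
  expect_gt(model_alpha(fit$model), 1)
})

test_that("checkpoints round-trip and reproduce validation metrics exactly", {
  sp <- make_split()
  cfg <- dafh_model_config(n_classes = 3, hash_length = 8, side = 32)
  out <- tempfile("run_")
  fit <- dafh_train(sp$database, sp$query, dafh_model(cfg, seed = 5),
                    train_config(epochs = 1, learning_rate = 1e-3,
                                 batch_size = 16, seed = 2),
                    out_dir = out)
  expect_true(file.exists(file.path(out, "best.rds")))
  expect_true(file.exists(file.path(out, "last.rds")))
  expect_true(file.exists(file.path(out, "loss_log.jsonl")))
  restored <- load_checkpoint(file.path(out, "last.rds"))
  v1 <- dafh_validate(fit$model, sp$query, sp$database, k = 10)
  v2 <- dafh_validate(restored, sp$query, sp$database, k = 10)
  expect_identical(v1, v2)
  expect_equal(v2$map_at_k, fit$state$history$val_map_k[1])
  # the per-step loss log is valid JSONL with the expected fields
  rec <- jsonlite::fromJSON(readLines(file.path(out, "loss_log.jsonl"))[1])
  expect_true(all(c("epoch", "step", "focal_a", "triplet", "total",
                    "alpha") %in% names(rec)))
})

test_that("validation clamps k to the database size and rejects empty sets", {
  sp <- make_split(per_class = 5L)
  model <- dafh_model(dafh_model_config(n_classes = 3, hash_length = 8,
                                        side = 32), seed = 6)
  v <- dafh_validate(model, sp$query, sp$database, k = 10000)
  expect_equal(v$k, length(sp$database))
  expect_error(dafh_validate(model, list(), sp$database), "non-empty")
})

test_that("self-queries hit a zero-distance match, excluded only by source id", {
  sp <- make_split()
  model <- dafh_model(dafh_model_config(n_classes = 3, hash_length = 16,
                                        side = 32), seed = 7)
  enc <- encode_images(model, sp$query)
  idx <- retrieval_index(t(enc$code_bin), enc$labels, enc$ids)
  for (i in seq_along(sp$query)) {
    top <- query_index(idx, enc$code_bin[, i], k = 1)
    expect_equal(top$distances, 0L)
    excl <- query_index(idx, enc$code_bin[, i], k = idx$N,
                        exclude_id = enc$ids[i])
    expect_false(enc$ids[i] %in% excl$ids)
    expect_equal(length(excl$order), idx$N - 1L)
  }
})

test_that("single-class database is rejected", {
  imgs <- small_corpus(2, 6, 32)[1:6]
  model <- dafh_model(dafh_model_config(n_classes = 2, hash_length = 8,
                                        side = 32), seed = 1)
  expect_error(dafh_train(imgs, imgs, model, train_config(epochs = 1)),
               "2 classes")
})
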