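# Training loop: per epoch, shuffle the database set into batches, sample
# triplets within each batch, run one shared forward pass per batch, form the
# combined focal+triplet objective on the triplet members, backpropagate and
# take an Adam step; after every epoch, validate MAP@10 / MAP@1 of the query
# set against the database set. Fully reproducible given the config seed on a
# single CPU thread.

derive_seed <- function(seed, tag) {
  u <- utf8ToInt(tag)
  h <- sum(u * seq_along(u))
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

#' Training configuration
#'
#' Defaults mirror the reference training recipe: Adam, learning rate 1e-4,
#' weight decay (regularization rate) 1e-4, 50 epochs, triplet margin 0.5,
#' focal gamma 1.5.
#'
#' @param epochs number of passes over the database set.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 regularization rate added to gradients.
#' @param batch_size minibatch size (the batch is also the triplet pool).
#' @param weights a [loss_weights()].
#' @param seed integer seed controlling shuffling, triplet draws and any other
#'   training randomness.
#' @param k_validate ranking depth of the per-epoch validation MAP@k.
#' @param device `"cpu"` (the only built-in compute target).
#' @return list of class `dafh_train_config`.
#' @export
train_config <- function(epochs = 50L, learning_rate = 1e-4,
                         weight_decay = 1e-4, batch_size = 32L,
                         weights = loss_weights(), seed = 1L,
                         k_validate = 10L, device = "cpu") {
  stopifnot(epochs >= 0, learning_rate > 0, weight_decay >= 0, batch_size >= 2,
            inherits(weights, "dafh_loss_weights"))
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 weights = weights, seed = as.integer(seed),
                 k_validate = as.integer(k_validate), device = device),
            class = "dafh_train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, wd, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g + wd * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# one optimization step on a batch; returns loss breakdown and updated
# params/optimizer state
train_step <- function(model, batch_images, w, opt_state, lr, wd, step_seed) {
  labels <- vapply(batch_images, function(im) im$label, integer(1))
  trip <- suppressWarnings(sample_triplets(labels, step_seed))
  if (length(trip$anchor) == 0L)
    return(list(model = model, opt_state = opt_state, loss = NULL))
  x <- images_to_batch(batch_images, model$cfg)
  fw <- model_forward(model, x, want_cache = TRUE)
  Tn <- length(trip$anchor)
  pick <- function(idx) list(probs = fw$probs[, idx, drop = FALSE],
                             code_cont = fw$code_cont[, idx, drop = FALSE])
  out_a <- pick(trip$anchor); out_p <- pick(trip$positive)
  out_n <- pick(trip$negative)
  loss <- total_loss(out_a, out_p, out_n, labels[trip$anchor],
                     labels[trip$positive], labels[trip$negative], w)
  # gradients on logits (focal terms) and codes (triplet term), scattered
  # back onto batch columns; a batch element can appear in several triplets
  C <- nrow(fw$probs); L <- nrow(fw$code_cont); N <- ncol(fw$probs)
  dlogits <- matrix(0, C, N)
  dcode <- matrix(0, L, N)
  scatter <- function(acc, idx, g) {
    for (t in seq_along(idx)) acc[, idx[t]] <- acc[, idx[t]] + g[, t]
    acc
  }
  for (role in list(list(i = trip$anchor), list(i = trip$positive),
                    list(i = trip$negative))) {
    gl <- focal_logit_grad(fw$probs[, role$i, drop = FALSE], labels[role$i],
                           w$gamma, weight = w$lam / Tn)
    dlogits <- scatter(dlogits, role$i, gl)
  }
  tg <- triplet_grads(out_a$code_cont, out_p$code_cont, out_n$code_cont,
                      w$margin)
  dcode <- scatter(dcode, trip$anchor, w$beta * tg$da)
  dcode <- scatter(dcode, trip$positive, w$beta * tg$dp)
  dcode <- scatter(dcode, trip$negative, w$beta * tg$dn)
  grads <- model_backward(model, fw$cache, dlogits, dcode)
  upd <- adam_step(model$params, grads, opt_state, lr, wd)
  model$params <- upd$params
  list(model = model, opt_state = upd$state, loss = loss)
}

#' Train a hashing model
#'
#' Runs the full training loop on the database (training) set with per-epoch
#' validation on the query set, tracking the best checkpoint by validation
#' MAP@k.
#'
#' @param database_images labeled images forming the training corpus and
#'   retrieval database (must contain at least 2 classes).
#' @param query_images labeled images used as validation queries.
#' @param model a [dafh_model()].
#' @param cfg a [train_config()].
#' @param out_dir optional directory for checkpoints (`best.rds`, `last.rds`),
#'   a JSONL per-step loss log and a per-epoch metrics CSV.
#' @param verbose print per-epoch progress.
#' @return list with `model` (final), `best_model`, `state`
#'   (`epoch`, `step`, `best_map`, `history` data frame with one row per
#'   completed epoch: `epoch`, `train_loss`, `val_map_k`, `val_map_1`,
#'   `alpha`).
#' @export
dafh_train <- function(database_images, query_images, model, cfg,
                       out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "dafh_model"), inherits(cfg, "dafh_train_config"))
  db_labels <- vapply(database_images, function(im) im$label, integer(1))
  if (length(unique(db_labels)) < 2L)
    stop("database set must contain at least 2 classes")
  w <- cfg$weights
  opt <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_map_k = numeric(0), val_map_1 = numeric(0),
                        alpha = numeric(0))
  best_map <- -Inf
  best_model <- model
  step <- 0L
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_con <- file(file.path(out_dir, "loss_log.jsonl"), open = "wt")
    on.exit(close(log_con), add = TRUE)
  }
  N <- length(database_images)
  for (epoch in seq_len(cfg$epochs)) {
    set.seed(derive_seed(cfg$seed, paste0("shuffle_epoch", epoch)))
    ord <- sample.int(N)
    losses <- numeric(0)
    b0 <- 1L
    while (b0 <= N) {
      b1 <- min(b0 + cfg$batch_size - 1L, N)
      step <- step + 1L
      st <- train_step(model, database_images[ord[b0:b1]], w, opt,
                       cfg$learning_rate, cfg$weight_decay,
                       derive_seed(cfg$seed, paste0("triplets_e", epoch,
                                                    "_s", step)))
      model <- st$model
      opt <- st$opt_state
      if (!is.null(st$loss)) {
        if (!is.finite(st$loss$total))
          stop("training diverged (non-finite loss) at epoch ", epoch,
               ", step ", step)
        losses <- c(losses, st$loss$total)
        if (!is.null(log_con))
          writeLines(jsonlite::toJSON(c(list(epoch = epoch, step = step),
                                        st$loss,
                                        list(alpha = model_alpha(model))),
                                      auto_unbox = TRUE, digits = NA), log_con)
      }
      b0 <- b1 + 1L
    }
    stopifnot(model_alpha(model) > 1)
    val <- dafh_validate(model, query_images, database_images,
                         k = cfg$k_validate)
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = if (length(losses)) mean(losses) else NA_real_,
                                val_map_k = val$map_at_k,
                                val_map_1 = val$map_at_1,
                                alpha = model_alpha(model)))
    if (val$map_at_k > best_map) {
      best_map <- val$map_at_k
      best_model <- model
      if (!is.null(out_dir)) save_checkpoint(model, file.path(out_dir, "best.rds"))
    }
    if (!is.null(out_dir)) {
      save_checkpoint(model, file.path(out_dir, "last.rds"))
      write.csv(history, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    }
    if (verbose)
      message(sprintf("epoch %d/%d loss=%.4f map@%d=%.3f map@1=%.3f alpha=%.3f",
                      epoch, cfg$epochs, mean(losses), cfg$k_validate,
                      val$map_at_k, val$map_at_1, model_alpha(model)))
  }
  list(model = model, best_model = best_model,
       state = list(epoch = cfg$epochs, step = step,
                    best_map = if (is.finite(best_map)) best_map else NA_real_,
                    history = history))
}

#' Validate retrieval quality of a model
#'
#' Encodes query and database sets, builds the Hamming retrieval index from
#' the database side, and evaluates MAP@k and MAP@1. A pure function of the
#' model and the data.
#'
#' @param model a `dafh_model` (trained or untrained).
#' @param query_images,database_images labeled image lists; neither may be
#'   empty.
#' @param k ranking depth for MAP@k (clamped to the database size).
#' @return the [evaluate_retrieval()] report.
#' @export
dafh_validate <- function(model, query_images, database_images, k = 10L) {
  if (length(query_images) == 0 || length(database_images) == 0)
    stop("query and database sets must be non-empty")
  enc_db <- encode_images(model, database_images)
  enc_q <- encode_images(model, query_images)
  idx <- retrieval_index(t(enc_db$code_bin), enc_db$labels, enc_db$ids)
  overlap <- any(enc_q$ids %in% enc_db$ids)
  evaluate_retrieval(idx, t(enc_q$code_bin), enc_q$labels, k = k,
                     query_ids = if (overlap) enc_q$ids else NULL)
}
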