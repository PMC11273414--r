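# Multi-task objective: multi-class focal loss on each triplet member plus a
# margin-based triplet loss on the continuous hash codes,
#   L_total = lambda * (L_focal_a + L_focal_p + L_focal_n) + beta * L_triplet,
# with lambda = 1/3 so the classification term is the mean over the three
# triplet members, and beta = 1. Batch reduction is the mean for both terms.

FOCAL_EPS <- 1e-12

#' Loss weights
#'
#' @param lam weight on the summed focal terms (default 1/3, making the three
#'   per-member focal losses an average).
#' @param beta weight on the triplet term (default 1).
#' @param gamma focal focusing exponent (default 1.5).
#' @param margin triplet margin (default 0.5).
#' @return list of class `dafh_loss_weights`.
#' @export
loss_weights <- function(lam = 1 / 3, beta = 1, gamma = 1.5, margin = 0.5) {
  stopifnot(lam >= 0, beta >= 0, gamma >= 0, margin >= 0)
  structure(list(lam = lam, beta = beta, gamma = gamma, margin = margin),
            class = "dafh_loss_weights")
}

#' Multi-class focal loss
#'
#' For a predicted probability `p_y` of the true class,
#' `-(1 - p_y)^gamma * log(p_y)`; at `gamma = 0` this is exactly
#' cross-entropy. `p_y` is floored at 1e-12 before the log. Batch reduction is
#' the mean.
#'
#' @param probs probability vector over C classes, or a `(C, N)` matrix of
#'   column probability vectors.
#' @param y true class id(s) in `[0, C-1]` (length 1 or N).
#' @param gamma focusing exponent, >= 0.
#' @return scalar mean focal loss (>= 0).
#' @export
focal_loss <- function(probs, y, gamma = 1.5) {
  if (is.null(dim(probs))) probs <- matrix(probs, ncol = 1L)
  C <- nrow(probs); N <- ncol(probs)
  y <- as.integer(y)
  if (any(y < 0L | y >= C)) stop("class label out of range [0, ", C - 1L, "]")
  py <- pmax(probs[cbind(y + 1L, seq_len(N))], FOCAL_EPS)
  mean(-(1 - py)^gamma * log(py))
}

# gradient of mean focal loss w.r.t. logits (through softmax), (C,N) matrix;
# `weight` is a per-sample multiplier (already including 1/N reductions)
focal_logit_grad <- function(probs, y, gamma, weight = 1) {
  C <- nrow(probs); N <- ncol(probs)
  yi <- cbind(as.integer(y) + 1L, seq_len(N))
  py <- pmax(probs[yi], FOCAL_EPS)
  # dL/dp_y; the loss depends on p_y only. At py = 1 the loss is flat zero
  # (and the gamma < 1 power would be Inf*0), so force the term to 0 there.
  t1 <- if (gamma > 0) ifelse(py >= 1, 0, gamma * (1 - py)^(gamma - 1) * log(py)) else 0
  dLdpy <- t1 - (1 - py)^gamma / py
  if (length(weight) > 1L) weight <- rep(weight, each = C)
  # softmax jacobian: dL/dz = p .* (e_y - p) * dL/dp_y ... expanded:
  # dL/dz_i = dLdpy * p_y * ([i==y] - p_i)
  dz <- -probs * rep(dLdpy * py, each = C)
  dz[yi] <- dz[yi] + dLdpy * py
  dz * weight
}

#' Triplet margin loss on code vectors
#'
#' Mean over triplets of `max(0, d(a,p) - d(a,n) + margin)` with `d` the
#' Euclidean (optionally squared-Euclidean) distance on continuous codes.
#'
#' @param a,p,n anchor/positive/negative codes: equal-length vectors or
#'   `(L, N)` matrices of column vectors.
#' @param margin margin, >= 0.
#' @param squared use squared Euclidean distance.
#' @return scalar mean triplet loss (>= 0).
#' @export
triplet_loss <- function(a, p, n, margin = 0.5, squared = FALSE) {
  if (is.null(dim(a))) { a <- cbind(a); p <- cbind(p); n <- cbind(n) }
  if (!all(dim(a) == dim(p)) || !all(dim(a) == dim(n)))
    stop("anchor/positive/negative codes must have identical dimensions")
  dap <- sqrt(colSums((a - p)^2))
  dan <- sqrt(colSums((a - n)^2))
  if (squared) { dap <- dap^2; dan <- dan^2 }
  mean(pmax(0, dap - dan + margin))
}

# gradients of mean triplet loss w.r.t. a, p, n (Euclidean distance)
triplet_grads <- function(a, p, n, margin) {
  N <- ncol(a)
  dap <- sqrt(colSums((a - p)^2))
  dan <- sqrt(colSums((a - n)^2))
  active <- (dap - dan + margin) > 0
  sap <- ifelse(active & dap > 0, 1 / (N * pmax(dap, 1e-30)), 0)
  san <- ifelse(active & dan > 0, 1 / (N * pmax(dan, 1e-30)), 0)
  gap_ <- sweep(a - p, 2L, sap, "*")
  gan_ <- sweep(a - n, 2L, san, "*")
  list(da = gap_ - gan_, dp = -gap_, dn = gan_)
}

#' Combined multi-task loss
#'
#' `lam * (focal(anchor) + focal(positive) + focal(negative)) +
#'  beta * triplet(codes)`, each focal term a batch mean, plus a per-term
#' breakdown for logging.
#'
#' @param out_a,out_p,out_n forward outputs (lists with `probs`, `code_cont`)
#'   for the anchor, positive and negative members of aligned triplets.
#' @param labels_a,labels_p,labels_n true class ids per member.
#' @param w a [loss_weights()].
#' @return list with `total` and breakdown `focal_a`, `focal_p`, `focal_n`,
#'   `triplet`.
#' @export
total_loss <- function(out_a, out_p, out_n, labels_a, labels_p, labels_n, w) {
  fa <- focal_loss(out_a$probs, labels_a, w$gamma)
  fp <- focal_loss(out_p$probs, labels_p, w$gamma)
  fn <- focal_loss(out_n$probs, labels_n, w$gamma)
  tl <- triplet_loss(out_a$code_cont, out_p$code_cont, out_n$code_cont,
                     w$margin)
  list(total = w$lam * (fa + fp + fn) + w$beta * tl,
       focal_a = fa, focal_p = fp, focal_n = fn, triplet = tl)
}

#' Sample triplets from a labeled batch
#'
#' Every batch element with at least one same-class partner serves as anchor
#' exactly once; its positive is drawn uniformly from same-class others and
#' its negative uniformly from all other-class elements. Anchors without a
#' same-class partner are skipped and counted.
#'
#' @param labels integer class ids of the batch elements.
#' @param rng_seed integer seed; the draw is deterministic given the seed.
#' @return list of class `dafh_triplets` with integer index vectors
#'   `anchor`, `positive`, `negative` and scalar `n_skipped`. A single-class
#'   batch yields an empty triplet set with a warning.
#' @export
sample_triplets <- function(labels, rng_seed) {
  labels <- as.integer(labels)
  n <- length(labels)
  set.seed(as.integer(rng_seed))
  if (length(unique(labels)) < 2L) {
    warning("batch contains a single class; no triplets can be formed")
    return(structure(list(anchor = integer(0), positive = integer(0),
                          negative = integer(0), n_skipped = n),
                     class = "dafh_triplets"))
  }
  anchor <- integer(0); positive <- integer(0); negative <- integer(0)
  skipped <- 0L
  for (i in seq_len(n)) {
    same <- which(labels == labels[i]); same <- same[same != i]
    if (length(same) == 0L) { skipped <- skipped + 1L; next }
    diff <- which(labels != labels[i])
    anchor <- c(anchor, i)
    positive <- c(positive, same[sample.int(length(same), 1L)])
    negative <- c(negative, diff[sample.int(length(diff), 1L)])
  }
  structure(list(anchor = anchor, positive = positive, negative = negative,
                 n_skipped = skipped), class = "dafh_triplets")
}
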