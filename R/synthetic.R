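# Synthetic class-structured grayscale images. Each class carries a
# deterministic signature: an oriented sinusoidal grating with class-specific
# frequency, orientation and base phase, plus a class-specific layout of
# Gaussian blobs. Individual images vary by a small seeded phase and blob
# jitter, and are corrupted by Gaussian pixel noise of the requested standard
# deviation. With small noise the classes are linearly separable in raw pixel
# space, so retrieval quality on these fixtures is a meaningful signal.

#' Labeled image container
#'
#' @param pixels numeric matrix (grayscale) or `(H, W, 3)` array with values
#'   in `[0, 1]`.
#' @param label integer class id in `[0, C-1]` (NA allowed for unlabeled
#'   ingestion).
#' @param source_id provenance string (file path or synthetic tag).
#' @param split `"database"`, `"query"` or `"unassigned"`.
#' @return object of class `labeled_image`.
#' @export
labeled_image <- function(pixels, label, source_id,
                          split = c("unassigned", "database", "query")) {
  split <- match.arg(split)
  stopifnot(is.numeric(pixels), min(pixels) >= 0, max(pixels) <= 1)
  structure(list(pixels = pixels, label = as.integer(label),
                 source_id = as.character(source_id), split = split),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<labeled_image> ", x$source_id, " ", d[1], "x", d[2],
      " label=", x$label, " split=", x$split, "\n", sep = "")
  invisible(x)
}

#' Synthetic dataset specification
#'
#' @param n_classes number of classes (>= 2).
#' @param per_class_counts integer vector of images per class (allows
#'   imbalance); defaults to 50 per class.
#' @param image_side image side length in pixels.
#' @param noise_sd Gaussian pixel noise standard deviation (intensity units).
#' @param seed integer seed; regeneration under the same spec is
#'   bit-for-bit identical.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 4L,
                           per_class_counts = rep(50L, n_classes),
                           image_side = 64L, noise_sd = 0.02, seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  per_class_counts <- as.integer(per_class_counts)
  stopifnot(length(per_class_counts) == n_classes, all(per_class_counts >= 1),
            image_side >= 8, noise_sd >= 0)
  structure(list(n_classes = n_classes, per_class_counts = per_class_counts,
                 image_side = as.integer(image_side), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# deterministic signature parameters of one class
class_signature <- function(spec, cls) {
  set.seed(derive_seed(spec$seed, paste0("signature_class", cls)))
  n_blobs <- 2L + cls %% 3L
  list(theta = pi * cls / spec$n_classes,
       freq = 3 + 2 * cls,
       phase = 2 * pi * cls / spec$n_classes,
       blob_x = runif(n_blobs, 0.15, 0.85),
       blob_y = runif(n_blobs, 0.15, 0.85),
       blob_amp = 0.25, blob_sigma = spec$image_side / 8)
}

render_synthetic_image <- function(spec, sig, cls, i) {
  side <- spec$image_side
  set.seed(derive_seed(spec$seed, paste0("class", cls, "_img", i)))
  dphase <- runif(1, -0.5, 0.5)
  jx <- runif(length(sig$blob_x), -2, 2)
  jy <- runif(length(sig$blob_y), -2, 2)
  u <- (seq_len(side) - 0.5) / side
  U <- matrix(u, side, side)        # row coordinate
  V <- matrix(u, side, side, byrow = TRUE)
  px <- 0.5 + 0.22 * sin(2 * pi * sig$freq *
                           (U * cos(sig$theta) + V * sin(sig$theta)) +
                           sig$phase + dphase)
  ax <- sig$blob_x * side + jx
  ay <- sig$blob_y * side + jy
  R <- matrix(seq_len(side), side, side)
  Cc <- matrix(seq_len(side), side, side, byrow = TRUE)
  for (b in seq_along(ax))
    px <- px + sig$blob_amp *
      exp(-((R - ax[b])^2 + (Cc - ay[b])^2) / (2 * sig$blob_sigma^2))
  if (spec$noise_sd > 0)
    px <- px + rnorm(side * side, 0, spec$noise_sd)
  pmin(pmax(px, 0), 1)
}

#' Generate a synthetic labeled image set
#'
#' @param spec a [synthetic_spec()].
#' @return list of [labeled_image()] objects, grouped by class in label
#'   order, with `source_id` tags encoding class, index and seed.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  out <- vector("list", sum(spec$per_class_counts))
  k <- 0L
  for (cls in 0:(spec$n_classes - 1L)) {
    sig <- class_signature(spec, cls)
    for (i in seq_len(spec$per_class_counts[cls + 1L])) {
      k <- k + 1L
      out[[k]] <- labeled_image(
        render_synthetic_image(spec, sig, cls, i), cls,
        sprintf("synth_c%d_i%03d_s%d", cls, i, spec$seed))
    }
  }
  out
}
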