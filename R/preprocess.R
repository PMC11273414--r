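# Preprocessing: intensity standardization, corpus-level IQR outlier
# cleaning on per-image mean and variance, augmentation, and the stratified
# database/query split.

#' Min-max scale intensities to [0, 1]
#'
#' A constant-intensity image (degenerate range) maps to all zeros rather
#' than dividing by zero.
#'
#' @param px numeric matrix/array of intensities.
#' @return same shape, values in `[0, 1]`.
#' @export
minmax_scale <- function(px) {
  rng <- range(px)
  if (rng[2] - rng[1] <= 0) return(px * 0)
  (px - rng[1]) / (rng[2] - rng[1])
}

#' Standardize an image to the working size
#'
#' Min-max scales to `[0, 1]`, bilinearly resamples to `side x side`, and
#' quantizes to 8-bit depth so that PNG serialization round-trips losslessly.
#'
#' @param px numeric matrix of intensities (any range).
#' @param side target side length (default 224).
#' @return `side x side` matrix with values in `{0, 1/255, ..., 1}`.
#' @export
standardize_image <- function(px, side = 224L) {
  px <- minmax_scale(px)
  if (!all(dim(px)[1:2] == side))
    px <- EBImage::resize(px, w = side, h = side)
  px <- pmin(pmax(px, 0), 1)
  round(px * 255) / 255
}

#' Per-image and corpus intensity statistics
#'
#' Computes each image's mean and variance, and the corpus quartiles and
#' interquartile range of both statistics.
#'
#' @param images list of [labeled_image()] objects.
#' @return list with `per_image` (data frame: `source_id`, `mean`,
#'   `variance`) and `corpus` (for each statistic: `q1`, `q3`, `iqr`).
#' @export
image_stats <- function(images) {
  means <- vapply(images, function(im) mean(im$pixels), numeric(1))
  vars <- vapply(images, function(im) stats::var(as.vector(im$pixels)),
                 numeric(1))
  quart <- function(x) {
    q <- unname(quantile(x, c(0.25, 0.75)))
    list(q1 = q[1], q3 = q[2], iqr = q[2] - q[1])
  }
  list(per_image = data.frame(
         source_id = vapply(images, function(im) im$source_id, character(1)),
         mean = means, variance = vars),
       corpus = list(mean = quart(means), variance = quart(vars)))
}

#' Interquartile-range outlier cleaning
#'
#' An image is removed iff its per-image mean intensity or its per-image
#' variance falls outside `[Q1 - factor*IQR, Q3 + factor*IQR]` of that
#' statistic's corpus distribution. Kept and removed partition the input and
#' the input order is preserved within each part.
#'
#' @param images list of [labeled_image()] objects (at least 4, so quartiles
#'   are defined).
#' @param factor fence multiplier (conventional default 1.5; `Inf` removes
#'   nothing).
#' @return list with `kept`, `removed` (lists of images), `kept_mask`
#'   (logical, input order) and `stats` (the [image_stats()] record).
#' @export
iqr_clean <- function(images, factor = 1.5) {
  if (length(images) < 4L)
    stop("IQR cleaning needs at least 4 images (quartiles undefined for ",
         length(images), ")")
  st <- image_stats(images)
  inside <- function(x, q) {
    if (is.infinite(factor)) return(rep(TRUE, length(x)))
    x >= q$q1 - factor * q$iqr & x <= q$q3 + factor * q$iqr
  }
  keep <- inside(st$per_image$mean, st$corpus$mean) &
    inside(st$per_image$variance, st$corpus$variance)
  list(kept = images[keep], removed = images[!keep], kept_mask = keep,
       stats = st)
}

#' Default augmentation parameter ranges
#'
#' Units: noise sd in intensity units, blur sd in pixels, brightness delta in
#' intensity units, rotation in degrees, scale as a factor.
#'
#' @return named list of length-2 numeric ranges.
#' @export
augment_ranges <- function() {
  list(noise = c(0, 0.05), blur = c(0, 1.5), brightness = c(-0.2, 0.2),
       rotation = c(-15, 15), scaling = c(0.9, 1.1))
}

AUGMENT_OPS <- c("noise", "blur", "brightness", "rotation", "scaling")

apply_scaling <- function(px, s) {
  side_r <- nrow(px); side_c <- ncol(px)
  nr <- max(1L, round(side_r * s)); nc <- max(1L, round(side_c * s))
  sc <- EBImage::resize(px, w = nr, h = nc)
  out <- matrix(0, side_r, side_c)
  if (nr >= side_r) {                      # center crop
    r0 <- (nr - side_r) %/% 2L; c0 <- (nc - side_c) %/% 2L
    out <- sc[r0 + seq_len(side_r), c0 + seq_len(side_c)]
  } else {                                 # center pad
    r0 <- (side_r - nr) %/% 2L; c0 <- (side_c - nc) %/% 2L
    out[r0 + seq_len(nr), c0 + seq_len(nc)] <- sc
  }
  out
}

#' Augment a labeled image
#'
#' Applies a subset of \{rotation, scaling, blur, noise, brightness\} in that
#' fixed order. `ops` may be a character vector, in which case each
#' parameter is drawn uniformly from `ranges` under `rng_seed`, or a named
#' list giving explicit parameters (rotation angle in degrees, scale factor,
#' blur sd in px, noise sd, brightness delta). Output has the same shape and
#' label, values clipped to `[0, 1]`; identical seed and ops give identical
#' output.
#'
#' @param image a [labeled_image()].
#' @param ops character vector or named parameter list; empty means identity.
#' @param rng_seed integer seed for parameter draws and noise.
#' @param ranges parameter ranges, see [augment_ranges()].
#' @return the augmented [labeled_image()].
#' @export
augment <- function(image, ops, rng_seed = 1L, ranges = augment_ranges()) {
  nms <- if (is.list(ops)) names(ops) else as.character(ops)
  bad <- setdiff(nms, AUGMENT_OPS)
  if (length(bad))
    stop("unknown augmentation op(s): ", paste(bad, collapse = ", "),
         "; valid ops: ", paste(AUGMENT_OPS, collapse = ", "))
  if (length(nms) == 0L) return(image)
  set.seed(as.integer(rng_seed))
  par <- list()
  for (op in AUGMENT_OPS) {            # fixed draw order for determinism
    if (!op %in% nms) next
    par[[op]] <- if (is.list(ops) && !is.null(ops[[op]])) ops[[op]] else
      runif(1, ranges[[op]][1], ranges[[op]][2])
  }
  px <- image$pixels
  if ("rotation" %in% nms && abs(par$rotation) > 0)
    px <- EBImage::rotate(px, par$rotation,
                          output.dim = c(nrow(px), ncol(px)), bg.col = 0)
  if ("scaling" %in% nms && abs(par$scaling - 1) > 0)
    px <- apply_scaling(px, par$scaling)
  if ("blur" %in% nms && par$blur > 1e-8)
    px <- EBImage::gblur(px, sigma = par$blur)
  if ("noise" %in% nms && par$noise > 0)
    px <- px + rnorm(length(px), 0, par$noise)
  if ("brightness" %in% nms)
    px <- px + par$brightness
  px <- pmin(pmax(px, 0), 1)
  dim(px) <- dim(image$pixels)
  out <- image
  out$pixels <- px
  out
}

#' Stratified database/query split
#'
#' Per class, `round(ratio * n_c)` images (round half to even; shortfalls go
#' to the query side) are drawn into the database set - which doubles as the
#' training corpus and retrieval database - and the rest become queries. The
#' split is deterministic under the seed.
#'
#' @param images list of [labeled_image()] objects; every class needs >= 2
#'   images.
#' @param ratio database-side fraction (default 0.8).
#' @param seed integer seed.
#' @return list with `database` and `query` image lists (with their `split`
#'   field set).
#' @export
stratified_split <- function(images, ratio = 0.8, seed = 1L) {
  labels <- vapply(images, function(im) im$label, integer(1))
  tab <- table(labels)
  small <- names(tab)[tab < 2]
  if (length(small))
    stop("class(es) with fewer than 2 images: ", paste(small, collapse = ", "))
  db_idx <- integer(0)
  for (cls in as.integer(names(tab))) {
    idx <- which(labels == cls)
    n_db <- round(ratio * length(idx))
    set.seed(derive_seed(seed, paste0("split_class", cls)))
    db_idx <- c(db_idx, idx[sample.int(length(idx), n_db)])
  }
  db_idx <- sort(db_idx)
  mark <- function(im, sp) { im$split <- sp; im }
  list(database = lapply(images[db_idx], mark, "database"),
       query = lapply(images[setdiff(seq_along(images), db_idx)], mark, "query"))
}
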