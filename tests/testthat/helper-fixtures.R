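# Shared fixtures: tiny model configurations, small synthetic corpora, and a
# DICOM byte-stream writer independent of the package's reader.

tiny_cfg <- function(n_classes = 3L, hash_length = 8L, side = 16L) {
  dafh_model_config(n_classes = n_classes, hash_length = hash_length,
                    side = side, channels = c(4L, 6L, 8L), d_linear1 = 10L,
                    reduction = 2L, spatial_kernel = 3L)
}

random_images <- function(n, side = 16L, n_classes = 3L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    labeled_image(matrix(runif(side * side), side, side),
                  (i - 1L) %% n_classes, paste0("rand_", i)))
}

constant_image <- function(value, side = 8L, label = 0L, id = "const") {
  labeled_image(matrix(value, side, side), label, id)
}

small_corpus <- function(n_classes = 3L, per_class = 12L, side = 32L,
                         noise_sd = 0, seed = 1L) {
  generate_synthetic(synthetic_spec(n_classes, rep(per_class, n_classes),
                                    side, noise_sd, seed))
}

# ---- DICOM writer (explicit or implicit VR little endian) -------------------
# Encodes the byte layout straight from the standard: 128-byte preamble,
# "DICM", explicit-VR file meta group with the transfer syntax UID, then the
# image module tags and 16-bit PixelData, row-major.

dcm_u16 <- function(v) writeBin(as.integer(v), raw(), size = 2,
                                endian = "little")
dcm_u32 <- function(v) writeBin(as.integer(v), raw(), size = 4,
                                endian = "little")

dcm_elem_explicit <- function(group, element, vr, payload) {
  if (length(payload) %% 2L == 1L) payload <- c(payload, as.raw(0))
  hdr <- c(dcm_u16(group), dcm_u16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(hdr, as.raw(c(0, 0)), dcm_u32(length(payload)), payload)
  else
    c(hdr, dcm_u16(length(payload)), payload)
}

dcm_elem_implicit <- function(group, element, payload) {
  if (length(payload) %% 2L == 1L) payload <- c(payload, as.raw(0))
  c(dcm_u16(group), dcm_u16(element), dcm_u32(length(payload)), payload)
}

#' write a single-frame 16-bit unsigned DICOM; pixels: integer matrix
write_test_dicom <- function(path, pixels, explicit = TRUE,
                             omit_pixeldata = FALSE) {
  ts <- if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
  ts_elem <- dcm_elem_explicit(0x0002, 0x0010, "UI", charToRaw(ts))
  meta <- c(dcm_elem_explicit(0x0002, 0x0000, "UL", dcm_u32(length(ts_elem))),
            ts_elem)
  el <- if (explicit) {
    function(g, e, vr, payload) dcm_elem_explicit(g, e, vr, payload)
  } else {
    function(g, e, vr, payload) dcm_elem_implicit(g, e, payload)
  }
  body <- c(el(0x0028, 0x0010, "US", dcm_u16(nrow(pixels))),
            el(0x0028, 0x0011, "US", dcm_u16(ncol(pixels))),
            el(0x0028, 0x0100, "US", dcm_u16(16)),
            el(0x0028, 0x0101, "US", dcm_u16(16)),
            el(0x0028, 0x0103, "US", dcm_u16(0)))
  if (!omit_pixeldata) {
    pd <- writeBin(as.integer(t(pixels)), raw(), size = 2, endian = "little")
    body <- c(body, el(0x7FE0, 0x0010, "OW", pd))
  }
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), path)
  invisible(path)
}

# brute-force AP straight from the defining sum, used as metric oracle
oracle_ap <- function(relevance, n_gt) {
  s <- 0
  hits <- 0
  for (k in seq_along(relevance)) {
    if (relevance[k] == 1) {
      hits <- hits + 1
      s <- s + hits / k
    }
  }
  s / n_gt
}
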