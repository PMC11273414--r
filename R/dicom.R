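# Minimal DICOM reader for single-frame, uncompressed, little-endian files
# (explicit or implicit VR). Covers the tags needed to recover the pixel
# array: Rows, Columns, BitsAllocated, PixelRepresentation, the rescale
# slope/intercept, and PixelData. Compressed transfer syntaxes, sequences of
# undefined length and multi-frame objects are out of scope and rejected
# with an explicit error.

u16 <- function(raw, off) {
  readBin(raw[(off + 1):(off + 2)], "integer", size = 2, endian = "little",
          signed = FALSE)
}
u32 <- function(raw, off) {
  lo <- u16(raw, off); hi <- u16(raw, off + 2)
  lo + hi * 65536
}

VR_LONG <- c("OB", "OW", "OF", "SQ", "UT", "UN")
TS_IMPLICIT <- "1.2.840.10008.1.2"
TS_EXPLICIT <- "1.2.840.10008.1.2.1"

# parse one data element; returns list(group, element, value_raw, next_off)
parse_element <- function(raw, off, explicit) {
  g <- u16(raw, off); e <- u16(raw, off + 2)
  if (explicit) {
    vr <- rawToChar(raw[(off + 5):(off + 6)])
    if (vr %in% VR_LONG) {
      len <- u32(raw, off + 8)
      hdr <- 12L
    } else {
      len <- u16(raw, off + 6)
      hdr <- 8L
    }
  } else {
    len <- u32(raw, off + 4)
    hdr <- 8L
    vr <- NA_character_
  }
  if (len == 4294967295)
    stop("DICOM element (", sprintf("%04x,%04x", g, e),
         ") has undefined length; sequences are not supported")
  val <- if (len > 0) raw[(off + hdr + 1):(off + hdr + len)] else raw(0)
  list(group = g, element = e, vr = vr, value = val,
       next_off = off + hdr + len)
}

#' Read a single-frame DICOM file
#'
#' Parses uncompressed little-endian DICOM (explicit or implicit VR) and
#' returns the raw pixel matrix with the rescale slope/intercept applied.
#'
#' @param path DICOM file path.
#' @return list with `pixels` (numeric matrix, rows x columns), `rows`,
#'   `cols`, `bits_allocated`.
#' @export
read_dicom <- function(path) {
  if (!file.exists(path)) stop("DICOM file not found: ", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  off <- 0L
  if (length(raw) > 132 && rawToChar(raw[129:132]) == "DICM") off <- 132L
  # file meta group (0002,xxxx) is always explicit VR little endian
  ts <- TS_EXPLICIT
  repeat {
    if (off + 8 > length(raw)) break
    g <- u16(raw, off)
    if (g != 2L) break
    el <- parse_element(raw, off, explicit = TRUE)
    if (el$element == 16L)            # (0002,0010) TransferSyntaxUID
      ts <- rawToChar(el$value[el$value != as.raw(0)])  # strip NUL padding
    off <- el$next_off
  }
  ts <- trimws(ts)
  if (!ts %in% c(TS_IMPLICIT, TS_EXPLICIT))
    stop("unsupported DICOM transfer syntax '", ts, "' in ", path,
         " (only uncompressed little endian is supported)")
  explicit <- identical(ts, TS_EXPLICIT)
  tags <- list()
  while (off + 8 <= length(raw)) {
    el <- parse_element(raw, off, explicit)
    tags[[sprintf("%04x%04x", el$group, el$element)]] <- el
    off <- el$next_off
  }
  need_us <- function(key, name) {
    el <- tags[[key]]
    if (is.null(el)) stop("DICOM file ", path, " lacks ", name)
    u16(el$value, 0)
  }
  rows <- need_us("00280010", "Rows")
  cols <- need_us("00280011", "Columns")
  bits <- need_us("00280100", "BitsAllocated")
  pixrep <- if (!is.null(tags[["00280103"]])) u16(tags[["00280103"]]$value, 0) else 0L
  ds_num <- function(key, default) {
    el <- tags[[key]]
    if (is.null(el)) return(default)
    as.numeric(trimws(rawToChar(el$value)))
  }
  slope <- ds_num("00281053", 1)
  intercept <- ds_num("00281052", 0)
  pd <- tags[["7fe00010"]]
  if (is.null(pd) || length(pd$value) == 0)
    stop("DICOM file ", path, " has no readable PixelData")
  n <- rows * cols
  vals <- if (bits == 16L) {
    if (length(pd$value) < 2 * n)
      stop("PixelData in ", path, " is truncated")
    readBin(pd$value, "integer", n = n, size = 2, endian = "little",
            signed = pixrep == 1L)
  } else if (bits == 8L) {
    if (length(pd$value) < n) stop("PixelData in ", path, " is truncated")
    as.integer(pd$value[seq_len(n)])
  } else stop("unsupported BitsAllocated ", bits, " in ", path)
  px <- matrix(as.numeric(vals), nrow = rows, ncol = cols, byrow = TRUE)
  list(pixels = px * slope + intercept, rows = rows, cols = cols,
       bits_allocated = bits)
}

#' Convert a DICOM slice to a standardized labeled image
#'
#' Reads the slice, min-max scales intensities to `[0, 1]` per image
#' (constant slices map to zeros), resamples to `side x side`, and quantizes
#' to 8-bit depth so the PNG serialization round-trips losslessly.
#'
#' @param dicom_path path to a single-slice DICOM file.
#' @param side target side length (default 224).
#' @param label optional integer class label (NA when unknown at ingestion).
#' @return a [labeled_image()].
#' @export
convert_dicom <- function(dicom_path, side = 224L, label = NA_integer_) {
  dcm <- read_dicom(dicom_path)
  labeled_image(standardize_image(dcm$pixels, side), label, dicom_path)
}
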