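# Image and manifest I/O: PNG read/write, CSV manifests
# (`path,label,collection`), and the batch preprocessing driver that ties
# conversion, cleaning and splitting together.

#' Read an image file into a labeled image
#'
#' PNG files are read directly (color images are collapsed to grayscale by
#' channel averaging); DICOM files go through [convert_dicom()].
#'
#' @param path PNG or DICOM file path.
#' @param side standardized side length.
#' @param label optional integer class label.
#' @return a [labeled_image()].
#' @export
read_image <- function(path, side = 224L, label = NA_integer_) {
  ext <- tolower(file_ext(path))
  if (ext %in% c("dcm", "dicom") || ext == "")
    return(convert_dicom(path, side, label))
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- apply(px[, , 1:3, drop = FALSE], c(1, 2), mean)
  labeled_image(standardize_image(px, side), label, path)
}

#' Write a labeled image as 8-bit PNG
#'
#' @param image a [labeled_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image$pixels, path)
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with columns `path,label` and optionally
#' `collection`, one image file per row.
#'
#' @param path manifest CSV path.
#' @param side standardized side length for loaded images.
#' @param base_dir directory against which relative manifest paths are
#'   resolved (default: the manifest's directory).
#' @return list of [labeled_image()] objects.
#' @export
read_manifest <- function(path, side = 224L, base_dir = dirname(path)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(df)))
    stop("manifest must have columns 'path' and 'label'")
  lapply(seq_len(nrow(df)), function(i) {
    p <- df$path[i]
    if (!file.exists(p)) p <- file.path(base_dir, df$path[i])
    read_image(p, side, df$label[i])
  })
}

#' Preprocess a raw image corpus
#'
#' Runs the full ingestion pipeline on a manifest: standardize every image,
#' exclude outliers with the IQR fence on per-image mean and variance, split
#' the survivors into database and query sides with stratified sampling, and
#' write standardized PNGs, a cleaned manifest (original columns plus `kept`
#' and `split`) and a JSON stats file.
#'
#' @param manifest_path CSV manifest (`path,label[,collection]`).
#' @param out_dir output directory.
#' @param side standardized side length.
#' @param iqr_factor IQR fence multiplier.
#' @param ratio database-side split fraction.
#' @param seed split seed.
#' @return list with `database`, `query`, `removed`, and `out_dir`,
#'   invisibly.
#' @export
preprocess_dataset <- function(manifest_path, out_dir, side = 224L,
                               iqr_factor = 1.5, ratio = 0.8, seed = 1L) {
  dir.create(file.path(out_dir, "png"), recursive = TRUE, showWarnings = FALSE)
  df <- read.csv(manifest_path, stringsAsFactors = FALSE)
  images <- read_manifest(manifest_path, side)
  cl <- iqr_clean(images, iqr_factor)
  sp <- stratified_split(cl$kept, ratio, seed)
  split_of <- c(setNames(rep("database", length(sp$database)),
                         vapply(sp$database, `[[`, "", "source_id")),
                setNames(rep("query", length(sp$query)),
                         vapply(sp$query, `[[`, "", "source_id")))
  ids <- vapply(images, `[[`, "", "source_id")
  df$kept <- cl$kept_mask
  df$split <- ifelse(df$kept, split_of[ids], "excluded")
  out_png <- character(nrow(df))
  for (i in seq_along(images)) {
    out_png[i] <- file.path(out_dir, "png",
                            paste0(sprintf("img_%05d", i), ".png"))
    write_image_png(images[[i]], out_png[i])
  }
  df$standardized_path <- out_png
  write.csv(df, file.path(out_dir, "manifest_clean.csv"), row.names = FALSE)
  st <- cl$stats
  jsonlite::write_json(list(per_image = st$per_image, corpus = st$corpus),
                       file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(database = sp$database, query = sp$query,
                 removed = cl$removed, out_dir = out_dir))
}
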