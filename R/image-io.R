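#' Plate image container
#'
#' An RGB raster of a seed plate together with its illumination mode and an
#' optional pixel scale. Pixels are stored as an `H x W x 3` integer array
#' (red, green, blue; values 0-255, row = image row from the top).
#'
#' @param pixels `H x W x 3` numeric array with values in 0-255, or an
#'   `H x W` matrix (replicated across the three channels).
#' @param mode Illumination mode: `"FLUO"` (fluorescent, 400-500 nm
#'   excitation, signal mainly in the red channel), `"VISBACK"` (visible
#'   back-lit) or `"VISFRONT"` (visible top-lit).
#' @param id Plate label (barcode); free text.
#' @param px_per_cm Optional positive scale in pixels per centimetre.
#' @return An object of class `plate_image`.
#' @export
plate_image <- function(pixels, mode = c("FLUO", "VISBACK", "VISFRONT"),
                        id = "plate", px_per_cm = NULL) {
  mode <- match.arg(mode)
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort("`pixels` must be an H x W x 3 array or an H x W matrix.",
          class = "seedsalt_input_error")
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    abort("Image must have at least one row and one column.",
          class = "seedsalt_input_error")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    abort("Channel values must lie in [0, 255] with no missing values.",
          class = "seedsalt_input_error")
  }
  if (!is.null(px_per_cm)) {
    stopifnot(is.numeric(px_per_cm), length(px_per_cm) == 1L, px_per_cm > 0)
  }
  structure(
    list(id = as.character(id), pixels = round(pixels), mode = mode,
         px_per_cm = px_per_cm),
    class = "plate_image"
  )
}

#' @export
print.plate_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<plate_image> id=%s mode=%s %dx%d px%s\n", x$id, x$mode,
              d[1], d[2],
              if (is.null(x$px_per_cm)) "" else
                sprintf(" (%.2f px/cm)", x$px_per_cm)))
  invisible(x)
}

image_format_from_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = "png",
    tif = , tiff = "tiff",
    jpg = , jpeg = "jpeg",
    abort(sprintf("Unsupported image format '%s' for '%s'.", ext, path),
          class = "seedsalt_input_error")
  )
}

#' Load a plate image from disk
#'
#' Reads a PNG, TIFF or JPEG file into a [plate_image]. Greyscale sources
#' are replicated across the three channels; 16-bit sources are rescaled to
#' 0-255 by `floor(v / 257)`; an alpha channel, if present, is dropped.
#'
#' @param path Path to an image file.
#' @inheritParams plate_image
#' @param id Plate label; defaults to the file stem.
#' @return A [plate_image].
#' @export
load_image <- function(path, mode = c("FLUO", "VISBACK", "VISFRONT"),
                       id = NULL, px_per_cm = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) {
    abort(sprintf("Image file '%s' does not exist.", path),
          class = "seedsalt_input_error")
  }
  fmt <- image_format_from_path(path)
  raw <- tryCatch(
    switch(fmt,
      png = png::readPNG(path, info = TRUE),
      tiff = tiff::readTIFF(path, info = TRUE),
      jpeg = jpeg::readJPEG(path)
    ),
    error = function(e) {
      abort(sprintf("Could not decode image '%s': %s", path,
                    conditionMessage(e)),
            class = "seedsalt_input_error")
    }
  )
  depth <- 8L
  if (fmt == "png") {
    info <- attr(raw, "info")
    if (!is.null(info$bit.depth)) depth <- as.integer(info$bit.depth)
  } else if (fmt == "tiff") {
    bps <- attr(raw, "bits.per.sample")
    if (!is.null(bps)) depth <- as.integer(bps[1])
  }
  raw <- unclass(raw)
  if (length(dim(raw)) == 2L) raw <- array(raw, dim = c(dim(raw), 1L))
  if (dim(raw)[3] >= 3L) raw <- raw[, , 1:3, drop = FALSE] else
    raw <- array(rep(raw[, , 1L], 3L), dim = c(dim(raw)[1:2], 3L))
  # readers return values in [0,1]; recover the integer code, then rescale
  # 16-bit content to 0-255 by integer division (floor(v16 / 257))
  codes <- round(raw * (2^depth - 1))
  pixels <- if (depth > 8L) floor(codes / 257) else codes
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  plate_image(pixels, mode = mode, id = id, px_per_cm = px_per_cm)
}

#' Write a plate image to disk
#'
#' Companion to [load_image()]; mainly used by the simulation CLI and the
#' test-suite roundtrips. Format follows the file extension.
#'
#' @param image A [plate_image].
#' @param path Output path (`.png`, `.tif`/`.tiff` or `.jpg`/`.jpeg`).
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  stopifnot(inherits(image, "plate_image"))
  fmt <- image_format_from_path(path)
  arr <- image$pixels / 255
  switch(fmt,
    png = png::writePNG(arr, path),
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    jpeg = jpeg::writeJPEG(arr, path, quality = 1)
  )
  invisible(path)
}

#' Write a 16-bit label raster
#'
#' Stores a segmentation label matrix losslessly as an RGB PNG with the
#' 16-bit label packed into two 8-bit channels (red = high byte, green =
#' low byte; label 0 = background). This is the format written by
#' `seedsalt segment`.
#'
#' @param labels Integer matrix of region labels (0-65535).
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
save_label_raster <- function(labels, path) {
  stopifnot(is.matrix(labels), max(labels) <= 65535, min(labels) >= 0)
  arr <- array(0, dim = c(dim(labels), 3L))
  arr[, , 1] <- (labels %/% 256) / 255
  arr[, , 2] <- (labels %% 256) / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' Read a label raster written by [save_label_raster()]
#'
#' @param path Path to the label PNG.
#' @return Integer matrix of region labels.
#' @export
load_label_raster <- function(path) {
  raw <- png::readPNG(path)
  stopifnot(length(dim(raw)) == 3L, dim(raw)[3] >= 2L)
  hi <- round(raw[, , 1] * 255)
  lo <- round(raw[, , 2] * 255)
  matrix(as.integer(hi * 256 + lo), nrow = dim(raw)[1])
}

#' Write a per-seed feature table to CSV
#'
#' One row per seed with the `plate` and `id` columns followed by the 7
#' morphological and 16 colorimetric feature identifiers (and `condition`
#' when present). RFC-4180 quoting; numeric columns are written with 6
#' decimals.
#'
#' @param records Tibble of seed records, e.g. from [extract_plate_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(records, path) {
  cols <- c("plate", "id", ALL_FEATURES)
  if (!all(cols %in% names(records)) && nrow(records) > 0) {
    missing <- setdiff(cols, names(records))
    abort(paste0("Feature table is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "seedsalt_input_error")
  }
  if (nrow(records) == 0) {
    out <- as.data.frame(setNames(rep(list(character()), length(cols)), cols))
  } else {
    if ("condition" %in% names(records)) cols <- c(cols, "condition")
    out <- as.data.frame(records[, cols])
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(x) formatC(x, digits = 6,
                                                     format = "f"))
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a feature CSV written by [write_feature_csv()]
#'
#' @param path Path to the CSV.
#' @return Tibble of seed records.
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Feature CSV '%s' does not exist.", path),
          class = "seedsalt_input_error")
  }
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in intersect(ALL_FEATURES, names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if ("id" %in% names(df)) df$id <- as.integer(df$id)
  as_tibble(df)
}
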