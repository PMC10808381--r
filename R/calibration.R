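#' Pixel-to-metric calibration from the dish diameter
#'
#' The pixel scale is set by measuring a known physical length in the
#' image, typically the inside diameter of the petri dish (8.50 cm for the
#' standard plates). The scale is kept at full precision internally;
#' [format_scale()] reproduces the truncated 2-decimal display.
#'
#' @param diameter_px Measured length in pixels (> 0).
#' @param diameter_cm The same length in centimetres (> 0).
#' @param source Free-text provenance of the measurement.
#' @return An object of class `scale_calibration` with element `px_per_cm`.
#' @export
#' @examples
#' pixels_per_cm(846.50, 8.50)  # the fluorescent-camera dish measurement
pixels_per_cm <- function(diameter_px, diameter_cm,
                          source = "dish inner diameter") {
  stopifnot(is.numeric(diameter_px), diameter_px > 0,
            is.numeric(diameter_cm), diameter_cm > 0)
  structure(
    list(px_per_cm = diameter_px / diameter_cm, source = as.character(source)),
    class = "scale_calibration"
  )
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("<scale_calibration> %s px/cm (%s)\n", format_scale(x),
              x$source))
  invisible(x)
}

#' Truncated 2-decimal display of a pixel scale
#'
#' @param cal A [pixels_per_cm()] calibration (or a bare number).
#' @return Character scalar, e.g. `"99.58"`.
#' @export
format_scale <- function(cal) {
  v <- if (inherits(cal, "scale_calibration")) cal$px_per_cm else cal
  sprintf("%.2f", trunc(v * 100) / 100)
}

#' Seed length and width in millimetres
#'
#' Twice the major and minor semi-axes serve as proxies for seed length
#' and width; the calibration converts pixels to millimetres.
#'
#' @param features One-row tibble (or data frame) with `major` and `minor`
#'   columns in pixels, e.g. from [morphological_features()].
#' @param cal A [pixels_per_cm()] calibration.
#' @return Tibble with `length_mm` and `width_mm`.
#' @export
#' @examples
#' cal <- pixels_per_cm(1812, 8.50)
#' seed_dimensions(data.frame(major = 21.75, minor = 10.83), cal)
seed_dimensions <- function(features, cal) {
  stopifnot(inherits(cal, "scale_calibration"))
  tibble(
    length_mm = 2 * features$major / cal$px_per_cm * 10,
    width_mm = 2 * features$minor / cal$px_per_cm * 10
  )
}

#' Plate-level phenotype summary
#'
#' Seed count and arithmetic means of size, length, width and circularity
#' for one plate. Metric columns are reported only when a calibration is
#' supplied; means are `NA` for an empty plate.
#'
#' @param records Seed-record tibble of one plate
#'   (from [extract_plate_table()]).
#' @param cal Optional [pixels_per_cm()] calibration.
#' @return One-row tibble: `plate`, `n_seeds`, `mean_area_px`,
#'   `mean_circularity`, and with a calibration also `mean_area_mm2`,
#'   `mean_length_mm`, `mean_width_mm`.
#' @export
plate_summary <- function(records, cal = NULL) {
  n <- nrow(records)
  plate <- if (n > 0) records$plate[1] else NA_character_
  out <- tibble(
    plate = plate,
    n_seeds = n,
    mean_area_px = if (n > 0) mean(records$area) else NA_real_,
    mean_circularity = if (n > 0) mean(records$circularity) else NA_real_
  )
  if (!is.null(cal)) {
    stopifnot(inherits(cal, "scale_calibration"))
    k <- cal$px_per_cm
    out$mean_area_mm2 <- if (n > 0) mean(records$area) / k^2 * 100 else
      NA_real_
    out$mean_length_mm <- if (n > 0) mean(2 * records$major / k * 10) else
      NA_real_
    out$mean_width_mm <- if (n > 0) mean(2 * records$minor / k * 10) else
      NA_real_
  }
  out
}

#' Summaries for a multi-plate feature table
#'
#' @param records Seed records possibly spanning several plates.
#' @inheritParams plate_summary
#' @return One row per plate, via [plate_summary()].
#' @export
plate_summaries <- function(records, cal = NULL) {
  records |>
    dplyr::group_by(.data$plate) |>
    dplyr::group_split() |>
    purrr::map(plate_summary, cal = cal) |>
    dplyr::bind_rows()
}
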