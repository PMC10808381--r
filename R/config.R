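#' Seed detection setup
#'
#' The reusable segmentation configuration: which channel to threshold, the
#' threshold itself (a fixed 0-255 value or `"otsu"` for automatic
#' selection by exhaustive between-class variance maximization), the
#' polarity of the objects relative to the background, an area gate that
#' rejects debris and plate-rim artifacts, and an optional circular region
#' of interest restricting the search to the dish.
#'
#' @param mode Preset name the config derives from (free text).
#' @param channel Channel to threshold: `"red"`, `"green"`, `"blue"` or
#'   `"grey"` (rounded mean of the three).
#' @param threshold Integer 0-255, or `"otsu"`.
#' @param polarity `"bright_objects"` (foreground >= threshold) or
#'   `"dark_objects"` (foreground <= threshold).
#' @param min_area,max_area Region area gate, in pixels.
#' @param roi Optional circular region of interest: numeric
#'   `c(row, col, radius)` in pixels.
#' @param px_per_cm Optional positive scale in pixels per centimetre.
#' @return An object of class `seg_config`.
#' @export
#' @examples
#' seg_config(channel = "red", threshold = 60, min_area = 30)
seg_config <- function(mode = "custom",
                       channel = c("grey", "red", "green", "blue"),
                       threshold = "otsu",
                       polarity = c("bright_objects", "dark_objects"),
                       min_area = 0, max_area = Inf,
                       roi = NULL, px_per_cm = NULL) {
  channel <- match.arg(channel)
  polarity <- match.arg(polarity)
  cfg <- structure(
    list(mode = as.character(mode), channel = channel, threshold = threshold,
         polarity = polarity, min_area = min_area, max_area = max_area,
         roi = roi, px_per_cm = px_per_cm),
    class = "seg_config"
  )
  validate_seg_config(cfg)
}

validate_seg_config <- function(cfg) {
  bad <- character()
  thr <- cfg$threshold
  if (is.character(thr)) {
    if (!identical(thr, "otsu")) bad <- c(bad, "threshold")
  } else if (!is.numeric(thr) || length(thr) != 1L || is.na(thr) ||
             thr < 0 || thr > 255) {
    bad <- c(bad, "threshold")
  }
  if (!is.numeric(cfg$min_area) || cfg$min_area < 0) bad <- c(bad, "min_area")
  if (!is.numeric(cfg$max_area) || cfg$max_area < cfg$min_area) {
    bad <- c(bad, "max_area")
  }
  if (!is.null(cfg$roi)) {
    roi <- cfg$roi
    if (!is.numeric(roi) || length(roi) != 3L || roi[3] <= 0) {
      bad <- c(bad, "roi")
    }
  }
  if (!is.null(cfg$px_per_cm) &&
      (!is.numeric(cfg$px_per_cm) || cfg$px_per_cm <= 0)) {
    bad <- c(bad, "px_per_cm")
  }
  if (length(bad)) {
    abort(paste0("Invalid segmentation config field(s): ",
                 paste(unique(bad), collapse = ", ")),
          class = "seedsalt_config_error")
  }
  cfg
}

#' @export
print.seg_config <- function(x, ...) {
  cat(sprintf(
    "<seg_config> mode=%s channel=%s threshold=%s polarity=%s area=[%s, %s]%s\n",
    x$mode, x$channel, as.character(x$threshold), x$polarity,
    format(x$min_area), format(x$max_area),
    if (is.null(x$roi)) "" else sprintf(" roi=(%g,%g,r=%g)", x$roi[1],
                                        x$roi[2], x$roi[3])))
  invisible(x)
}

CONFIG_FIELDS <- c("version", "mode", "channel", "threshold", "polarity",
                   "min_area", "max_area", "roi", "px_per_cm")

#' Built-in detection presets
#'
#' One preset per illumination mode. `FLUO` thresholds the red channel
#' (the fluorescent signal is concentrated there) for bright objects on a
#' dark background; `VISBACK` looks for dark objects on the back-lit
#' bright dish; `VISFRONT` for bright top-lit seeds on a mid-grey
#' background. All three select the threshold automatically by Otsu's
#' criterion and gate regions to 30-5000 px, which rejects specks and the
#' dark dish surround of back-lit images. The numeric values are package
#' defaults chosen for the bundled plate simulator; real imaging setups
#' should start from a preset and adjust via [seg_config()].
#'
#' @param name Preset name, case-insensitive: `"FLUO"`, `"VISBACK"` or
#'   `"VISFRONT"`.
#' @return A [seg_config()].
#' @export
#' @examples
#' preset_config("FLUO")
preset_config <- function(name) {
  key <- toupper(as.character(name)[1])
  switch(key,
    FLUO = seg_config(mode = "FLUO", channel = "red", threshold = "otsu",
                      polarity = "bright_objects", min_area = 30,
                      max_area = 5000, px_per_cm = 99.58),
    VISBACK = seg_config(mode = "VISBACK", channel = "grey",
                         threshold = "otsu", polarity = "dark_objects",
                         min_area = 30, max_area = 5000,
                         px_per_cm = 213.17),
    VISFRONT = seg_config(mode = "VISFRONT", channel = "grey",
                          threshold = "otsu", polarity = "bright_objects",
                          min_area = 30, max_area = 5000),
    abort(sprintf("Unknown preset '%s' (expected FLUO, VISBACK or VISFRONT).",
                  name),
          class = "seedsalt_config_error")
  )
}

#' Save a detection setup as JSON
#'
#' The configuration is versioned so that saved setups can be reused in
#' later analyses.
#'
#' @param config A [seg_config()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "seg_config"))
  obj <- list(version = 1L, mode = config$mode, channel = config$channel,
              threshold = config$threshold, polarity = config$polarity,
              min_area = config$min_area, max_area = config$max_area)
  if (!is.null(config$roi)) {
    obj$roi <- list(row = config$roi[1], col = config$roi[2],
                    radius = config$roi[3])
  }
  if (!is.null(config$px_per_cm)) obj$px_per_cm <- config$px_per_cm
  if (is.infinite(obj$max_area)) obj$max_area <- "Inf"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a detection setup from JSON
#'
#' @param path Path to a JSON file written by [save_config()], or a preset
#'   name (`"FLUO"`, `"VISBACK"`, `"VISFRONT"`).
#' @return A [seg_config()].
#' @export
load_config <- function(path) {
  if (toupper(path) %in% c("FLUO", "VISBACK", "VISFRONT")) {
    return(preset_config(path))
  }
  if (!file.exists(path)) {
    abort(sprintf("Config file '%s' does not exist.", path),
          class = "seedsalt_config_error")
  }
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    abort(sprintf("Could not parse config '%s': %s", path,
                                  conditionMessage(e)),
                          class = "seedsalt_config_error")
                  })
  unknown <- setdiff(names(obj), CONFIG_FIELDS)
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "seedsalt_config_error")
  }
  required <- c("mode", "channel", "threshold", "polarity", "min_area",
                "max_area")
  missing <- setdiff(required, names(obj))
  if (length(missing)) {
    abort(paste0("Config is missing required key(s): ",
                 paste(missing, collapse = ", ")),
          class = "seedsalt_config_error")
  }
  if (identical(obj$max_area, "Inf")) obj$max_area <- Inf
  roi <- NULL
  if (!is.null(obj$roi)) {
    roi <- c(obj$roi$row, obj$roi$col, obj$roi$radius)
  }
  seg_config(mode = obj$mode, channel = obj$channel,
             threshold = obj$threshold, polarity = obj$polarity,
             min_area = obj$min_area, max_area = obj$max_area,
             roi = roi, px_per_cm = obj$px_per_cm)
}
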