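channel_matrix <- function(image, channel) {
  px <- image$pixels
  switch(channel,
    red = px[, , 1],
    green = px[, , 2],
    blue = px[, , 3],
    grey = round((px[, , 1] + px[, , 2] + px[, , 3]) / 3)
  )
}

roi_mask <- function(dim_hw, roi) {
  if (is.null(roi)) return(NULL)
  rows <- matrix(seq_len(dim_hw[1]), dim_hw[1], dim_hw[2])
  cols <- matrix(seq_len(dim_hw[2]), dim_hw[1], dim_hw[2], byrow = TRUE)
  (rows - roi[1])^2 + (cols - roi[2])^2 <= roi[3]^2
}

#' Otsu threshold by exhaustive between-class variance maximization
#'
#' Scans every candidate boundary `t` in 0-255, splitting values into a
#' dark class `< t` and a bright class `>= t`, and returns the smallest
#' `t` maximizing the between-class variance
#' `w_dark * w_bright * (mu_dark - mu_bright)^2`.
#'
#' @param values Integer vector (or matrix) of channel values in 0-255.
#' @return The boundary `t`: bright foreground is `value >= t`, dark
#'   foreground is `value <= t - 1`. A degenerate single-valued histogram
#'   has no split; `0` is returned and [binarize()] treats the image as
#'   all background.
#' @export
otsu_threshold <- function(values) {
  v <- as.integer(values)
  counts <- tabulate(v + 1L, nbins = 256L)
  n <- sum(counts)
  if (n == 0) abort("No pixels to threshold.", class = "seedsalt_input_error")
  lv <- 0:255
  csum <- cumsum(counts)            # csum[t] = # values <= t-1 ... careful
  cmoment <- cumsum(counts * lv)
  total <- cmoment[256]
  best <- -1; best_t <- 0L
  for (t in 1:255) {
    n0 <- csum[t]                   # values < t (i.e. <= t-1)
    if (n0 == 0 || n0 == n) next
    m0 <- cmoment[t] / n0
    m1 <- (total - cmoment[t]) / (n - n0)
    bc <- (n0 / n) * ((n - n0) / n) * (m0 - m1)^2
    if (bc > best + 1e-12) { best <- bc; best_t <- t }
  }
  best_t
}

#' Binarize a plate image
#'
#' Thresholds the configured channel: a pixel is foreground iff its value
#' is `>= threshold` (`bright_objects`) or `<= threshold`
#' (`dark_objects`). With `threshold = "otsu"` the boundary is chosen by
#' [otsu_threshold()] over the (ROI-restricted) channel histogram; bright
#' foreground is then `>= t` and dark foreground `<= t - 1`, so the two
#' polarities partition the same Otsu split. Pixels outside the ROI circle
#' are always background.
#'
#' @param image A [plate_image].
#' @param config A [seg_config()].
#' @return Logical `H x W` matrix (`TRUE` = candidate seed pixel).
#' @export
binarize <- function(image, config) {
  stopifnot(inherits(image, "plate_image"), inherits(config, "seg_config"))
  ch <- channel_matrix(image, config$channel)
  inside <- roi_mask(dim(ch), config$roi)
  if (identical(config$threshold, "otsu")) {
    vals <- if (is.null(inside)) ch else ch[inside]
    t <- otsu_threshold(vals)
    mask <- if (t == 0L) {
      matrix(FALSE, nrow(ch), ncol(ch))  # constant image: nothing to split
    } else if (config$polarity == "bright_objects") ch >= t else ch <= t - 1
  } else {
    t <- config$threshold
    mask <- if (config$polarity == "bright_objects") ch >= t else ch <= t
  }
  if (!is.null(inside)) mask <- mask & inside
  mask
}

region_from_label <- function(labels, contour, lab) {
  idx <- which(labels == lab, arr.ind = TRUE)
  colnames(idx) <- c("row", "col")
  centroid <- c(row = mean(idx[, 1]), col = mean(idx[, 2]))
  bbox <- c(min(idx[, 1]), min(idx[, 2]), max(idx[, 1]), max(idx[, 2]))
  structure(
    list(label = lab, pixels = idx, outer_contour = contour,
         centroid = centroid, bbox = bbox, area = nrow(idx)),
    class = "seed_region"
  )
}

#' @export
print.seed_region <- function(x, ...) {
  cat(sprintf("<seed_region> label=%d area=%d centroid=(%.1f, %.1f)\n",
              x$label, x$area, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Label connected regions by combined contour tracing
#'
#' Identifies every 8-connected foreground component of a binary mask in a
#' single raster scan: each first-met boundary pixel launches a
#' Moore-neighbourhood contour trace (outer contours clockwise in image
#' coordinates), hole boundaries are traced and marked so they never seed
#' spurious components, and interior pixels inherit the label of their
#' left neighbour. Labels are consecutive from 1 in scan order.
#'
#' @param mask Logical `H x W` matrix.
#' @return List of `seed_region` objects, each holding the pixel set, the
#'   closed outer contour, centroid, bounding box and area.
#' @export
label_regions <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  res <- .label_regions_cpp(mask)
  labs <- res$labels
  n <- length(res$contours)
  lapply(seq_len(n), function(i) {
    region_from_label(labs, res$contours[[i]], i)
  })
}

#' Label matrix of a region list
#'
#' @param regions List of `seed_region`s.
#' @param dim_hw Integer `c(H, W)` of the source mask.
#' @return Integer matrix with each region's label painted on its pixels.
#' @export
regions_to_labels <- function(regions, dim_hw) {
  out <- matrix(0L, dim_hw[1], dim_hw[2])
  for (rg in regions) out[rg$pixels] <- rg$label
  out
}

#' Filter labeled regions by the detection setup
#'
#' Keeps regions whose area lies within `[min_area, max_area]` and, when an
#' ROI is configured, whose centroid falls inside the ROI circle.
#' Survivors are relabeled consecutively from 1, preserving scan order.
#'
#' @param regions List of `seed_region`s from [label_regions()].
#' @param config A [seg_config()].
#' @return Filtered, relabeled list of `seed_region`s.
#' @export
filter_regions <- function(regions, config) {
  stopifnot(inherits(config, "seg_config"))
  keep <- vapply(regions, function(rg) {
    ok <- rg$area >= config$min_area && rg$area <= config$max_area
    if (ok && !is.null(config$roi)) {
      d2 <- (rg$centroid[1] - config$roi[1])^2 +
        (rg$centroid[2] - config$roi[2])^2
      ok <- d2 <= config$roi[3]^2
    }
    ok
  }, logical(1))
  out <- regions[keep]
  for (i in seq_along(out)) out[[i]]$label <- i
  out
}

#' Segment a plate image
#'
#' The full detection chain: [binarize()], [label_regions()],
#' [filter_regions()].
#'
#' @inheritParams binarize
#' @return List of `seed_region`s, one per detected seed.
#' @export
segment_plate <- function(image, config) {
  filter_regions(label_regions(binarize(image, config)), config)
}

#' Count detected objects
#'
#' Runs the detection chain and returns the number of surviving regions.
#' With a suitable setup this counts seeds on a plate or, with adjusted
#' thresholds and area gates, other objects such as seed pods in side-view
#' plant images.
#'
#' @inheritParams binarize
#' @return Integer count.
#' @export
count_objects <- function(image, config) {
  length(segment_plate(image, config))
}
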