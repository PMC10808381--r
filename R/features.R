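# Fill holes: a seed is the interior of its outer contour, so background
# pockets (glare holes in back-lit images) enclosed by the region are
# assigned to it. BFS from the bounding-box frame over 4-connected
# background; anything unreached is a hole.
fill_region_holes <- function(region) {
  bb <- region$bbox
  h <- bb[3] - bb[1] + 1L
  w <- bb[4] - bb[2] + 1L
  if (h * w == region$area) return(region$pixels)
  inside <- matrix(FALSE, h + 2L, w + 2L)
  inside[cbind(region$pixels[, 1] - bb[1] + 2L,
               region$pixels[, 2] - bb[2] + 2L)] <- TRUE
  outside <- matrix(FALSE, h + 2L, w + 2L)
  # seed the BFS with the padding frame
  frontier <- which(
    (row(inside) %in% c(1L, h + 2L) | col(inside) %in% c(1L, w + 2L)) &
      !inside
  )
  outside[frontier] <- TRUE
  nr <- h + 2L
  steps <- c(-1L, 1L, -nr, nr)
  # column-end wrap-around of the +/-1 steps always lands on frame cells
  # (rows 1 and h+2), which are already marked outside, so it is harmless
  while (length(frontier)) {
    nbr <- unique(as.vector(outer(frontier, steps, `+`)))
    nbr <- nbr[nbr >= 1L & nbr <= length(inside)]
    nbr <- nbr[!inside[nbr] & !outside[nbr]]
    outside[nbr] <- TRUE
    frontier <- nbr
  }
  filled <- which(!outside, arr.ind = TRUE)
  filled <- cbind(row = filled[, 1] + bb[1] - 2L,
                  col = filled[, 2] + bb[2] - 2L)
  colnames(filled) <- c("row", "col")
  filled
}

contour_length <- function(contour) {
  n <- nrow(contour)
  if (n < 2) return(0)
  nxt <- rbind(contour[-1, , drop = FALSE], contour[1, , drop = FALSE])
  d <- abs(nxt - contour)
  sum(ifelse(d[, 1] + d[, 2] == 2, sqrt(2), 1))
}

#' Morphological features of a seed region
#'
#' The 7 shape descriptors computed per seed: `area` (pixel count of the
#' hole-filled region), `perimeter` (polygonal length of the closed outer
#' contour through pixel centres: 1 per axial step, sqrt(2) per diagonal),
#' `circularity` (perimeter^2 / area), `compactness` (area / perimeter),
#' `major` and `minor` (semi-axis lengths `2 * sqrt(lambda)` from the
#' eigenvalues of the second central moment matrix of the pixel
#' coordinates, so a solid ellipse with semi-axes a >= b yields
#' `major ~ a`), and `eccentricity` (major / minor, >= 1). Degenerate
#' single-row or single-column regions have the minor axis floored at
#' 0.5 px.
#'
#' @param region A `seed_region` from [label_regions()].
#' @return One-row tibble with the 7 feature columns.
#' @export
morphological_features <- function(region) {
  stopifnot(inherits(region, "seed_region"))
  if (region$area < 1) {
    abort("Empty region.", class = "seedsalt_input_error")
  }
  px <- fill_region_holes(region)
  area <- nrow(px)
  perimeter <- contour_length(region$outer_contour)
  r <- px[, 1] - mean(px[, 1])
  c_ <- px[, 2] - mean(px[, 2])
  mu <- matrix(c(mean(r * r), mean(r * c_), mean(r * c_), mean(c_ * c_)), 2)
  ev <- sort(eigen(mu, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  major <- max(2 * sqrt(max(ev[1], 0)), 0.5)
  minor <- max(2 * sqrt(max(ev[2], 0)), 0.5)
  tibble(
    area = area,
    perimeter = perimeter,
    circularity = perimeter^2 / area,
    compactness = if (perimeter > 0) area / perimeter else NA_real_,
    major = major,
    minor = minor,
    eccentricity = major / minor
  )
}

rgb_to_hue <- function(r, g, b) {
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- mx - mn
  h <- numeric(length(r))
  i <- d > 0 & mx == r
  h[i] <- ((g[i] - b[i]) / d[i]) %% 6
  i <- d > 0 & mx == g & mx != r
  h[i] <- (b[i] - r[i]) / d[i] + 2
  i <- d > 0 & mx == b & mx != r & mx != g
  h[i] <- (r[i] - g[i]) / d[i] + 4
  (h * 60) %% 360
}

hue_class_max <- function(hue, k) {
  bin <- pmin(floor(hue * k / 360), k - 1)
  counts <- tabulate(bin + 1L, nbins = k)
  which.max(counts) - 1L  # which.max takes the smallest index on ties
}

#' Colorimetric features of a seed region
#'
#' The 16 colour descriptors computed over the (hole-filled) pixel set of
#' a seed: the grey-histogram peak `hisgreypeak` (0-255 bin of the rounded
#' grey value `(R+G+B)/3` with maximal count, smallest bin on ties),
#' quartiles of the grey and of each channel's pixel-value distribution
#' (linear interpolation between closest order statistics), and the most
#' populated hue class among 16, 32 and 64 equal divisions of the HSB hue
#' circle (hue in degrees `[0, 360)`, zero-saturation pixels assigned hue
#' 0, floor binning, smallest index on ties).
#'
#' @param region A `seed_region`.
#' @param image The [plate_image] the region was segmented from.
#' @return One-row tibble with the 16 feature columns.
#' @export
colorimetric_features <- function(region, image) {
  stopifnot(inherits(region, "seed_region"), inherits(image, "plate_image"))
  d <- dim(image$pixels)
  px <- fill_region_holes(region)
  if (min(px) < 1 || max(px[, 1]) > d[1] || max(px[, 2]) > d[2]) {
    abort("Region lies outside the image raster.",
          class = "seedsalt_input_error")
  }
  r <- image$pixels[cbind(px[, 1], px[, 2], 1L)]
  g <- image$pixels[cbind(px[, 1], px[, 2], 2L)]
  b <- image$pixels[cbind(px[, 1], px[, 2], 3L)]
  grey <- (r + g + b) / 3
  grey_counts <- tabulate(floor(grey + 0.5) + 1L, nbins = 256L)
  q <- function(x) unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  qg <- q(grey); qr <- q(r); qgr <- q(g); qb <- q(b)
  hue <- rgb_to_hue(r, g, b)
  tibble(
    hisgreypeak = which.max(grey_counts) - 1L,
    q1grey = qg[1], q2grey = qg[2], q3grey = qg[3],
    q1r = qr[1], q2r = qr[2], q3r = qr[3],
    q1g = qgr[1], q2g = qgr[2], q3g = qgr[3],
    q1b = qb[1], q2b = qb[2], q3b = qb[3],
    hue16max = hue_class_max(hue, 16L),
    hue32max = hue_class_max(hue, 32L),
    hue64max = hue_class_max(hue, 64L)
  )
}

#' Extract the per-seed feature table of a plate
#'
#' Segments the plate ([segment_plate()]) and computes the 7 morphological
#' and 16 colorimetric features for every detected seed, ordered by label.
#'
#' @inheritParams binarize
#' @return Tibble with columns `plate`, `id` and the 23 features; zero
#'   rows for a blank plate.
#' @export
#' @examples
#' plate <- generate_plate(plate_spec("FLUO", n_seeds = 5, image_size = 220,
#'                                    dish_radius = 100, seed = 1))
#' extract_plate_table(plate$image, preset_config("FLUO"))
extract_plate_table <- function(image, config) {
  regions <- segment_plate(image, config)
  if (length(regions) == 0) {
    return(vctrs_empty_features(tibble(plate = character(), id = integer())))
  }
  feats <- purrr::map(regions, function(rg) {
    dplyr::bind_cols(
      tibble(plate = image$id, id = rg$label),
      morphological_features(rg),
      colorimetric_features(rg, image)
    )
  })
  dplyr::bind_rows(feats)
}

vctrs_empty_features <- function(base) {
  for (col in ALL_FEATURES) base[[col]] <- numeric()
  base
}
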