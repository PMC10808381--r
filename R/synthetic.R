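mode_defaults <- function(mode, condition) {
  # Class-dependent shifts follow the fluorescent-camera observations:
  # salt-grown seeds are larger (+30% semi-major axis) and brighter in the
  # red channel (+40 on the seed-mean red intensity); back-lit and top-lit
  # defaults carry no class effect, where no consistent pattern exists.
  salt <- identical(condition, "salt")
  base <- list(
    axis_mean = 9.8, axis_sd = 1.0,
    aspect_mean = 1.9, aspect_sd = 0.15,
    noise_sd = 6
  )
  cols <- switch(mode,
    FLUO = list(
      seed_rgb_mean = c(if (salt) 160 else 120, 40, 2),
      seed_rgb_sd = c(15, 8, 1),
      background_rgb = c(5, 5, 5),
      surround_rgb = NULL
    ),
    VISBACK = list(
      seed_rgb_mean = c(45, 35, 30),
      seed_rgb_sd = c(8, 8, 8),
      background_rgb = c(230, 230, 230),
      surround_rgb = c(30, 30, 30)  # dark rim outside the back-lit dish
    ),
    VISFRONT = list(
      seed_rgb_mean = c(190, 165, 120),
      seed_rgb_sd = c(10, 10, 10),
      background_rgb = c(120, 120, 120),
      surround_rgb = NULL
    )
  )
  if (salt && mode == "FLUO") base$axis_mean <- base$axis_mean * 1.3
  c(base, cols)
}

#' Specification of a synthetic seed plate
#'
#' Describes one plate image to simulate: elliptical seeds scattered
#' without overlap on a circular dish, with per-seed axis lengths, aspect
#' ratios and channel intensities drawn from normal distributions, plus
#' per-pixel Gaussian noise. The defaults emulate the fluorescent imaging
#' conditions: a 900 x 900 px image of an 8.5 cm dish (423 px radius, about
#' 99.5 px/cm), 90 seeds of mean semi-major axis 9.8 px and aspect ratio
#' 1.9 (seed area near 150 px), red-dominant seed signal on a dark
#' background. Under `condition = "salt"` the FLUO defaults shift the
#' semi-major axis by +30% and the seed red mean by +40; back-lit
#' (`VISBACK`: bright dish, dark seeds, dark surround) and top-lit
#' (`VISFRONT`: mid-grey background, bright textured seeds) defaults carry
#' no class effect. Any default can be overridden through `...`.
#'
#' @param mode Illumination mode: `"FLUO"`, `"VISBACK"`, `"VISFRONT"`.
#' @param condition Plate condition label: `"non-salt"` or `"salt"`.
#' @param n_seeds Number of seeds to place (>= 0).
#' @param image_size Image side(s) in pixels, `c(H, W)` or a scalar.
#' @param dish_center Dish centre `c(row, col)`; defaults to the image
#'   centre.
#' @param dish_radius Dish radius in pixels.
#' @param seed Integer RNG seed; generation is fully deterministic.
#' @param ... Overrides for `axis_mean`, `axis_sd`, `aspect_mean`,
#'   `aspect_sd`, `seed_rgb_mean`, `seed_rgb_sd`, `background_rgb`,
#'   `surround_rgb`, `noise_sd`.
#' @return Object of class `plate_spec`.
#' @export
#' @examples
#' plate_spec("FLUO", condition = "salt", n_seeds = 20, seed = 7)
plate_spec <- function(mode = c("FLUO", "VISBACK", "VISFRONT"),
                       condition = c("non-salt", "salt"),
                       n_seeds = 90L,
                       image_size = c(900L, 900L),
                       dish_center = NULL,
                       dish_radius = 423,
                       seed = 1L, ...) {
  mode <- match.arg(mode)
  condition <- match.arg(condition)
  stopifnot(n_seeds >= 0, dish_radius > 0)
  if (length(image_size) == 1L) image_size <- c(image_size, image_size)
  if (is.null(dish_center)) dish_center <- (image_size + 1) / 2
  spec <- c(
    list(mode = mode, condition = condition, n_seeds = as.integer(n_seeds),
         image_size = as.integer(image_size), dish_center = dish_center,
         dish_radius = dish_radius, seed = as.integer(seed)),
    mode_defaults(mode, condition)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(spec))
  if (length(unknown)) {
    abort(paste0("Unknown plate_spec field(s): ",
                 paste(unknown, collapse = ", ")),
          class = "seedsalt_config_error")
  }
  spec[names(overrides)] <- overrides
  if (any(spec$seed_rgb_mean < 0 | spec$seed_rgb_mean > 255) ||
      any(spec$background_rgb < 0 | spec$background_rgb > 255)) {
    abort("Intensity means must lie in [0, 255].",
          class = "seedsalt_config_error")
  }
  structure(spec, class = "plate_spec")
}

#' @export
print.plate_spec <- function(x, ...) {
  cat(sprintf("<plate_spec> mode=%s condition=%s n_seeds=%d %dx%d seed=%d\n",
              x$mode, x$condition, x$n_seeds, x$image_size[1],
              x$image_size[2], x$seed))
  invisible(x)
}

place_seeds <- function(spec) {
  n <- spec$n_seeds
  a <- pmax(rnorm(n, spec$axis_mean, spec$axis_sd), 2)
  aspect <- pmax(rnorm(n, spec$aspect_mean, spec$aspect_sd), 1.01)
  b <- a / aspect
  theta <- runif(n, 0, pi)
  rows <- cols <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 400L * max(n, 1L)
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort(paste0("Could not place all seeds without overlap; ",
                   "use fewer or smaller seeds or a larger dish."),
            class = "seedsalt_generation_error")
    }
    i <- placed + 1L
    rmax <- spec$dish_radius - a[i] - 2
    if (rmax <= 0) {
      abort("Seeds are larger than the dish.",
            class = "seedsalt_generation_error")
    }
    rad <- rmax * sqrt(runif(1))
    ang <- runif(1, 0, 2 * pi)
    cand_r <- spec$dish_center[1] + rad * sin(ang)
    cand_c <- spec$dish_center[2] + rad * cos(ang)
    ok <- TRUE
    if (placed > 0) {
      d <- sqrt((rows[seq_len(placed)] - cand_r)^2 +
                  (cols[seq_len(placed)] - cand_c)^2)
      ok <- all(d >= a[seq_len(placed)] + a[i] + 2)
    }
    if (ok) {
      rows[i] <- cand_r
      cols[i] <- cand_c
      placed <- i
    }
  }
  tibble(seed = seq_len(n), row = rows, col = cols, a = a, b = b,
         theta = theta)
}

rasterize_ellipse <- function(truth_row, dim_hw) {
  a <- truth_row$a; b <- truth_row$b; th <- truth_row$theta
  r0 <- truth_row$row; c0 <- truth_row$col
  ext <- ceiling(a) + 1L
  rr <- max(1L, floor(r0 - ext)):min(dim_hw[1], ceiling(r0 + ext))
  cc <- max(1L, floor(c0 - ext)):min(dim_hw[2], ceiling(c0 + ext))
  dr <- matrix(rr - r0, length(rr), length(cc))
  dc <- matrix(cc - c0, length(rr), length(cc), byrow = TRUE)
  u <- dr * cos(th) + dc * sin(th)
  v <- -dr * sin(th) + dc * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(row = rr[idx[, 1]], col = cc[idx[, 2]])
}

#' Generate one synthetic plate
#'
#' Rasterizes the spec's filled ellipses onto the dish, draws per-seed
#' channel intensities and per-pixel Gaussian noise, clips to `[0, 255]`
#' and returns the image together with its ground truth. Deterministic for
#' a given `spec$seed`.
#'
#' @param spec A [plate_spec()].
#' @return Object of class `synthetic_plate`: `image` (a [plate_image]),
#'   `labels` (integer ground-truth raster), `truth` (per-seed tibble
#'   with centre, semi-axes, orientation and drawn colours) and
#'   `condition`.
#' @export
#' @examples
#' p <- generate_plate(plate_spec("FLUO", n_seeds = 10, image_size = 300,
#'                                dish_radius = 140, seed = 42))
#' p$image
generate_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  withr::with_seed(spec$seed, {
    H <- spec$image_size[1]; W <- spec$image_size[2]
    truth <- place_seeds(spec)
    labels <- matrix(0L, H, W)
    img <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) img[, , ch] <- spec$background_rgb[ch]
    if (!is.null(spec$surround_rgb)) {
      outside <- !roi_mask(c(H, W), c(spec$dish_center, spec$dish_radius))
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[outside] <- spec$surround_rgb[ch]
        img[, , ch] <- plane
      }
    }
    n <- spec$n_seeds
    seed_rgb <- matrix(0, max(n, 1L), 3)
    for (ch in 1:3) {
      seed_rgb[, ch] <- pmin(pmax(rnorm(max(n, 1L), spec$seed_rgb_mean[ch],
                                        spec$seed_rgb_sd[ch]), 0), 255)
    }
    if (n > 0) {
      for (i in seq_len(n)) {
        px <- rasterize_ellipse(truth[i, ], c(H, W))
        labels[px] <- i
        for (ch in 1:3) img[cbind(px, ch)] <- seed_rgb[i, ch]
      }
    }
    img <- img + array(rnorm(H * W * 3, 0, spec$noise_sd), dim = c(H, W, 3))
    img <- round(pmin(pmax(img, 0), 255))
    truth$red <- seed_rgb[seq_len(n), 1]
    truth$green <- seed_rgb[seq_len(n), 2]
    truth$blue <- seed_rgb[seq_len(n), 3]
    id <- sprintf("sim-%s-%s-%d", tolower(spec$mode),
                  gsub("-", "", spec$condition), spec$seed)
    structure(
      list(image = plate_image(img, mode = spec$mode, id = id),
           labels = labels, truth = truth, condition = spec$condition,
           spec = spec),
      class = "synthetic_plate"
    )
  })
}

#' @export
print.synthetic_plate <- function(x, ...) {
  cat(sprintf("<synthetic_plate> %s: %d seeds, condition=%s\n",
              x$image$id, nrow(x$truth), x$condition))
  invisible(x)
}

#' Generate a balanced labeled dataset of synthetic plates
#'
#' Draws `n_plates_per_class` plates from each of two specs (differing in
#' their class-dependent distributions). Per-plate RNG seeds are derived
#' deterministically from the master `seed`.
#'
#' @param n_plates_per_class Plates per condition.
#' @param salt_spec,nonsalt_spec [plate_spec()]s for the two conditions.
#' @param seed Master integer seed.
#' @return List of `synthetic_plate`s (salt plates first), with unique
#'   plate ids.
#' @export
generate_dataset <- function(n_plates_per_class, salt_spec, nonsalt_spec,
                             seed = 1L) {
  stopifnot(inherits(salt_spec, "plate_spec"),
            inherits(nonsalt_spec, "plate_spec"),
            identical(salt_spec$condition, "salt"),
            identical(nonsalt_spec$condition, "non-salt"))
  n <- n_plates_per_class
  plate_seeds <- withr::with_seed(seed,
                                  sample.int(.Machine$integer.max - 1L,
                                             2L * n))
  plates <- vector("list", 2L * n)
  for (i in seq_len(2L * n)) {
    spec <- if (i <= n) salt_spec else nonsalt_spec
    spec$seed <- plate_seeds[i]
    plates[[i]] <- generate_plate(spec)
    plates[[i]]$image$id <- sprintf("%s-p%03d", plates[[i]]$image$id, i)
  }
  plates
}

#' Feature table of a synthetic dataset
#'
#' Runs the full detection and feature chain on every plate of a
#' [generate_dataset()] result and attaches the ground-truth condition,
#' yielding a table ready for [train_ensemble()] / [run_kfold()].
#'
#' @param plates List of `synthetic_plate`s.
#' @param config A [seg_config()]; defaults to the preset matching each
#'   plate's mode.
#' @return Tibble of labeled seed records.
#' @export
dataset_features <- function(plates, config = NULL) {
  purrr::map(plates, function(p) {
    cfg <- if (is.null(config)) preset_config(p$image$mode) else config
    tab <- extract_plate_table(p$image, cfg)
    if (nrow(tab) > 0) tab$condition <- p$condition
    tab
  }) |>
    dplyr::bind_rows()
}

#' Ground-truth condition table of a dataset
#'
#' @param plates List of `synthetic_plate`s.
#' @return Tibble with `plate` and `condition`.
#' @export
dataset_truth <- function(plates) {
  tibble(
    plate = vapply(plates, function(p) p$image$id, character(1)),
    condition = vapply(plates, function(p) p$condition, character(1))
  )
}
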