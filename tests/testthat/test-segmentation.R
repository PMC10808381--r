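grey_image <- function(m) plate_image(m, mode = "FLUO")

test_that("binarize applies threshold, polarity and ROI as documented", {
  cfg <- function(...) seg_config(channel = "grey", ...)

  uniform <- grey_image(matrix(40, 4, 4))
  m <- binarize(uniform, cfg(threshold = 100, polarity = "bright_objects"))
  expect_false(any(m))

  two <- grey_image(matrix(c(10, 30, 200, 250), 2, 2))
  m <- binarize(two, cfg(threshold = 100, polarity = "bright_objects"))
  expect_equal(sum(m), 2L)
  expect_true(all(two$pixels[, , 1][m] >= 100))

  # dark_objects is the complementary comparison (<= threshold)
  m2 <- binarize(two, cfg(threshold = 100, polarity = "dark_objects"))
  expect_equal(m2, !m)

  # ROI forces everything outside the circle to background
  big <- grey_image(matrix(200, 11, 11))
  m3 <- binarize(big, cfg(threshold = 100, polarity = "bright_objects",
                          roi = c(6, 6, 2)))
  expect_true(m3[6, 6])
  expect_false(m3[1, 1])
  expect_equal(sum(m3), sum((row(matrix(0, 11, 11)) - 6)^2 +
                              (col(matrix(0, 11, 11)) - 6)^2 <= 4))
})

test_that("otsu threshold equals exhaustive between-class variance search", {
  # bimodal two-valued image: the split must separate the populations
  vals <- c(rep(50, 70), rep(200, 30))
  t <- otsu_threshold(vals)
  expect_true(t > 50 && t <= 200)
  expect_equal(sum(vals >= t), 30L)

  brute_otsu <- function(v) {
    best <- -1; best_t <- 0L
    for (t in 1:255) {
      lo <- v[v < t]; hi <- v[v >= t]
      if (!length(lo) || !length(hi)) next
      bc <- (length(lo) / length(v)) * (length(hi) / length(v)) *
        (mean(lo) - mean(hi))^2
      if (bc > best + 1e-12) { best <- bc; best_t <- t }
    }
    best_t
  }
  expect_equal(t, brute_otsu(vals))

  withr::with_seed(42, {
    for (i in 1:20) {
      v <- sample(0:255, 200, replace = TRUE)
      expect_equal(otsu_threshold(v), brute_otsu(v))
    }
  })
})

test_that("labeling handles the smallest objects and 8-connectivity", {
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  rg <- label_regions(single)
  expect_length(rg, 1L)
  expect_equal(rg[[1]]$area, 1L)
  expect_equal(unname(rg[[1]]$outer_contour[1, ]), c(3L, 3L))
  expect_equal(nrow(rg[[1]]$outer_contour), 1L)

  diag2 <- matrix(FALSE, 4, 4); diag2[2, 2] <- TRUE; diag2[3, 3] <- TRUE
  expect_length(label_regions(diag2), 1L)

  expect_length(label_regions(matrix(FALSE, 3, 3)), 0L)
})

test_that("contour-traced partition matches flood fill on random masks", {
  withr::with_seed(7, {
    for (i in 1:200) {
      n <- sample(8:64, 1)
      m <- matrix(runif(n * n) < runif(1, 0.15, 0.7), n, n)
      L <- regions_to_labels(label_regions(m), dim(m))
      expect_identical(canonical_labels(L), canonical_labels(flood_label(m)))
      expect_equal(sum(L > 0), sum(m))  # areas partition the foreground
    }
  })
})

test_that("outer contours are closed clockwise cycles on region pixels", {
  withr::with_seed(11, {
    for (i in 1:25) {
      m <- matrix(runif(400) < 0.45, 20, 20)
      for (rg in label_regions(m)) {
        ct <- rg$outer_contour
        # every contour point belongs to the region
        keys <- paste(rg$pixels[, 1], rg$pixels[, 2])
        expect_true(all(paste(ct[, 1], ct[, 2]) %in% keys))
        # closed: successive steps (wrapping) are Moore-neighbour moves
        nxt <- rbind(ct[-1, , drop = FALSE], ct[1, , drop = FALSE])
        expect_true(all(abs(nxt - ct) <= 1))
        # clockwise in image coordinates (positive shoelace on (col,row))
        if (nrow(ct) >= 3 && rg$area > 2) {
          x <- ct[, 2]; y <- ct[, 1]
          x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
          expect_gte(sum(x * y2 - x2 * y) / 2, 0)
        }
      }
    }
  })
})

test_that("labeling is translation invariant", {
  withr::with_seed(3, {
    m <- matrix(runif(900) < 0.3, 30, 30)
    shifted <- matrix(FALSE, 40, 40)
    shifted[6:35, 9:38] <- m
    a <- label_regions(m)
    b <- label_regions(shifted)
    expect_length(b, length(a))
    for (i in seq_along(a)) {
      expect_equal(b[[i]]$pixels[, 1], a[[i]]$pixels[, 1] + 5L,
                   ignore_attr = TRUE)
      expect_equal(b[[i]]$pixels[, 2], a[[i]]$pixels[, 2] + 8L,
                   ignore_attr = TRUE)
    }
  })
})

test_that("filter_regions gates on area and ROI and relabels from 1", {
  m <- matrix(FALSE, 20, 20)
  m[2, 2] <- TRUE                  # 1-px speck
  m[5:14, 5:14] <- TRUE            # 100-px seed
  regions <- label_regions(m)
  kept <- filter_regions(regions, seg_config(min_area = 5, max_area = 1e4))
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$label, 1L)
  expect_equal(kept[[1]]$area, 100L)

  # max_area gate removes an oversized rim-like blob
  kept2 <- filter_regions(regions, seg_config(min_area = 0, max_area = 50))
  expect_length(kept2, 1L)
  expect_equal(kept2[[1]]$area, 1L)

  # brute-force predicate oracle over random region lists
  withr::with_seed(21, {
    for (i in 1:20) {
      mm <- matrix(runif(32 * 32) < 0.35, 32, 32)
      rgs <- label_regions(mm)
      cfg <- seg_config(min_area = sample(1:4, 1), max_area = sample(5:40, 1),
                        roi = c(16, 16, runif(1, 5, 20)))
      kept <- filter_regions(rgs, cfg)
      oracle <- Filter(function(rg) {
        rg$area >= cfg$min_area && rg$area <= cfg$max_area &&
          (rg$centroid[1] - 16)^2 + (rg$centroid[2] - 16)^2 <= cfg$roi[3]^2
      }, rgs)
      expect_equal(length(kept), length(oracle))
      if (length(kept)) {
        expect_equal(lapply(kept, `[[`, "pixels"),
                     lapply(oracle, `[[`, "pixels"))
        expect_equal(vapply(kept, `[[`, integer(1), "label"),
                     seq_along(kept))
      }
    }
  })
})

test_that("count_objects recovers the generator's ground truth", {
  blank <- plate_image(matrix(0, 50, 50), mode = "FLUO")
  expect_equal(count_objects(blank, preset_config("FLUO")), 0L)

  plate <- generate_plate(small_spec(n_seeds = 20, seed = 9))
  expect_equal(count_objects(plate$image, preset_config("FLUO")), 20L)

  # pod-like side-view fixture: sparser, larger bright objects on a dark
  # field, counted with an adjusted detection setup
  pods <- generate_plate(plate_spec("FLUO", n_seeds = 8, image_size = 300,
                                    dish_radius = 140, seed = 13,
                                    axis_mean = 16, aspect_mean = 3.2))
  cfg <- seg_config(channel = "red", threshold = "otsu",
                    polarity = "bright_objects", min_area = 40,
                    max_area = 10000)
  expect_equal(count_objects(pods$image, cfg), 8L)
})
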