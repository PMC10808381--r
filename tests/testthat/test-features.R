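test_that("3x3 solid square has hand-traced feature values", {
  m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
  f <- morphological_features(region_of(m))
  expect_equal(f$area, 9L)
  expect_equal(f$perimeter, 8.0)
  expect_equal(f$circularity, 64 / 9)
  expect_equal(f$compactness, 9 / 8)
  expect_equal(f$eccentricity, 1.0)
  # symmetric square: both moment axes equal
  expect_equal(f$major, f$minor)
})

test_that("digital disc and ellipse recover their axes from moments", {
  f <- morphological_features(region_of(disc_mask(20)))
  expect_lt(abs(f$major - 20) / 20, 0.05)
  expect_lt(abs(f$minor - 20) / 20, 0.05)
  expect_lt(abs(f$eccentricity - 1), 0.02)

  # solid axis-aligned ellipse a=30, b=10, against the exhaustive pixel
  # moment oracle
  mask <- disc_mask(30, a = 30, b = 10)
  f2 <- morphological_features(region_of(mask))
  px <- which(mask, arr.ind = TRUE)
  lam <- sort(eigen(cov(px) * (nrow(px) - 1) / nrow(px))$values,
              decreasing = TRUE)
  expect_equal(f2$major, 2 * sqrt(lam[1]), tolerance = 1e-10)
  expect_equal(f2$minor, 2 * sqrt(lam[2]), tolerance = 1e-10)
  expect_lt(abs(f2$major - 30) / 30, 0.05)
  expect_lt(abs(f2$minor - 10) / 10, 0.05)
  expect_lt(abs(f2$eccentricity - 3) / 3, 0.07)
})

test_that("degenerate one-pixel-wide regions floor the minor axis", {
  line <- matrix(FALSE, 3, 8); line[2, 2:7] <- TRUE
  f <- morphological_features(region_of(line))
  expect_equal(f$minor, 0.5)
  expect_gte(f$major, f$minor)
})

test_that("circularity of growing discs approaches 4*pi", {
  for (r in c(15, 25, 40)) {
    f <- morphological_features(region_of(disc_mask(r)))
    expect_gte(f$circularity, 4 * pi * 0.85)
    expect_lte(f$circularity, 4 * pi * 1.15)
  }
})

test_that("rotating an ellipse 90 degrees preserves shape features", {
  mask <- disc_mask(24, a = 24, b = 9)
  rot <- t(mask)
  fa <- morphological_features(region_of(mask))
  fb <- morphological_features(region_of(rot))
  expect_equal(fb$area, fa$area)
  expect_equal(fb$major, fa$major, tolerance = 1e-10)
  expect_equal(fb$minor, fa$minor, tolerance = 1e-10)
  expect_equal(fb$eccentricity, fa$eccentricity, tolerance = 1e-10)
  expect_lt(abs(fb$perimeter - fa$perimeter) / fa$perimeter, 0.02)
})

const_image <- function(rgb, n = 8) {
  px <- array(0, dim = c(n, n, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  plate_image(px, mode = "FLUO")
}

test_that("uniform regions give constant quartiles and grey peak", {
  img <- const_image(c(120, 60, 30))
  m <- matrix(FALSE, 8, 8); m[3:6, 3:6] <- TRUE
  f <- colorimetric_features(region_of(m), img)
  expect_equal(c(f$q1r, f$q2r, f$q3r), c(120, 120, 120))
  expect_equal(c(f$q1g, f$q2g, f$q3g), c(60, 60, 60))
  expect_equal(c(f$q1b, f$q2b, f$q3b), c(30, 30, 30))
  expect_equal(c(f$q1grey, f$q2grey, f$q3grey), c(70, 70, 70))
  expect_equal(f$hisgreypeak, 70L)
})

test_that("pure red sits in hue class 0 at every division", {
  img <- const_image(c(255, 0, 0))
  m <- matrix(FALSE, 8, 8); m[2:5, 2:5] <- TRUE
  f <- colorimetric_features(region_of(m), img)
  expect_equal(f$hue16max, 0L)
  expect_equal(f$hue32max, 0L)
  expect_equal(f$hue64max, 0L)
})

test_that("quartiles interpolate between closest order statistics", {
  px <- array(0, dim = c(1, 4, 3))
  px[1, , 1] <- c(10, 20, 30, 40)
  px[1, , 2] <- c(10, 20, 30, 40)
  px[1, , 3] <- c(10, 20, 30, 40)
  img <- plate_image(px, mode = "FLUO")
  m <- matrix(TRUE, 1, 4)
  f <- colorimetric_features(region_of(m), img)
  expect_equal(f$q1grey, 17.5)
  expect_equal(f$q2grey, 25.0)
  expect_equal(f$q3grey, 32.5)
})

test_that("quartile ordering holds on fuzzed random regions", {
  withr::with_seed(17, {
    for (i in 1:40) {
      n <- 12
      px <- array(sample(0:255, n * n * 3, replace = TRUE),
                  dim = c(n, n, 3))
      img <- plate_image(px, mode = "FLUO")
      m <- matrix(runif(n * n) < 0.5, n, n)
      if (!any(m)) next
      for (rg in label_regions(m)) {
        f <- colorimetric_features(rg, img)
        expect_true(f$q1grey <= f$q2grey && f$q2grey <= f$q3grey)
        expect_true(f$q1r <= f$q2r && f$q2r <= f$q3r)
        expect_true(f$q1g <= f$q2g && f$q2g <= f$q3g)
        expect_true(f$q1b <= f$q2b && f$q2b <= f$q3b)
        expect_true(f$hue16max >= 0 && f$hue16max <= 15)
        expect_true(f$hue32max >= 0 && f$hue32max <= 31)
        expect_true(f$hue64max >= 0 && f$hue64max <= 63)
      }
    }
  })
})

test_that("color features are invariant to region translation", {
  withr::with_seed(23, {
    tile <- array(sample(0:255, 8 * 8 * 3, replace = TRUE), dim = c(8, 8, 3))
    base <- array(0, dim = c(30, 30, 3))
    shifted <- base
    base[3:10, 3:10, ] <- tile
    shifted[15:22, 18:25, ] <- tile
    ma <- matrix(FALSE, 30, 30); ma[3:10, 3:10] <- TRUE
    mb <- matrix(FALSE, 30, 30); mb[15:22, 18:25] <- TRUE
    fa <- colorimetric_features(region_of(ma), plate_image(base, "FLUO"))
    fb <- colorimetric_features(region_of(mb), plate_image(shifted, "FLUO"))
    expect_equal(fa, fb)
  })
})

test_that("extract_plate_table composes segmentation and both feature sets", {
  blank <- plate_image(matrix(0, 40, 40), mode = "FLUO")
  expect_equal(nrow(extract_plate_table(blank, preset_config("FLUO"))), 0L)

  plate <- generate_plate(small_spec(n_seeds = 15, seed = 31))
  cfg <- preset_config("FLUO")
  tab <- extract_plate_table(plate$image, cfg)
  expect_equal(nrow(tab), 15L)
  expect_identical(tab$id, 1:15)
  expect_true(all(tab$eccentricity >= 1))
  expect_true(all(tab$major >= tab$minor))
  expect_true(all(tab$circularity > 0))

  # conservation: region areas sum to the filtered foreground pixel count
  mask <- binarize(plate$image, cfg)
  kept <- filter_regions(label_regions(mask), cfg)
  expect_equal(sum(tab$area),
               sum(vapply(kept, function(r) morphological_features(r)$area,
                          numeric(1))))
})
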