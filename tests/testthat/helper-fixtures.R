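# Small, fast fixtures shared across test files. Unit and property tests
# run on down-scaled plates (300 px dish, ~20 seeds); the acceptance tests
# use the generator defaults.

small_spec <- function(mode = "FLUO", condition = "non-salt", seed = 1L,
                       n_seeds = 20L, ...) {
  plate_spec(mode, condition = condition, n_seeds = n_seeds,
             image_size = 300L, dish_radius = 140, seed = seed, ...)
}

# Feature-level synthetic seed records: Gaussian features with an optional
# shift on q2r, for classifier tests that do not need images.
feature_records <- function(n, shift = 0, plate = "p1",
                            condition = "non-salt", seed = 1L) {
  withr::with_seed(seed, {
    x <- as.data.frame(matrix(rnorm(n * 23), n, 23))
    names(x) <- feature_columns("all")
    x$q2r <- x$q2r + shift
    out <- tibble::as_tibble(x)
    out$plate <- plate
    out$condition <- condition
    out$id <- seq_len(n)
    out
  })
}

# Independent 8-connected labeling oracle: plain BFS flood fill.
flood_label <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W); cur <- 0L
  for (s in which(mask)) {
    if (lab[s] > 0) next
    cur <- cur + 1L
    queue <- s; lab[s] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1) %% H + 1; c <- (p - 1) %/% H + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && mask[rr, cc]) {
          q <- (cc - 1) * H + rr
          if (lab[q] == 0) { lab[q] <- cur; queue <- c(queue, q) }
        }
      }
    }
  }
  lab
}

# Canonical form of a labeling: labels renumbered by first occurrence, so
# two labelings describe the same partition iff their canonical forms match.
canonical_labels <- function(lab) {
  v <- as.vector(lab)
  u <- unique(v[v > 0])
  match(v, u, nomatch = 0L)
}

# A solid digital disc / axis-aligned ellipse as a logical mask.
disc_mask <- function(radius, a = radius, b = radius) {
  n <- 2L * ceiling(a) + 5L
  cen <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  ((rr - cen) / b)^2 + ((cc - cen) / a)^2 <= 1
}

region_of <- function(mask) label_regions(mask)[[1]]

# Printed 2-decimal table values mix rounding and truncation; a computed
# metric matches a printed value if either display reproduces it.
expect_printed_2dp <- function(value, printed) {
  expect_true(
    isTRUE(all.equal(format_metric(value, "round"), printed)) ||
      isTRUE(all.equal(format_metric(value, "truncate"), printed)),
    label = sprintf("%.6f displayed at 2 decimals as %.2f", value, printed)
  )
}
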