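test_that("lane segmentation partitions the gel width with the remainder
           distributed from the left", {
  g <- gel_geometry(11, 160, 10, 100)           # width 150
  l <- segment_lanes(g, 10)
  w <- l$right_col - l$left_col + 1L
  expect_true(all(w == 15L))
  expect_identical(l$left_col[1], 11L)
  expect_identical(l$right_col[10], 160L)
  expect_true(all(l$left_col[-1] == l$right_col[-10] + 1L))  # no gaps/overlap

  g2 <- gel_geometry(1, 152, 10, 100)           # width 152
  w2 <- with(segment_lanes(g2, 10), right_col - left_col + 1L)
  expect_identical(as.integer(w2), c(16L, 16L, rep(15L, 8)))
  expect_identical(sum(w2), 152L)

  expect_error(segment_lanes(gel_geometry(1, 5, 1, 9), 10), "exceeds")

  # every true lane centre of a simulated gel falls inside its lane
  sim <- quick_sim(noise_sd = 0, seed = 2)
  lanes <- segment_lanes(sim$truth$geometry, sim$truth$config$n_lanes)
  tl <- sim$truth$lanes
  ctr <- (tl$left_col + tl$right_col) / 2
  expect_true(all(ctr >= lanes$left_col & ctr <= lanes$right_col))
})

test_that("profile extraction partitions total gel intensity exactly and
           matches closed-form band integrals", {
  sim <- quick_sim(noise_sd = 2, seed = 5)
  geom <- sim$truth$geometry
  lanes <- segment_lanes(geom, 8)
  m <- sim$image$pixels[["700nm"]]
  tots <- vapply(seq_len(8), function(i)
    sum(extract_profile(sim$image, geom, lanes[i, ], "700nm")$intensity),
    numeric(1))
  region <- m[geom$resolving_top_row:(geom$bottom_row - 1),
              geom$left_col:geom$right_col]
  expect_identical(sum(tots), sum(region))

  # constant field: every entry equals the lane width
  const <- gel_image(list(matrix(1, 120, 100)), "700nm")
  cg <- gel_geometry(11, 85, 20, 110)
  lc <- segment_lanes(cg, 5)
  p <- extract_profile(const, cg, lc[1, ], "700nm")
  expect_true(all(p$intensity == 15))
  expect_length(p$intensity, 110 - 20)          # bottom_row - resolving_top
  expect_identical(p$distance, 0:(110 - 20 - 1))

  # single Gaussian band: integral = A * sigma * sqrt(2*pi) * width within 1%
  A <- 40; sg <- 4
  gm <- matrix(0, 200, 60)
  gm[, 11:40] <- A * exp(-(seq_len(200) - 100)^2 / (2 * sg^2))
  img <- gel_image(list(gm), "700nm")
  gg <- gel_geometry(11, 40, 5, 200)
  pp <- extract_profile(img, gg, data.frame(index = 1L, left_col = 11L,
                                            right_col = 40L), "700nm")
  expect_lt(abs(sum(pp$intensity) - A * sg * sqrt(2 * pi) * 30) /
              (A * sg * sqrt(2 * pi) * 30), 0.01)

  expect_error(extract_profile(img, gg, data.frame(index = 1L,
    left_col = 11L, right_col = 40L), "800nm"), "unknown channel")
})

test_that("rolling-minimum background subtraction removes baselines and
           preserves narrow peaks", {
  const <- make_profile(rep(100, 300), subtracted = FALSE)
  expect_true(all(subtract_background(const)$intensity == 0))

  # Gaussian sigma 3 on offset 100: peak height within 2% of its amplitude
  x <- 100 + 500 * exp(-(0:299 - 150)^2 / (2 * 3^2))
  p <- subtract_background(make_profile(x, subtracted = FALSE), 51)
  expect_true(p$background_subtracted)
  expect_lt(abs(max(p$intensity) - 500) / 500, 0.02)

  # idempotent on already-zero-baseline input
  p2 <- subtract_background(p, 51)
  expect_equal(p2$intensity, p$intensity, tolerance = 1e-10)

  expect_error(subtract_background(make_profile(1:10), 51), "larger")
  expect_error(subtract_background(make_profile(1:100), 1), ">= 3")
})

test_that("band detection implements topographic prominence, checked
           against an exhaustive oracle", {
  # lone Gaussian at distance 120
  x <- 300 * exp(-(0:299 - 120)^2 / 18)
  b <- detect_bands(make_profile(x))
  expect_identical(nrow(b), 1L)
  expect_equal(b$apex_distance, 120)
  expect_gt(b$area, 0)
  expect_lte(b$prominence, b$height)

  # two peaks, prominences 100 and 10: absolute threshold 50 keeps one
  y <- numeric(200)
  y <- y + 100 * exp(-(0:199 - 60)^2 / 8) + 10 * exp(-(0:199 - 140)^2 / 8)
  got <- detect_bands(make_profile(y), 50, absolute = TRUE)
  expect_identical(nrow(got), 1L)
  expect_equal(got$apex_distance, 60)
  orc <- oracle_peaks(y)
  expect_equal(got$apex_distance, orc$idx[orc$prominence >= 50] - 1)

  # plateau: leftmost sample is the apex
  z <- c(0, 1, 5, 5, 5, 1, 0)
  expect_equal(detect_bands(make_profile(z))$apex_distance, 2)

  # random profiles: prominences match the oracle exactly
  set.seed(99)
  for (rep in 1:8) {
    v <- pmax(stats::filter(rnorm(150, 0, 1), rep(1, 5) / 5,
                            circular = TRUE) + 0.5, 0)
    v <- as.numeric(v)
    got <- detect_bands(make_profile(v), 1e-9, absolute = TRUE)
    orc <- oracle_peaks(v)
    expect_equal(got$apex_distance, orc$idx - 1)
    expect_equal(got$prominence, orc$prominence, tolerance = 1e-12)
  }
})

test_that("band detection is scale-invariant and monotone in the threshold", {
  set.seed(7)
  v <- pmax(as.numeric(stats::filter(rnorm(200), rep(1, 7) / 7,
                                     circular = TRUE)), 0)
  b1 <- detect_bands(make_profile(v), 0.1)
  b2 <- detect_bands(make_profile(123.4 * v), 0.1)
  expect_equal(b1$apex_distance, b2$apex_distance)

  counts <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.5, 1),
                   function(t) nrow(detect_bands(make_profile(v), t)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))

  expect_identical(nrow(detect_bands(make_profile(rep(0, 50)))), 0L)
})

test_that("the simulated marker lane yields one band per ladder rung within
           2 px of truth", {
  sim <- quick_sim(noise_sd = 1.5, seed = 12)   # band SNR ~ 20
  geom <- sim$truth$geometry
  lanes <- segment_lanes(geom, 8)
  p <- subtract_background(
    extract_profile(sim$image, geom, lanes[1, ], "800nm"))
  b <- detect_bands(p, 0.05)
  tb <- sim$truth$bands
  tb <- tb[tb$channel == "800nm", ]
  expect_identical(nrow(b), nrow(tb))
  expect_true(all(abs(sort(b$apex_distance) - sort(tb$distance)) <= 2))
})
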