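test_that("marker-mass assignment pairs by order and prunes spurious peaks
           like the exhaustive subset oracle", {
  ladder <- c(250, 150, 100, 75, 50, 37, 25)
  b <- data.frame(apex_distance = c(30, 55, 80, 110, 150, 200, 260),
                  height = 1, prominence = c(9, 8, 9, 7, 8, 9, 8), area = 1)
  a <- assign_marker_masses(b, ladder)
  expect_equal(a$distance, b$apex_distance)
  expect_equal(a$mass, ladder)

  # 8 bands incl. one spurious low-prominence peak: compare with brute force
  b8 <- data.frame(apex_distance = c(30, 55, 80, 95, 110, 150, 200, 260),
                   height = 1,
                   prominence = c(9, 8, 9, 0.5, 7, 8, 9, 8), area = 1)
  got <- assign_marker_masses(b8, ladder)
  subsets <- utils::combn(8, 7)
  best <- subsets[, which.max(apply(subsets, 2, function(s)
    sum(b8$prominence[s])))]
  expect_equal(got$distance, b8$apex_distance[sort(best)])
  expect_equal(got$mass, ladder)

  expect_error(assign_marker_masses(b[1:5, ], ladder), "insufficient")
})

test_that("calibration interpolates log-linearly through every anchor and
           extrapolates the end segments", {
  cal <- fit_calibration(data.frame(distance = c(10, 110),
                                    mass = c(100, 10)))
  expect_equal(as.numeric(predict(cal, 60)), 10^1.5)
  expect_equal(as.numeric(predict(cal, 160)), 10^0.5)   # extrapolated
  expect_true(attr(predict(cal, 160), "extrapolated"))
  expect_false(attr(predict(cal, 60), "extrapolated"))

  # passes through every anchor exactly
  anc <- data.frame(distance = c(20, 84, 126, 156, 198, 230, 270),
                    mass = c(250, 150, 100, 75, 50, 37, 25))
  cal2 <- fit_calibration(anc)
  expect_equal(as.numeric(predict(cal2, anc$distance)), anc$mass)
  expect_equal(distance_at(cal2, anc$mass), anc$distance)

  # anchors sampled from an exact log-linear law reproduce the law to
  # machine precision at random distances, interpolated and extrapolated
  a <- 606; b <- 240
  law_mass <- function(d) 10^((a - d) / b)
  anchors <- data.frame(distance = c(30, 80, 150, 220, 280),
                        mass = law_mass(c(30, 80, 150, 220, 280)))
  cal3 <- fit_calibration(anchors)
  set.seed(123)
  d <- runif(1000, 10, 330)
  expect_equal(as.numeric(predict(cal3, d)), law_mass(d), tolerance = 1e-12)
  # strictly monotone decreasing
  ds <- sort(d)
  expect_true(all(diff(as.numeric(predict(cal3, ds))) < 0))

  expect_error(fit_calibration(data.frame(distance = c(10, 5),
                                          mass = c(100, 10))), "increasing")
  expect_error(fit_calibration(data.frame(distance = c(10, 20),
                                          mass = c(10, 100))), "decreasing")
  expect_error(fit_calibration(anc[1, ]), ">= 2")
})

test_that("rebinning onto the mass axis is conservative, local and linear", {
  anc <- data.frame(distance = c(10, 300), mass = c(250, 10))
  cal <- fit_calibration(anc)
  grid <- mass_grid(300, 7, 400)   # covers the profile's full mass span

  set.seed(21)
  p <- make_profile(pmax(rnorm(320, 5, 3), 0))
  mp <- profile_to_mass_axis(p, cal, grid)
  expect_lt(abs(sum(mp$intensity) - sum(p$intensity)) / sum(p$intensity),
            0.005)
  expect_true(all(mp$intensity >= 0))

  # single-pixel spike lands in the cells covering its mass interval
  spike <- make_profile(replace(numeric(320), 151, 1000))  # distance 150
  ms <- profile_to_mass_axis(spike, cal, grid)
  expect_equal(sum(ms$intensity), 1000, tolerance = 1e-6)
  hi <- as.numeric(predict(cal, 150)); lo <- as.numeric(predict(cal, 151))
  nz <- which(ms$intensity > 0)
  expect_true(all(ms$mass_grid[nz] <= hi * 1.01 &
                  ms$mass_grid[nz] >= lo * 0.99))

  # oracle: direct interval-overlap computation for the spike
  edges <- 10^fluorogel:::.grid_edges(grid)          # ascending masses
  ov <- pmin(log10(edges[-1]), log10(hi)) - pmax(log10(edges[-length(edges)]),
                                                 log10(lo))
  expected <- rev(1000 * pmax(ov, 0) / (log10(hi) - log10(lo)))
  expect_equal(ms$intensity, expected, tolerance = 1e-9)

  # linearity: rebin(aP + bQ) = a rebin(P) + b rebin(Q)
  q <- make_profile(pmax(rnorm(320, 2, 1), 0))
  comb <- make_profile(3 * p$intensity + 7 * q$intensity)
  lhs <- profile_to_mass_axis(comb, cal, grid)$intensity
  rhs <- 3 * profile_to_mass_axis(p, cal, grid)$intensity +
         7 * profile_to_mass_axis(q, cal, grid)$intensity
  expect_equal(lhs, rhs, tolerance = 1e-9)

  # zero in, zero out; contract checks
  expect_true(all(profile_to_mass_axis(make_profile(numeric(320)), cal,
                                       grid)$intensity == 0))
  expect_error(profile_to_mass_axis(p, cal, rev(grid)), "decreasing")
  expect_error(profile_to_mass_axis(make_profile(1:10, subtracted = FALSE),
                                    cal, grid), "background")
})

test_that("composing the simulator's migration law with the fitted
           calibration is the identity within 2%", {
  sim <- quick_sim(noise_sd = 0, seed = 6)
  cfg <- sim$truth$config
  d_anchor <- sim_distance(cfg, cfg$ladder)
  cal <- fit_calibration(data.frame(distance = d_anchor, mass = cfg$ladder))
  masses <- seq(26, 240, by = 2)
  back <- as.numeric(predict(cal, sim_distance(cfg, masses)))
  expect_lt(max(abs(back - masses) / masses), 0.001)  # inside anchor span
})

test_that("bleed correction recovers the simulated emission-shoulder
           coefficient and cleans the marker channel", {
  sim <- quick_sim(noise_sd = 1, bleed_k = 0.25, seed = 13)
  geom <- detect_gel_region(sim$image)
  lanes <- segment_lanes(geom, 8)
  fixed <- correct_bleed(sim$image, geom, lanes, 1L, "700nm", "800nm")
  expect_lt(abs(fixed$meta$bleed_k - 0.25), 0.05)

  # sample bands no longer leak into the marker channel: lane-5 marker
  # profile shows no peaks above threshold where sample bands sit
  p_raw <- subtract_background(
    extract_profile(sim$image, geom, lanes[5, ], "800nm"))
  p_fix <- subtract_background(
    extract_profile(fixed, geom, lanes[5, ], "800nm"))
  expect_lt(max(p_fix$intensity), 0.25 * max(p_raw$intensity))
})
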