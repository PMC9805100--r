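test_that("squared Pearson correlation has its defining properties and
           matches a closed-form example", {
  g <- mass_grid(100, 10, 5)
  x <- make_mass_profile(c(0, 1, 2, 3, 4), g)
  y <- make_mass_profile(c(0, 1, 2, 3, 8), g)
  expect_equal(profile_correlation(x, x), 1)
  # affine invariance
  expect_equal(profile_correlation(x, make_mass_profile(3 * x$intensity + 5,
                                                        g)), 1)
  # closed-form Pearson on the listed vectors: r2 = 18^2 / (10 * 38.8)
  expect_equal(profile_correlation(x, y), 18^2 / (10 * 38.8))
  expect_equal(round(profile_correlation(x, y), 3), 0.835)
  # symmetry
  expect_equal(profile_correlation(x, y), profile_correlation(y, x))

  expect_error(profile_correlation(x, make_mass_profile(1:4,
    mass_grid(100, 10, 4))), "grid mismatch")
  expect_error(profile_correlation(x, make_mass_profile(rep(2, 5), g)),
               "zero-variance")
})

test_that("set correlation yields a unit diagonal for self-comparison and
           correct best matches", {
  sim <- simulate_class_patterns(n_replicates = 1, jitter = 0,
                                 noise_sd = 0, seed = 2)
  refs <- sim$references
  self <- correlate_sets(refs, refs)
  expect_equal(unname(diag(self$r2)), rep(1, length(refs)))
  expect_identical(self$best_match$label, names(refs))
  expect_true(all(self$r2 >= 0 & self$r2 <= 1))

  # zero jitter, zero noise: replicates correlate perfectly with their class
  cs <- correlate_sets(sim$queries, refs)
  expect_equal(unname(cs$best_match$r2), rep(1, length(sim$queries)),
               tolerance = 1e-9)
  expect_identical(cs$best_match$label,
                   sub("_rep[0-9]+$", "", names(sim$queries)))

  expect_error(correlate_sets(list(), refs), "empty")
})

test_that("library serialization round-trips bit-exactly and enforces the
           shared grid", {
  sim <- simulate_class_patterns(n_replicates = 1, jitter = 0.1,
                                 noise_sd = 0.5, seed = 5)
  lib <- reference_library()
  for (nm in names(sim$references))
    lib <- add_entry(lib, nm, sim$references[[nm]])

  path <- withr::local_tempfile(fileext = ".json")
  save_library(lib, path)
  back <- load_library(path)
  expect_identical(back$grid, lib$grid)
  expect_identical(back$entries, lib$entries)
  expect_identical(names(back$entries), names(lib$entries))

  other <- make_mass_profile(rnorm(100)^2, mass_grid(200, 20, 100))
  expect_error(add_entry(lib, "other", other), "grid mismatch")
  expect_error(add_entry(lib, "native", sim$references$native), "duplicate")

  # schema-version guard
  bad <- jsonlite::read_json(path)
  bad$version <- "9.9"
  badf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, badf, auto_unbox = TRUE)
  expect_error(load_library(badf), "schema-version")
})

test_that("classification ranks all references by r2, consistently with the
           correlation matrix", {
  sim <- simulate_class_patterns(n_replicates = 2, jitter = 0.1,
                                 noise_sd = 0.5, seed = 7)
  lib <- reference_library()
  for (nm in names(sim$references))
    lib <- add_entry(lib, nm, sim$references[[nm]])

  q <- sim$references$uv                        # library entry as query
  rk <- classify_profile(q, lib)
  expect_identical(rk$label[1], "uv")
  expect_equal(rk$r2[1], 1)
  expect_identical(nrow(rk), 4L)
  expect_true(all(diff(rk$r2) <= 0))

  # ranked values are a permutation of the correlate_sets row
  cs <- correlate_sets(list(q = q), fluorogel:::.lib_profiles(lib))
  expect_equal(sort(rk$r2), sort(as.numeric(cs$r2["q", ])))

  # an intermediate-intensity variant of a pattern classifies to its class
  pats <- class_pattern_defaults()
  half_uv <- pats$uv; half_uv$intensity <- 0.5 * half_uv$intensity
  q5 <- simulate_class_patterns(classes = c(pats, list(uv5 = half_uv)),
                                n_replicates = 1, jitter = 0.05,
                                noise_sd = 0.5, seed = 8)$queries$uv5_rep1
  expect_identical(classify_profile(q5, lib)$label[1], "uv")

  # a 20% spike-in of a deglycosylated-like pattern into a near-blank
  # native background is assigned to the deglycosylation reference
  mix <- make_mass_profile(0.2 * sim$references$deglyc$intensity +
                           0.8 * sim$references$native$intensity)
  expect_identical(classify_profile(mix, lib)$label[1], "deglyc")
})
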