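# shared fixtures and independent oracles, built in code at test time

# a lane_profile from a bare intensity vector
make_profile <- function(intensity, lane_index = 1L, channel = "700nm",
                         subtracted = TRUE) {
  structure(list(lane_index = lane_index, channel = channel,
                 distance = seq_along(intensity) - 1L,
                 intensity = as.numeric(intensity),
                 background_subtracted = subtracted),
            class = "lane_profile")
}

# a mass_profile from a bare intensity vector
make_mass_profile <- function(intensity, grid = mass_grid(), meta = list()) {
  structure(list(mass_grid = grid, intensity = as.numeric(intensity),
                 meta = meta),
            class = "mass_profile")
}

# oracle: topographic prominence of every local maximum, by exhaustive
# scan (independent of the package's implementation)
oracle_peaks <- function(x) {
  n <- length(x)
  peaks <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[j]) j <- j + 1
      if (j < n && x[j + 1] < x[j]) peaks <- c(peaks, i)
    }
  }
  prom <- vapply(peaks, function(p) {
    lefts <- x[seq_len(p - 1)]
    higher_l <- which(lefts > x[p])
    lbase <- if (length(higher_l)) min(x[(max(higher_l) + 1):(p - 1)])
             else min(lefts)
    rights <- if (p < n) x[(p + 1):n] else numeric(0)
    higher_r <- which(rights > x[p])
    rbase <- if (length(higher_r)) min(rights[seq_len(min(higher_r) - 1)])
             else if (length(rights)) min(rights) else x[p]
    x[p] - max(lbase, rbase)
  }, numeric(1))
  data.frame(idx = peaks, prominence = prom)
}

# simulated gel small enough for fast unit tests but with realistic layout
quick_sim <- function(...) {
  simulate_gel(sim_config(...))
}

# classification band sets in nmol, used by the cross-gel experiments:
# native is near-blank, the stressed classes carry distinct fragment ladders
class_band_sets <- function() {
  list(
    native = data.frame(mass = c(150, 50), amount = c(0.12, 0.06), sigma = 3),
    uv     = data.frame(mass = c(100, 50, 37, 25),
                        amount = c(0.5, 0.8, 0.6, 0.35), sigma = 3),
    heat   = data.frame(mass = c(150, 95, 70, 45, 30, 20),
                        amount = c(0.9, 0.7, 0.8, 0.6, 0.5, 0.45), sigma = 3),
    deglyc = data.frame(mass = c(140, 115, 48),
                        amount = c(0.6, 0.45, 0.55), sigma = 3))
}

# render a set of class lanes (plus marker in lane 1) as one simulated gel;
# `scale` multiplies all sample amounts (exposure-like), `jitter_sd` applies
# multiplicative per-band jitter, `extra` appends additional lanes
class_gel <- function(classes, seed, rotation = 0, exposure = 1,
                      jitter_sd = 0, noise_sd = 1, extra = NULL) {
  set.seed(seed + 5000L)
  bands <- NULL
  lane <- 1L
  for (nm in names(classes)) {
    lane <- lane + 1L
    b <- classes[[nm]]
    if (jitter_sd > 0)
      b$amount <- b$amount * pmax(1 + rnorm(nrow(b), 0, jitter_sd), 0.05)
    bands <- rbind(bands, cbind(lane = lane, b, label = nm))
  }
  if (!is.null(extra))
    for (nm in names(extra)) {
      lane <- lane + 1L
      bands <- rbind(bands, cbind(lane = lane, extra[[nm]], label = nm))
    }
  labels <- unique(bands[, c("lane", "label")])
  cfg <- sim_config(n_lanes = lane, marker_lanes = 1L,
                    bands = bands[, c("lane", "mass", "amount", "sigma")],
                    rotation_deg = rotation, exposure = exposure,
                    noise_sd = noise_sd, seed = seed)
  list(sim = simulate_gel(cfg), labels = labels)
}

# run the analysis pipeline on a class gel and return its per-lane mass
# profiles named by class label
class_gel_profiles <- function(cg, grid = mass_grid()) {
  res <- run_gel_analysis(gel_run_config(image = cg$sim$image, n_lanes =
    cg$sim$truth$config$n_lanes, marker_lanes = 1L, grid = grid))
  out <- list()
  for (i in seq_len(nrow(cg$labels))) {
    ln <- cg$labels$lane[i]
    out[[cg$labels$label[i]]] <- res$mass_profiles[[paste0("lane", ln)]]
  }
  out
}
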