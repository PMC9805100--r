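#' Simulated-gel configuration
#'
#' Defines a synthetic two-channel fluorescence gel with full ground truth.
#' Band migration follows the idealised log-linear law
#' `d(M) = a - b * log10(M)` pixels below the stacking/resolving border
#' (`a`, `b` > 0, so heavier proteins migrate less), which is the relation
#' the calibration model assumes; an optional mild quadratic curvature term
#' exists for robustness testing. Bands are rendered as vertical Gaussians
#' spread over the lane width with softened edges. The marker channel
#' receives a configurable fraction (`bleed_k`) of the sample-channel band
#' signal, emulating a fluorophore emission shoulder. Background is a level
#' within the gel (reduced in the stacking region, which is what makes the
#' stacking/resolving border visible), plus a smooth vertical gradient.
#' Noise is additive Gaussian (optionally Poisson); everything is seeded.
#'
#' @param n_rows,n_cols image dimensions in px.
#' @param left_col,right_col,top_row,resolving_top_row,bottom_row true gel
#'   geometry (1-based, inclusive).
#' @param a,b migration-law coefficients (px; px per decade of kDa).
#' @param curvature quadratic coefficient in log10-mass (default 0: exactly
#'   log-linear).
#' @param n_lanes lane count; `ladder` masses (kDa, decreasing) are loaded in
#'   `marker_lanes` on `marker_channel`.
#' @param bands data.frame of sample bands: columns `lane`, `mass` (kDa),
#'   `amount` (nmol), `sigma` (vertical Gaussian sd, px).
#' @param band_frac fraction of the lane width a band occupies (centred);
#'   real wells are narrower than the lane pitch, leaving dark inter-lane
#'   gaps.
#' @param smear_frac loaded lanes show a faint continuous smear along the
#'   whole separation path (incompletely focused material); this fraction of
#'   each lane's band amount is spread uniformly down the lane.
#' @param intensity_per_nmol rendered integrated intensity per nmol at
#'   exposure 1.
#' @param marker_amount nmol loaded per marker band.
#' @param background background level inside the resolving gel;
#'   `stacking_frac` scales it in the stacking region; `bg_gradient` adds a
#'   linear vertical ramp of that relative amplitude.
#' @param bleed_k fraction of sample-channel band signal leaking into the
#'   marker channel.
#' @param rotation_deg global gel rotation applied to the rendered image.
#' @param exposure global exposure scale factor.
#' @param noise_sd additive Gaussian noise sd; `poisson = TRUE` adds shot
#'   noise instead.
#' @param channels channel labels: sample first, marker second.
#' @param seed RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_rows = 520L, n_cols = 460L,
                       left_col = 35L, right_col = 424L,
                       top_row = 45L, resolving_top_row = 90L,
                       bottom_row = 500L,
                       a = 606, b = 240, curvature = 0,
                       n_lanes = 8L, ladder = c(250, 150, 100, 75, 50, 37, 25),
                       marker_lanes = 1L,
                       bands = sim_default_bands(),
                       band_frac = 0.7, smear_frac = 0.05,
                       intensity_per_nmol = 1e4,
                       marker_amount = 0.5,
                       background = 60, stacking_frac = 0.35,
                       bg_gradient = 0.1,
                       bleed_k = 0.1, rotation_deg = 0, exposure = 1,
                       noise_sd = 3, poisson = FALSE,
                       channels = c("700nm", "800nm"), seed = 1L) {
  cfg <- list(n_rows = n_rows, n_cols = n_cols, left_col = left_col,
              right_col = right_col, top_row = top_row,
              resolving_top_row = resolving_top_row, bottom_row = bottom_row,
              a = a, b = b, curvature = curvature, n_lanes = n_lanes,
              ladder = ladder, marker_lanes = marker_lanes, bands = bands,
              band_frac = band_frac, smear_frac = smear_frac,
              intensity_per_nmol = intensity_per_nmol,
              marker_amount = marker_amount, background = background,
              stacking_frac = stacking_frac, bg_gradient = bg_gradient,
              bleed_k = bleed_k, rotation_deg = rotation_deg,
              exposure = exposure, noise_sd = noise_sd, poisson = poisson,
              channels = channels, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default sample-band layout for the simulator
#'
#' Lanes 2-7 carry two to four bands between 160 and 20 kDa at amounts that
#' give clearly resolved peaks; lane 8 is left empty.
#'
#' @return data.frame with columns `lane`, `mass`, `amount`, `sigma`.
#' @export
sim_default_bands <- function() {
  data.frame(
    lane   = c(2, 2, 3, 3, 3, 4, 4, 5, 5, 5, 5, 6, 6, 7),
    mass   = c(150, 50, 120, 60, 30, 100, 37, 160, 80, 40, 20, 75, 25, 55),
    amount = c(0.8, 0.6, 0.7, 0.9, 0.5, 1.0, 0.6, 0.6, 0.8, 0.7, 0.4,
               0.9, 0.5, 1.0),
    sigma  = 3)
}

#' Migration distance of a mass under a simulator's law
#'
#' @param cfg a `sim_config`.
#' @param mass masses in kDa.
#' @return distances in px below the stacking/resolving border.
#' @export
sim_distance <- function(cfg, mass) {
  lm <- log10(mass)
  cfg$a - cfg$b * lm + cfg$curvature * lm^2
}

## render one band: vertical Gaussian x soft-edged box across the lane
.render_band <- function(canvas, row0, cols, amount_intensity, sigma) {
  nr <- nrow(canvas)
  w <- rep(1, length(cols))
  w[c(1L, length(w))] <- 0.5                      # soft lane edges
  rows <- max(1L, floor(row0 - 5 * sigma)):min(nr, ceiling(row0 + 5 * sigma))
  g <- exp(-(rows - row0)^2 / (2 * sigma^2))
  g <- g / sum(g)
  add <- outer(g, w / sum(w)) * amount_intensity
  canvas[rows, cols] <- canvas[rows, cols] + add
  canvas
}

#' Render a synthetic two-channel gel with ground truth
#'
#' Deterministic for a fixed seed. Returns both the image and a ground-truth
#' record: true band positions/masses/intensities, geometry, rotation,
#' migration-law coefficients, and the true fluorophore amount per lane.
#'
#' @param cfg a [sim_config].
#' @return list with `image` (a [gel_image]) and `truth` (list: `geometry`,
#'   `rotation_deg`, `law` (a, b, curvature), `bands` data.frame with
#'   columns `lane`, `channel`, `mass`, `row` (unrotated apex row),
#'   `distance`, `intensity`, `amount`; `lanes` lane table;
#'   `fluor_nmol` per-lane totals; `config`).
#' @export
simulate_gel <- function(cfg) {
  set.seed(cfg$seed)
  nr <- cfg$n_rows; nc <- cfg$n_cols
  geom <- gel_geometry(cfg$left_col, cfg$right_col, cfg$resolving_top_row,
                       cfg$bottom_row, rotation_deg = 0)
  lanes <- segment_lanes(geom, cfg$n_lanes)
  ch_s <- cfg$channels[1L]; ch_m <- cfg$channels[2L]

  marker_df <- do.call(rbind, lapply(cfg$marker_lanes, function(ml)
    data.frame(lane = ml, mass = cfg$ladder, amount = cfg$marker_amount,
               sigma = 2.5, channel = ch_m)))
  sample_df <- if (nrow(cfg$bands) > 0L)
    cbind(cfg$bands, channel = ch_s) else NULL
  all_bands <- rbind(marker_df, sample_df)
  all_bands$distance <- sim_distance(cfg, all_bands$mass)
  all_bands$row <- cfg$resolving_top_row + all_bands$distance
  if (any(all_bands$row < cfg$resolving_top_row |
          all_bands$row > cfg$bottom_row - 1L))
    stop("band outside the resolving gel")
  all_bands$intensity <-
    all_bands$amount * cfg$intensity_per_nmol * cfg$exposure

  sample_sig <- matrix(0, nr, nc)
  marker_sig <- matrix(0, nr, nc)
  band_cols <- function(ln) {
    w <- ln$right_col - ln$left_col + 1L
    bw <- max(3L, round(cfg$band_frac * w))
    off <- (w - bw) %/% 2L
    (ln$left_col + off):(ln$left_col + off + bw - 1L)
  }
  for (i in seq_len(nrow(all_bands))) {
    bi <- all_bands[i, ]
    ln <- lanes[bi$lane, ]
    rendered <- .render_band(
      if (bi$channel == ch_s) sample_sig else marker_sig,
      bi$row, band_cols(ln),
      bi$amount * cfg$intensity_per_nmol, bi$sigma)
    if (bi$channel == ch_s) sample_sig <- rendered else marker_sig <- rendered
  }
  if (cfg$smear_frac > 0) {
    smear_rows <- cfg$resolving_top_row:(cfg$bottom_row - 1L)
    for (li in unique(all_bands$lane)) {
      tot <- sum(all_bands$amount[all_bands$lane == li]) *
        cfg$intensity_per_nmol * cfg$smear_frac
      cols <- band_cols(lanes[li, ])
      per_px <- tot / (length(smear_rows) * length(cols))
      in_sample <- any(all_bands$lane == li & all_bands$channel == ch_s)
      if (in_sample)
        sample_sig[smear_rows, cols] <- sample_sig[smear_rows, cols] + per_px
      else
        marker_sig[smear_rows, cols] <- marker_sig[smear_rows, cols] + per_px
    }
  }
  truth_bands <- all_bands[, c("lane", "channel", "mass", "row", "distance",
                               "intensity", "amount")]

  # emission-shoulder bleed of the sample signal into the marker channel
  marker_sig <- marker_sig + cfg$bleed_k * sample_sig

  # background: stacking region dimmer than resolving, mild vertical ramp
  bg <- matrix(0, nr, nc)
  gel_rows <- cfg$top_row:cfg$bottom_row
  gel_cols <- cfg$left_col:cfg$right_col
  lvl <- rep(cfg$background, length(gel_rows))
  lvl[gel_rows < cfg$resolving_top_row] <- cfg$background * cfg$stacking_frac
  ramp <- 1 + cfg$bg_gradient * (seq_along(gel_rows) / length(gel_rows) - 0.5)
  bg[gel_rows, gel_cols] <- lvl * ramp

  finish <- function(sig) {
    m <- (sig + bg) * cfg$exposure
    if (cfg$rotation_deg != 0) m <- .rotate_matrix(m, cfg$rotation_deg, 0)
    if (cfg$poisson) m <- matrix(stats::rpois(length(m), pmax(m, 0)),
                                 nrow(m), ncol(m))
    if (cfg$noise_sd > 0)
      m <- m + stats::rnorm(length(m), 0, cfg$noise_sd)
    pmax(m, 0)
  }
  px <- list(finish(sample_sig), finish(marker_sig))
  names(px) <- c(ch_s, ch_m)
  img <- gel_image(px[cfg$channels], cfg$channels, 16L,
                   meta = list(simulated = TRUE, seed = cfg$seed))

  # labelled material per lane includes the smear (same fluorophore)
  fl <- tapply(truth_bands$amount[truth_bands$channel == ch_s],
               truth_bands$lane[truth_bands$channel == ch_s], sum)
  fluor <- stats::setNames(numeric(cfg$n_lanes), seq_len(cfg$n_lanes))
  fluor[names(fl)] <- fl * (1 + cfg$smear_frac)
  list(image = img,
       truth = list(geometry = geom, rotation_deg = cfg$rotation_deg,
                    law = c(a = cfg$a, b = cfg$b, curvature = cfg$curvature),
                    bands = truth_bands, lanes = lanes, fluor_nmol = fluor,
                    config = cfg))
}

#' Default modification-class band patterns
#'
#' Four classes emulating typical labelling outcomes of a stressed antibody:
#' a near-blank `native` class (faint residual labelling of the intact
#' protein), a `uv`-stress fragment ladder, a dense `heat`-stress ladder,
#' and a `deglyc` pattern with shifted heavy-chain species.
#'
#' @return named list of data.frames with columns `mass` (kDa) and
#'   `intensity` (arbitrary units).
#' @export
class_pattern_defaults <- function() {
  list(
    native = data.frame(mass = c(150, 50),
                        intensity = c(30, 12)),
    uv     = data.frame(mass = c(100, 50, 37, 25),
                        intensity = c(400, 700, 500, 300)),
    heat   = data.frame(mass = c(150, 95, 70, 45, 30, 20),
                        intensity = c(900, 700, 800, 600, 500, 400)),
    deglyc = data.frame(mass = c(140, 115, 48),
                        intensity = c(600, 450, 550)))
}

## render a band list as Gaussian peaks in log10-mass on a grid
.pattern_profile <- function(pattern, grid, sigma_log = 0.012) {
  lg <- log10(grid)
  v <- numeric(length(grid))
  for (i in seq_len(nrow(pattern)))
    v <- v + pattern$intensity[i] *
      exp(-(lg - log10(pattern$mass[i]))^2 / (2 * sigma_log^2))
  v
}

#' Simulate labelled reference and replicate query mass profiles
#'
#' Renders each class's band pattern on the common mass grid as a clean
#' reference, then draws replicate queries with per-band multiplicative
#' intensity jitter, a global exposure scale, and additive Gaussian noise —
#' emulating the same samples re-run on independent gels.
#'
#' @param classes named list of band patterns (`mass`, `intensity` columns);
#'   >= 2 classes with distinct band lists.
#' @param n_replicates queries per class.
#' @param jitter sd of the per-band multiplicative intensity jitter
#'   (e.g. 0.1 for 10 %).
#' @param exposure_range range of the per-replicate global scale factor.
#' @param noise_sd additive noise sd on the profile.
#' @param grid common mass grid.
#' @param seed RNG seed.
#' @return list with `references` and `queries`: named lists of
#'   `mass_profile` objects; query names are `<class>_rep<i>`.
#' @export
simulate_class_patterns <- function(classes = class_pattern_defaults(),
                                    n_replicates = 3L, jitter = 0.1,
                                    exposure_range = c(0.5, 2),
                                    noise_sd = 1, grid = mass_grid(),
                                    seed = 1L) {
  if (length(classes) < 2L) stop("need >= 2 classes")
  key <- vapply(classes, function(p)
    paste(p$mass, p$intensity, collapse = ","), character(1L))
  if (anyDuplicated(key)) stop("classes with identical band lists")
  set.seed(seed)
  mk <- function(v, meta) structure(list(mass_grid = grid, intensity = v,
                                         meta = meta),
                                    class = "mass_profile")
  refs <- lapply(names(classes), function(cl)
    mk(.pattern_profile(classes[[cl]], grid), list(condition = cl,
                                                   role = "reference")))
  names(refs) <- names(classes)
  queries <- list()
  for (cl in names(classes))
    for (r in seq_len(n_replicates)) {
      p <- classes[[cl]]
      p$intensity <- p$intensity * pmax(1 + stats::rnorm(nrow(p), 0, jitter), 0)
      scale <- stats::runif(1L, exposure_range[1L], exposure_range[2L])
      v <- scale * .pattern_profile(p, grid)
      if (noise_sd > 0)
        v <- pmax(v + stats::rnorm(length(v), 0, noise_sd), 0)
      queries[[paste0(cl, "_rep", r)]] <-
        mk(v, list(condition = cl, role = "query", replicate = r))
    }
  list(references = refs, queries = queries)
}

#' Simulate a fluorophore dilution series
#'
#' Serial two-fold dilutions from `top_moles`, with intensities drawn from
#' the linear law `intensity = slope * moles + intercept` plus Gaussian
#' noise.
#'
#' @param true_slope,true_intercept the underlying linear law.
#' @param n_points number of dilution points (>= 2).
#' @param noise_sd Gaussian noise sd on the intensities.
#' @param top_moles amount at the top of the series.
#' @param seed RNG seed.
#' @return list with `points` (data.frame `moles`, `intensity`) and `truth`
#'   (slope, intercept).
#' @export
simulate_dilution_series <- function(true_slope, true_intercept = 0,
                                     n_points = 8L, noise_sd = 0,
                                     top_moles = 1, seed = 1L) {
  if (n_points < 2L) stop("n_points must be >= 2")
  set.seed(seed)
  moles <- top_moles / 2^(seq_len(n_points) - 1L)
  intensity <- true_slope * moles + true_intercept
  if (noise_sd > 0) intensity <- intensity + stats::rnorm(n_points, 0, noise_sd)
  list(points = data.frame(moles = moles, intensity = intensity),
       truth = c(slope = true_slope, intercept = true_intercept))
}
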