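#' Ladder specification
#'
#' Ordered marker masses in kDa, strictly decreasing from the top of the gel
#' (largest, least-migrated protein) downward.
#'
#' @param masses numeric vector, >= 2 strictly decreasing positive masses.
#' @return the validated numeric vector, class `ladder_spec`.
#' @export
ladder_spec <- function(masses) {
  masses <- as.numeric(masses)
  if (length(masses) < 2L) stop("ladder needs >= 2 masses")
  if (any(masses <= 0)) stop("ladder masses must be > 0")
  if (any(diff(masses) >= 0)) stop("ladder masses must be strictly decreasing")
  structure(masses, class = "ladder_spec")
}

#' Assign ladder masses to detected marker bands
#'
#' With exactly as many bands as ladder masses the pairing is by order: the
#' least-migrated band takes the largest mass. With surplus bands (spurious
#' peaks), the subset of `length(ladder)` bands with the greatest total
#' prominence is retained, preserving migration order, and paired the same
#' way.
#'
#' @param bands data.frame from [detect_bands()], sorted by `apex_distance`.
#' @param ladder a [ladder_spec] (or plain decreasing numeric vector).
#' @return data.frame of anchors: `distance` (px), `mass` (kDa),
#'   `prominence`.
#' @export
assign_marker_masses <- function(bands, ladder) {
  ladder <- ladder_spec(unclass(ladder))
  m <- length(ladder)
  if (nrow(bands) < m)
    stop("insufficient marker bands: ", nrow(bands), " detected, ",
         m, " expected")
  ord <- order(bands$apex_distance)
  bands <- bands[ord, , drop = FALSE]
  if (nrow(bands) > m) {
    # any distance-ordered subset is valid, so the maximal-total-prominence
    # subset is simply the m most prominent bands, re-sorted by distance
    keep <- sort(order(bands$prominence, decreasing = TRUE)[seq_len(m)])
    bands <- bands[keep, , drop = FALSE]
  }
  data.frame(distance = bands$apex_distance, mass = as.numeric(ladder),
             prominence = bands$prominence)
}

#' Fit a migration-distance to molecular-mass calibration
#'
#' SDS-PAGE migration is close to linear in log10(mass), so the calibration
#' is the piecewise-linear interpolant of (distance, log10 mass) through the
#' marker anchors — it passes through every anchor exactly — extended beyond
#' the first/last anchor by continuing the adjacent segment's slope.
#'
#' @param anchors data.frame with columns `distance` (strictly increasing,
#'   px) and `mass` (strictly decreasing, kDa); >= 2 rows.
#' @return an object of class `gel_calibration`.
#' @seealso [predict.gel_calibration()]
#' @export
fit_calibration <- function(anchors) {
  d <- as.numeric(anchors$distance)
  m <- as.numeric(anchors$mass)
  if (length(d) < 2L) stop("need >= 2 anchors")
  if (any(diff(d) <= 0)) stop("anchor distances must be strictly increasing")
  if (any(m <= 0) || any(diff(m) >= 0))
    stop("anchor masses must be positive and strictly decreasing")
  structure(list(anchors = data.frame(distance = d, mass = m),
                 logm = log10(m)),
            class = "gel_calibration")
}

## piecewise-linear interpolation with end-segment extrapolation
.pwl <- function(x, xs, ys) {
  i <- findInterval(x, xs, all.inside = TRUE)
  ys[i] + (ys[i + 1L] - ys[i]) * (x - xs[i]) / (xs[i + 1L] - xs[i])
}

#' Predict molecular mass from migration distance
#'
#' @param object a `gel_calibration`.
#' @param distance migration distances in px from the resolving border.
#' @param ... unused.
#' @return masses in kDa, with attribute `extrapolated`: logical, TRUE where
#'   the distance lies outside the anchor span (less reliable assignment).
#' @export
predict.gel_calibration <- function(object, distance, ...) {
  d <- object$anchors$distance
  out <- 10^.pwl(distance, d, object$logm)
  attr(out, "extrapolated") <- distance < d[1L] | distance > d[length(d)]
  out
}

#' Predict migration distance from molecular mass (inverse calibration)
#'
#' @param curve a `gel_calibration`.
#' @param mass masses in kDa.
#' @return distances in px.
#' @export
distance_at <- function(curve, mass) {
  # log-mass is strictly decreasing in distance: invert segment-wise
  lm <- rev(curve$logm)
  dd <- rev(curve$anchors$distance)
  .pwl(log10(mass), lm, dd)
}

#' @export
print.gel_calibration <- function(x, ...) {
  cat("gel_calibration: ", nrow(x$anchors), " anchors, ",
      x$anchors$mass[nrow(x$anchors)], "-", x$anchors$mass[1L],
      " kDa over ", x$anchors$distance[1L], "-",
      x$anchors$distance[nrow(x$anchors)], " px\n", sep = "")
  invisible(x)
}

#' @export
coef.gel_calibration <- function(object, ...) object$anchors

#' @export
plot.gel_calibration <- function(x, ...) {
  graphics::plot(x$anchors$distance, x$anchors$mass, log = "y",
                 xlab = "migration distance (px)",
                 ylab = "molecular mass (kDa)",
                 main = "migration-distance calibration", pch = 19, ...)
  d <- seq(min(x$anchors$distance), max(x$anchors$distance), length.out = 200)
  graphics::lines(d, predict(x, d))
  invisible(x)
}

#' Logarithmically spaced molecular-mass grid
#'
#' The common mass axis onto which lane profiles are rebinned for storage and
#' correlation. Strictly decreasing, log-spaced.
#'
#' @param mass_max,mass_min grid range in kDa (defaults 260 and 10, spanning
#'   typical prestained ladders).
#' @param n number of cells (default 500).
#' @return strictly decreasing numeric vector of cell-centre masses.
#' @export
mass_grid <- function(mass_max = 260, mass_min = 10, n = 500L) {
  if (mass_max <= mass_min || mass_min <= 0) stop("invalid mass range")
  10^seq(log10(mass_max), log10(mass_min), length.out = n)
}

## log10 cell edges (ascending) for a decreasing cell-centre grid
.grid_edges <- function(grid) {
  lg <- rev(log10(grid))               # ascending
  mid <- (lg[-1L] + lg[-length(lg)]) / 2
  c(2 * lg[1L] - mid[1L], mid, 2 * lg[length(lg)] - mid[length(mid)])
}

#' Rebin a lane profile onto the common molecular-mass axis
#'
#' Each unit pixel interval `[d, d+1)` of the profile maps through the
#' calibration to a mass interval `[mass(d+1), mass(d))`; its intensity is
#' deposited into grid cells proportionally to interval overlap in log10-mass
#' coordinates (conservative rebinning, linear in the profile). Grid cells
#' outside the profile's mass span stay 0; intensity mapping outside the grid
#' is dropped, so choose a grid covering the calibrated range of interest.
#'
#' @param profile a background-subtracted `lane_profile`.
#' @param curve a `gel_calibration`.
#' @param grid strictly decreasing mass grid from [mass_grid()].
#' @param meta named list of sample metadata (label, condition, gel id, ...).
#' @return an object of class `mass_profile`: list with `mass_grid`,
#'   `intensity` (per grid cell), `meta`.
#' @export
profile_to_mass_axis <- function(profile, curve, grid = mass_grid(),
                                 meta = list()) {
  if (!isTRUE(profile$background_subtracted))
    stop("profile must be background-subtracted")
  if (any(diff(grid) >= 0)) stop("mass grid must be strictly decreasing")
  edges <- .grid_edges(grid)           # ascending log10 mass
  n <- length(grid)
  d <- profile$distance
  lm <- log10(predict(curve, c(d, d[length(d)] + 1L)))
  out <- numeric(n)
  for (i in seq_along(d)) {
    x <- profile$intensity[i]
    if (x == 0) next
    a <- lm[i + 1L]; b <- lm[i]        # pixel interval [a, b] in log10 mass
    if (b <= edges[1L] || a >= edges[n + 1L]) next
    j <- max(findInterval(a, edges), 1L)
    k <- min(findInterval(b, edges, rightmost.closed = TRUE), n)
    ov <- pmin(edges[(j:k) + 1L], b) - pmax(edges[j:k], a)
    cells <- n + 1L - (j:k)            # edges ascend, grid descends
    out[cells] <- out[cells] + x * ov / (b - a)
  }
  structure(list(mass_grid = grid, intensity = out, meta = meta),
            class = "mass_profile")
}

#' @export
print.mass_profile <- function(x, ...) {
  cat("mass_profile: ", length(x$mass_grid), " cells, ",
      format(x$mass_grid[length(x$mass_grid)]), "-",
      format(x$mass_grid[1L]), " kDa, total intensity ",
      format(sum(x$intensity)), "\n", sep = "")
  invisible(x)
}

#' @export
plot.mass_profile <- function(x, ...) {
  graphics::plot(x$mass_grid, x$intensity, type = "l", log = "x",
                 xlim = rev(range(x$mass_grid)),
                 xlab = "molecular mass (kDa)", ylab = "intensity", ...)
  invisible(x)
}

#' Estimate and remove sample-channel bleed from the marker channel
#'
#' Long-wavelength emission shoulders of the sample fluorophore can leak into
#' the marker channel and contaminate marker detection. The bleed coefficient
#' `k` is estimated by least squares of the marker channel's
#' background-corrected signal on the sample channel's, over the gel region
#' excluding the marker lane(s) (where the marker channel should carry no
#' true signal), clipped to [0, 1]; then `k` times the sample signal is
#' subtracted from the marker channel everywhere.
#'
#' @param img a [gel_image].
#' @param geom its [gel_geometry].
#' @param lanes lane table from [segment_lanes()].
#' @param marker_lanes indices of lanes loaded with the ladder.
#' @param sample_channel,marker_channel channel labels.
#' @return the corrected [gel_image], with `k` recorded in
#'   `meta$bleed_k`.
#' @export
correct_bleed <- function(img, geom, lanes, marker_lanes,
                          sample_channel, marker_channel) {
  s <- gel_channel(img, sample_channel)
  m <- gel_channel(img, marker_channel)
  rows <- geom$resolving_top_row:geom$bottom_row
  other <- lanes[!lanes$index %in% marker_lanes, , drop = FALSE]
  cols <- unlist(Map(seq, other$left_col, other$right_col))
  sp <- pmax(s[rows, cols] - stats::median(s[rows, cols]), 0)
  mp <- m[rows, cols] - stats::median(m[rows, cols])
  k <- if (sum(sp^2) > 0) sum(sp * mp) / sum(sp^2) else 0
  k <- min(max(k, 0), 1)
  img$pixels[[marker_channel]] <-
    pmax(m - k * pmax(s - stats::median(s), 0), 0)
  img$meta$bleed_k <- k
  img
}
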