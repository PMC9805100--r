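#' Partition the gel into equal-width lanes
#'
#' The lane width is computed from the declared number of lanes per gel: the
#' gel columns `[left_col, right_col]` are split into `n_lanes` contiguous,
#' non-overlapping strips whose widths differ by at most one pixel, any
#' remainder pixels being distributed one per lane from the left.
#'
#' @param geom a [gel_geometry].
#' @param n_lanes number of lanes loaded on the gel (>= 1).
#' @return a data.frame with columns `index` (1-based, left to right),
#'   `left_col`, `right_col` (inclusive pixel bounds).
#' @export
segment_lanes <- function(geom, n_lanes) {
  n_lanes <- as.integer(n_lanes)
  if (n_lanes < 1L) stop("n_lanes must be >= 1")
  width <- geom$right_col - geom$left_col + 1L
  if (n_lanes > width) stop("n_lanes exceeds gel width in pixels")
  base <- width %/% n_lanes
  w <- rep(base, n_lanes)
  rem <- width %% n_lanes
  if (rem > 0L) w[seq_len(rem)] <- w[seq_len(rem)] + 1L
  right <- geom$left_col - 1L + cumsum(w)
  data.frame(index = seq_len(n_lanes),
             left_col = c(geom$left_col, right[-n_lanes] + 1L),
             right_col = right)
}

#' Lane densitometry profile
#'
#' Intensity versus migration distance for one lane and channel. Migration
#' distance is measured in pixels from the stacking/resolving border:
#' distance `d` corresponds to image row `resolving_top_row + d`, for
#' `d = 0, 1, ..., bottom_row - resolving_top_row - 1`. The intensity at each
#' distance is the pixel sum across the lane width, so summing all lane
#' profiles reproduces the total gel-region intensity exactly.
#'
#' @param img a [gel_image].
#' @param geom its [gel_geometry].
#' @param lane one row of [segment_lanes()]'s output (or any list with
#'   `index`, `left_col`, `right_col`).
#' @param channel channel label to profile.
#' @return an object of class `lane_profile`: list with `lane_index`,
#'   `channel`, `distance` (0, 1, 2, ...), `intensity`, and
#'   `background_subtracted` flag.
#' @export
extract_profile <- function(img, geom, lane, channel) {
  m <- gel_channel(img, channel)
  if (lane$left_col < geom$left_col || lane$right_col > geom$right_col)
    stop("lane outside gel geometry")
  rows <- geom$resolving_top_row:(geom$bottom_row - 1L)
  intensity <- rowSums(m[rows, lane$left_col:lane$right_col, drop = FALSE])
  structure(list(lane_index = lane$index, channel = channel,
                 distance = seq_along(rows) - 1L,
                 intensity = as.numeric(intensity),
                 background_subtracted = FALSE),
            class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat("lane_profile: lane ", x$lane_index, ", channel ", x$channel, ", ",
      length(x$distance), " px, total ", format(sum(x$intensity)),
      if (x$background_subtracted) " (background-subtracted)" else "",
      "\n", sep = "")
  invisible(x)
}

## local linear smoother (Savitzky-Golay, degree 1): equals the centred
## moving average in the interior, stays exact on linear ramps, and handles
## the profile ends with shrinking windows instead of padding
.linsmooth <- function(x, window) {
  h <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    t <- max(1L, i - h):min(n, i + h)
    xt <- x[t]
    tm <- mean(t); xm <- mean(xt)
    den <- sum((t - tm)^2)
    b <- if (den > 0) sum((t - tm) * (xt - xm)) / den else 0
    xm + b * (i - tm)
  }, numeric(1L))
}

#' Subtract a rolling baseline from a lane profile
#'
#' Two-pass robust baseline. A running median over `window` pixels gives a
#' first background estimate; samples rising more than 3 robust standard
#' deviations above it — the bands, dilated by a quarter window to cover
#' their tails — are then excluded, the baseline is re-estimated by linear
#' interpolation across the excluded spans, and smoothed with a local linear
#' smoother of the same window (a centred moving average away from the
#' profile ends). The result tracks smooth backgrounds
#' (linear ramps are reproduced exactly), is unbiased under zero-mean noise,
#' and leaves peaks narrower than the window essentially untouched. The
#' residual is clipped at zero.
#'
#' Because the clipping step turns zero-mean noise into a positive residue,
#' the returned profile also carries `residual_total`, the unclipped sum of
#' (profile - baseline): over background-only stretches its noise averages
#' out, which makes it the right lane total for absolute quantification.
#'
#' @param profile a `lane_profile`.
#' @param window baseline window in pixels (odd; >= 3; default 51).
#' @return the background-subtracted `lane_profile`, with `residual_total`.
#' @export
subtract_background <- function(profile, window = 51L) {
  window <- as.integer(window)
  if (window < 3L) stop("window must be >= 3 px")
  if (window %% 2L == 0L) window <- window + 1L
  x <- profile$intensity
  n <- length(x)
  if (window > n) stop("window larger than profile (", n, " px)")
  base <- .linsmooth(stats::runmed(x, window, endrule = "med"), window)
  # 3 robust sd above baseline flags bands; the floor at 1% of the largest
  # excursion keeps near-noiseless baseline wiggle out of the mask
  thr <- max(3 * stats::mad(x - base), 0.01 * max(x - base))
  mask <- (x - base) > thr
  if (any(mask) && !all(mask)) {
    h <- max(3L, window %/% 4L)
    for (k in which(mask))                      # dilate over band tails
      mask[max(1L, k - h):min(n, k + h)] <- TRUE
    keep <- which(!mask)
    if (length(keep) >= 2L) {
      refit <- x
      refit[mask] <- stats::approx(keep, x[keep], xout = which(mask),
                                   rule = 2)$y
      base <- .linsmooth(refit, window)
    }
  }
  profile$residual_total <- sum(x - base)
  profile$intensity <- pmax(x - base, 0)
  profile$background_subtracted <- TRUE
  profile
}

## Local maxima of x; plateaus collapse to their leftmost sample.
.local_maxima <- function(x) {
  n <- length(x)
  out <- integer(0L)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) out <- c(out, i)  # leftmost of plateau
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

## Topographic prominence of peak at index p: height above the higher of the
## two key saddles, found by scanning each side out to the first strictly
## higher sample (or the signal end).
.prominence <- function(x, p) {
  n <- length(x)
  lmin <- x[p]; i <- p - 1L
  while (i >= 1L && x[i] <= x[p]) { if (x[i] < lmin) lmin <- x[i]; i <- i - 1L }
  rmin <- x[p]; i <- p + 1L
  while (i <= n && x[i] <= x[p]) { if (x[i] < rmin) rmin <- x[i]; i <- i + 1L }
  x[p] - max(lmin, rmin)
}

## nearest local minima (or ends) flanking peak p: the band's base
.peak_base <- function(x, p) {
  n <- length(x)
  l <- p
  while (l > 1L && x[l - 1L] <= x[l]) l <- l - 1L
  r <- p
  while (r < n && x[r + 1L] <= x[r]) r <- r + 1L
  c(l, r)
}

#' Detect bands in a lane profile by topographic prominence
#'
#' Bands are local maxima whose topographic prominence (height above the
#' highest saddle separating the peak from any higher peak) reaches the
#' threshold. By default the threshold is relative to the profile maximum, so
#' detection is invariant under exposure scaling; an absolute threshold is
#' available via `absolute = TRUE`. Adjacent equal-height plateau samples
#' collapse to their leftmost sample. The band area integrates the profile
#' between the two local minima flanking the apex.
#'
#' @param profile a background-subtracted `lane_profile`.
#' @param min_prominence threshold; fraction of the profile maximum
#'   (default 0.05), or an absolute intensity if `absolute = TRUE`.
#' @param absolute interpret `min_prominence` as an absolute intensity.
#' @return data.frame of bands sorted by apex distance: `apex_distance` (px
#'   from the resolving border), `height`, `prominence`, `area`. Zero rows if
#'   nothing reaches the threshold.
#' @export
detect_bands <- function(profile, min_prominence = 0.05, absolute = FALSE) {
  if (!absolute && (min_prominence <= 0 || min_prominence > 1))
    stop("relative min_prominence must be in (0, 1]")
  x <- profile$intensity
  empty <- data.frame(apex_distance = numeric(0), height = numeric(0),
                      prominence = numeric(0), area = numeric(0))
  if (max(x) <= 0) return(empty)
  thr <- if (absolute) min_prominence else min_prominence * max(x)
  peaks <- .local_maxima(x)
  if (length(peaks) == 0L) return(empty)
  prom <- vapply(peaks, function(p) .prominence(x, p), numeric(1L))
  keep <- prom >= thr
  if (!any(keep)) return(empty)
  peaks <- peaks[keep]; prom <- prom[keep]
  area <- vapply(peaks, function(p) {
    b <- .peak_base(x, p); sum(x[b[1L]:b[2L]])
  }, numeric(1L))
  data.frame(apex_distance = profile$distance[peaks],
             height = x[peaks], prominence = prom, area = area)
}
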