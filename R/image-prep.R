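#' Gel geometry
#'
#' Pixel bounds of the gel within the scan: outer left/right columns, the row
#' of the stacking/resolving border (from which migration distances are
#' measured), the bottom of the gel cassette, and the rotation correction that
#' has been applied to the image (degrees, counter-clockwise positive).
#'
#' @param left_col,right_col outermost gel columns (1-based, inclusive).
#' @param resolving_top_row row of the stacking/resolving border.
#' @param bottom_row bottom row of the gel cassette.
#' @param rotation_deg rotation correction applied to the image, degrees.
#' @return an object of class `gel_geometry`.
#' @export
gel_geometry <- function(left_col, right_col, resolving_top_row, bottom_row,
                         rotation_deg = 0) {
  if (left_col >= right_col) stop("left_col must be < right_col")
  if (resolving_top_row >= bottom_row)
    stop("resolving_top_row must be < bottom_row")
  structure(list(left_col = as.integer(left_col),
                 right_col = as.integer(right_col),
                 resolving_top_row = as.integer(resolving_top_row),
                 bottom_row = as.integer(bottom_row),
                 rotation_deg = rotation_deg),
            class = "gel_geometry")
}

#' @export
print.gel_geometry <- function(x, ...) {
  cat("gel_geometry: cols [", x$left_col, ", ", x$right_col,
      "], resolving border row ", x$resolving_top_row,
      ", bottom row ", x$bottom_row,
      ", rotation ", x$rotation_deg, " deg\n", sep = "")
  invisible(x)
}

## summed intensity over all channels
.combined <- function(img) Reduce(`+`, img$pixels)

## strongest positive / negative step in a 1-D projection, with a
## significance gate against the median gradient magnitude
.edge_pair <- function(proj, significance) {
  g <- diff(proj)
  ag <- abs(g)
  if (max(ag) == 0 || max(ag) < significance * stats::median(ag))
    stop("no gel detected: projection edges below ", significance,
         "x the median gradient magnitude")
  # step between i and i+1: rising edge -> first bright index is i+1,
  # falling edge -> last bright index is i
  list(lo = which.max(g) + 1L, hi = which.min(g))
}

#' Detect the gel region and the stacking/resolving border
#'
#' Locates the gel's left/right boundaries as the strongest rising/falling
#' steps of the column-sum projection, the stacking/resolving border as the
#' strongest rising step of the row-sum projection in the upper third of the
#' image (the resolving gel scatters more than the stacking gel), and the
#' cassette bottom as the lowest row whose summed intensity stands clearly
#' above the off-gel baseline. All projections use the channel-summed image,
#' so the result is invariant under uniform intensity scaling.
#'
#' @param img a [gel_image].
#' @param significance the strongest projection step must exceed
#'   `significance` times the median gradient magnitude, else the image is
#'   declared featureless ("no gel detected"). Default 5.
#' @return a [gel_geometry] with `rotation_deg = 0`.
#' @export
detect_gel_region <- function(img, significance = 5) {
  z <- .combined(img)
  cols <- .edge_pair(colSums(z), significance)
  left_col <- cols$lo; right_col <- cols$hi
  if (left_col >= right_col) stop("no gel detected: degenerate column bounds")

  rp <- rowSums(z[, left_col:right_col, drop = FALSE])
  upper <- seq_len(max(2L, floor(nrow(z) / 3)))
  gr <- diff(rp)[upper]
  if (max(abs(gr)) == 0 ||
      max(abs(gr)) < significance * stats::median(abs(diff(rp))))
    stop("no gel detected: no horizontal border in the upper third")
  resolving_top_row <- which.max(gr) + 1L

  lo <- stats::quantile(rp, 0.02, names = FALSE)
  hi <- stats::quantile(rp, 0.98, names = FALSE)
  above <- which(rp > lo + 0.25 * (hi - lo))
  bottom_row <- max(above)
  if (bottom_row <= resolving_top_row)
    stop("no gel detected: bottom edge above resolving border")
  gel_geometry(left_col, right_col, resolving_top_row, bottom_row,
               rotation_deg = 0)
}

## Bilinear rotation of a matrix by `angle` degrees (counter-clockwise
## positive) about the image centre; out-of-frame pixels take `fill`.
.rotate_matrix <- function(m, angle, fill) {
  if (angle == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  th <- angle * pi / 180
  rc <- (nr + 1) / 2; cc <- (nc + 1) / 2
  dr <- seq_len(nr) - rc
  dc <- seq_len(nc) - cc
  # inverse mapping: source coords of each destination pixel
  sr <- outer(cos(th) * dr, sin(th) * dc, `+`) + rc
  sc <- outer(-sin(th) * dr, cos(th) * dc, `+`) + cc
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  at <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- matrix(fill, nr, nc)
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  (1 - fr) * (1 - fc) * at(r0,     c0) +
  (1 - fr) * fc       * at(r0,     c0 + 1) +
  fr       * (1 - fc) * at(r0 + 1, c0) +
  fr       * fc       * at(r0 + 1, c0 + 1)
}

#' Rotate all channels of a gel image
#'
#' Rotates every channel by the same angle about the image centre with
#' bilinear interpolation; pixels mapped from outside the frame are filled
#' with the channel's background median, estimated from the image border
#' (the margin outside the gel). For gels with dark margins of at least
#' ~10 px the total intensity is conserved within 1 %.
#'
#' @param img a [gel_image].
#' @param angle rotation in degrees (counter-clockwise positive); |angle|
#'   must be <= 10.
#' @return the rotated [gel_image].
#' @export
rectify <- function(img, angle) {
  if (abs(angle) > 10) stop("rotation angle out of range (|angle| <= 10 deg)")
  px <- lapply(img$pixels, function(m) {
    edge <- c(m[1:3, ], m[nrow(m) - 0:2, ], m[, 1:3], m[, ncol(m) - 0:2])
    pmax(.rotate_matrix(m, angle, fill = stats::median(edge)), 0)
  })
  gel_image(px, img$channels, img$bit_depth, img$meta)
}

## Column-sum projection of `region` as seen after rotating it by `angle`,
## computed by per-row horizontal shear + scale with linear interpolation
## (the vertical component of a small rotation cancels in a column sum).
## A deterministic per-row sub-pixel phase dither (golden-ratio sequence)
## makes the interpolation fractions near-uniform at every angle, angle 0
## included, so no candidate gets a sharpness bonus or penalty from how its
## shear happens to meet the pixel grid.
.shear_projection <- function(region, angle) {
  th <- angle * pi / 180
  nr <- nrow(region); w <- ncol(region)
  s <- sin(th) * (seq_len(nr) - (nr + 1) / 2)   # per-row shift, px
  dither <- (seq_len(nr) * 0.6180339887498949) %% 1
  j <- seq_len(w)
  proj <- numeric(w)
  cover <- numeric(w)
  for (r in seq_len(nr)) {
    u <- (j - s[r] - dither[r]) / cos(th)
    k <- floor(u); f <- u - k
    ok <- k >= 1L & k < w
    kk <- k[ok]
    proj[ok] <- proj[ok] + (1 - f[ok]) * region[r, kk] +
      f[ok] * region[r, kk + 1L]
    cover[ok] <- cover[ok] + 1
  }
  list(proj = proj, cover = cover)
}

#' Estimate the rotation correction from lane alignment
#'
#' Exhaustive grid search for the angle whose application maximises an
#' alignment score: the variance of the column-sum projection of the
#' band-bearing region (rows below the stacking/resolving border, columns
#' inside the gel, all channels summed) after rotating by that angle.
#' Vertical, well-aligned lanes produce the sharpest columnwise structure and
#' hence the largest projection variance. The region is inset from the
#' detected bounds by the maximal shear the search range can produce, so the
#' gel's own boundary edges never enter the score, and the variance is taken
#' over a central column window covered at every candidate angle, so all
#' angles are scored on identical support. Ties are broken toward the
#' smallest |angle|, then the negative angle.
#'
#' @param img a [gel_image].
#' @param geom its [gel_geometry].
#' @param search_range_deg two-element numeric, default `c(-5, 5)`.
#' @param step_deg grid resolution in degrees, default 0.1.
#' @return the correction angle in degrees: pass it to [rectify] to align the
#'   lanes.
#' @export
estimate_rotation <- function(img, geom, search_range_deg = c(-5, 5),
                              step_deg = 0.1) {
  h <- geom$bottom_row - geom$resolving_top_row
  w <- geom$right_col - geom$left_col
  inset <- ceiling(tan(max(abs(search_range_deg)) * pi / 180) * max(h, w)) + 2L
  if (2L * inset >= min(h, w) - 4L)
    inset <- max((min(h, w) - 4L) %/% 4L, 0L)
  region <- .combined(img)[(geom$resolving_top_row + inset):
                             (geom$bottom_row - inset),
                           (geom$left_col + inset):(geom$right_col - inset),
                           drop = FALSE]
  angles <- seq(search_range_deg[1L], search_range_deg[2L], by = step_deg)
  # central columns covered by every row at the largest search angle
  margin <- ceiling(tan(max(abs(angles)) * pi / 180) * nrow(region) / 2) + 3L
  keep <- (1L + margin):(ncol(region) - margin)
  if (length(keep) < 8L) keep <- seq_len(ncol(region))
  score <- vapply(angles, function(a)
    stats::var(.shear_projection(region, a)$proj[keep]), numeric(1L))
  best <- order(-score, abs(angles), angles)[1L]
  angles[best]
}
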