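#' Fit a fluorophore standard curve from a dilution series
#'
#' Ordinary least-squares line `intensity = slope * moles + intercept`. The
#' intercept is kept free: scanners have blank/background offsets, and a true
#' zero-offset series still recovers intercept 0.
#'
#' @param points data.frame with columns `moles` and `intensity` (>= 2
#'   distinct mole values).
#' @return an object of class `standard_curve` with `slope` (intensity per
#'   mole), `intercept`, `r_squared`, `points` and the underlying `lm` fit.
#' @export
fit_standard_curve <- function(points) {
  if (!all(c("moles", "intensity") %in% names(points)))
    stop("points must have columns 'moles' and 'intensity'")
  if (nrow(points) < 2L) stop("need >= 2 dilution points")
  if (length(unique(points$moles)) < 2L)
    stop("all mole values identical; cannot fit a line")
  fit <- stats::lm(intensity ~ moles, data = points)
  sst <- sum((points$intensity - mean(points$intensity))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 points = points, fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("standard_curve: intensity = ", format(x$slope), " x moles + ",
      format(x$intercept), "  (R^2 = ", format(round(x$r_squared, 4)),
      ", n = ", nrow(x$points), ")\n", sep = "")
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
predict.standard_curve <- function(object, moles, ...)
  object$intercept + object$slope * moles

#' @export
plot.standard_curve <- function(x, ...) {
  graphics::plot(x$points$moles, x$points$intensity,
                 xlab = "fluorophore amount (mol)", ylab = "intensity",
                 main = "fluorophore standard curve", pch = 19, ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Absolute degree of labelling from a band intensity
#'
#' Inverts the standard curve to the molar amount of fluorophore in the band
#' (or lane), then expresses it as a percentage of the protein molecules
#' loaded. The value legitimately exceeds 100 % when molecules carry more
#' than one label. With `n_lysine` given, the percentage of lysine residues
#' labelled is also reported: `dol_lysine_pct = dol_protein_pct / n_lysine`.
#'
#' @param band_intensity background-subtracted intensity, same units as the
#'   standard-curve intensities.
#' @param curve a `standard_curve` with positive slope.
#' @param protein_moles moles of protein loaded in the lane (> 0), same mole
#'   units as the curve.
#' @param n_lysine optional lysine residues per protein molecule (>= 1).
#' @return an object of class `labelling_result`: list with `fluor_moles`,
#'   `protein_moles`, `dol_protein_pct`, `dol_lysine_pct` (NA when
#'   `n_lysine` is missing).
#' @export
degree_of_labelling <- function(band_intensity, curve, protein_moles,
                                n_lysine = NULL) {
  if (!inherits(curve, "standard_curve")) stop("curve must be a standard_curve")
  if (curve$slope <= 0) stop("standard curve slope must be > 0")
  if (protein_moles <= 0) stop("protein_moles must be > 0")
  fm <- (band_intensity - curve$intercept) / curve$slope
  if (fm < 0) {
    warning("inferred fluorophore amount negative; clipping to 0")
    fm <- 0
  }
  dol <- 100 * fm / protein_moles
  structure(list(fluor_moles = fm, protein_moles = protein_moles,
                 dol_protein_pct = dol,
                 dol_lysine_pct = if (is.null(n_lysine)) NA_real_
                                  else lysine_labelling_fraction(dol, n_lysine)),
            class = "labelling_result")
}

#' @export
print.labelling_result <- function(x, ...) {
  cat("degree of labelling: ", format(round(x$dol_protein_pct, 1)),
      " % of protein molecules", sep = "")
  if (!is.na(x$dol_lysine_pct))
    cat(" (", format(round(x$dol_lysine_pct, 2)), " % of lysine residues)",
        sep = "")
  cat("\n")
  invisible(x)
}

#' Per-lysine labelling fraction
#'
#' Converts a per-protein degree of labelling to the percentage of lysine
#' residues carrying a label.
#'
#' @param dol_protein_pct per-protein degree of labelling in percent.
#' @param n_lysine lysine residues per molecule (>= 1).
#' @return `dol_protein_pct / n_lysine`, in percent.
#' @export
lysine_labelling_fraction <- function(dol_protein_pct, n_lysine) {
  if (n_lysine < 1) stop("n_lysine must be >= 1")
  dol_protein_pct / n_lysine
}
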