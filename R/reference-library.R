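#' Squared Pearson correlation of two mass profiles
#'
#' The comparison statistic for classifying modification patterns: the square
#' of the Pearson correlation of the two intensity vectors on their shared
#' mass grid. Pearson's affine invariance makes the score insensitive to
#' exposure scaling and constant offsets, which is what makes profiles
#' comparable across independently run gels without intensity normalisation.
#'
#' @param a,b `mass_profile` objects on identical grids, each with nonzero
#'   intensity variance.
#' @return squared correlation in [0, 1].
#' @export
profile_correlation <- function(a, b) {
  if (!identical(a$mass_grid, b$mass_grid)) stop("mass grid mismatch")
  if (stats::var(a$intensity) == 0 || stats::var(b$intensity) == 0)
    stop("zero-variance profile: correlation undefined")
  stats::cor(a$intensity, b$intensity)^2
}

#' Correlate query profiles against reference profiles
#'
#' @param queries,refs named lists of `mass_profile` objects on one shared
#'   grid.
#' @return an object of class `correlation_result`: list with `r2` (matrix,
#'   rows = queries, cols = references) and `best_match` (data.frame with
#'   `query`, `label`, `r2`, `tie`). Ties go to the first reference in
#'   library order and are flagged.
#' @export
correlate_sets <- function(queries, refs) {
  if (length(queries) == 0L || length(refs) == 0L)
    stop("empty query or reference set")
  if (is.null(names(queries))) names(queries) <- paste0("query_", seq_along(queries))
  if (is.null(names(refs))) names(refs) <- paste0("ref_", seq_along(refs))
  r2 <- matrix(NA_real_, length(queries), length(refs),
               dimnames = list(names(queries), names(refs)))
  for (i in seq_along(queries))
    for (j in seq_along(refs))
      r2[i, j] <- profile_correlation(queries[[i]], refs[[j]])
  best <- apply(r2, 1L, which.max)
  tie <- vapply(seq_along(best), function(i)
    sum(r2[i, ] == r2[i, best[i]]) > 1L, logical(1L))
  structure(list(r2 = r2,
                 best_match = data.frame(query = names(queries),
                                         label = colnames(r2)[best],
                                         r2 = r2[cbind(seq_along(best), best)],
                                         tie = tie)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("correlation_result: ", nrow(x$r2), " query x ", ncol(x$r2),
      " reference R^2 matrix\n", sep = "")
  print(round(x$r2, 3))
  invisible(x)
}

#' Digital reference library of mass profiles
#'
#' A labelled collection of mass-calibrated intensity profiles for defined
#' protein modifications (e.g. "native", "UV 10 min", "deglycosylated"),
#' stored on one shared mass grid, against which unknown samples are
#' classified by squared Pearson correlation.
#'
#' @param grid shared mass grid (see [mass_grid()]).
#' @param version schema version string.
#' @return an empty `reference_library`.
#' @export
reference_library <- function(grid = mass_grid(), version = "1.0") {
  structure(list(grid = grid, entries = list(), meta = list(),
                 version = version),
            class = "reference_library")
}

#' Add a labelled entry to a reference library
#'
#' @param lib a `reference_library`.
#' @param label unique condition label.
#' @param profile a `mass_profile` on the library's grid.
#' @return the updated library.
#' @export
add_entry <- function(lib, label, profile) {
  if (!identical(profile$mass_grid, lib$grid))
    stop("grid mismatch: entry not on the library's mass grid")
  if (label %in% names(lib$entries)) stop("duplicate label: ", label)
  lib$entries[[label]] <- profile$intensity
  lib$meta[[label]] <- profile$meta
  lib
}

#' @export
print.reference_library <- function(x, ...) {
  cat("reference_library (v", x$version, "): ", length(x$entries),
      " entries on ", length(x$grid), "-cell grid",
      if (length(x$entries)) paste0("\n  [", paste(names(x$entries),
                                                   collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

.lib_profiles <- function(lib) {
  lapply(lib$entries, function(v)
    structure(list(mass_grid = lib$grid, intensity = v, meta = list()),
              class = "mass_profile"))
}

#' Classify a query profile against a reference library
#'
#' @param query a `mass_profile` on the library's grid.
#' @param lib a `reference_library`.
#' @return data.frame of all library entries ranked by descending R^2:
#'   columns `label`, `r2`.
#' @export
classify_profile <- function(query, lib) {
  if (!identical(query$mass_grid, lib$grid)) stop("mass grid mismatch")
  if (length(lib$entries) == 0L) stop("empty reference library")
  r2 <- vapply(.lib_profiles(lib), function(p)
    profile_correlation(query, p), numeric(1L))
  out <- data.frame(label = names(r2), r2 = unname(r2))
  out[order(-out$r2), , drop = FALSE]
}

## full-precision number formatting so serialization round-trips bit-exactly
.fmt17 <- function(x) sprintf("%.17g", x)

#' Save a reference library to disk
#'
#' Writes a human-inspectable pair of files: `<path>` is a JSON manifest
#' (version, labels, per-entry metadata, grid span) and `<path>` minus its
#' extension plus `_matrix.csv` holds the grid and one intensity column per
#' entry, at full double precision so the round trip through
#' [load_library()] is lossless.
#'
#' @param lib a `reference_library`.
#' @param path manifest path (`.json`).
#' @return `path`, invisibly.
#' @export
save_library <- function(lib, path) {
  csv <- sub("\\.json$", "", path)
  csv <- paste0(csv, "_matrix.csv")
  manifest <- list(format = "fluorogel-reference-library",
                   version = lib$version,
                   labels = as.list(names(lib$entries)),
                   meta = lib$meta,
                   n_cells = length(lib$grid),
                   mass_max_kDa = lib$grid[1L],
                   mass_min_kDa = lib$grid[length(lib$grid)],
                   matrix_file = basename(csv))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  df <- c(list(mass_kDa = .fmt17(lib$grid)),
          lapply(lib$entries, .fmt17))
  names(df) <- c("mass_kDa", names(lib$entries))
  utils::write.csv(as.data.frame(df, check.names = FALSE), csv,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a reference library from disk
#'
#' @param path manifest path written by [save_library()].
#' @return the `reference_library`, bit-exact on grid and intensities.
#' @export
load_library <- function(path) {
  manifest <- jsonlite::read_json(path)
  if (!identical(manifest$format, "fluorogel-reference-library"))
    stop("not a reference-library manifest: ", path)
  if (!identical(manifest$version, "1.0"))
    stop("schema-version mismatch: ", manifest$version)
  csv <- file.path(dirname(path), manifest$matrix_file)
  mat <- utils::read.csv(csv, check.names = FALSE,
                         colClasses = "numeric")
  lib <- reference_library(grid = mat$mass_kDa, version = manifest$version)
  for (lab in unlist(manifest$labels)) {
    lib$entries[[lab]] <- mat[[lab]]
    lib$meta[[lab]] <- manifest$meta[[lab]]
  }
  lib
}
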