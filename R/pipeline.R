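#' Configuration for an end-to-end gel analysis
#'
#' Validates all analysis parameters up front, before any computation.
#'
#' @param image a [gel_image], or a path readable by [read_gel()].
#' @param channels channel labels (needed when `image` is a path).
#' @param sample_channel,marker_channel which channel carries the labelled
#'   sample and the molecular-weight ladder.
#' @param n_lanes number of lanes loaded on the gel.
#' @param marker_lanes indices of the ladder lane(s).
#' @param ladder marker masses in kDa, strictly decreasing.
#' @param min_prominence band-detection threshold (fraction of lane maximum).
#' @param background_window rolling-minimum baseline window, px.
#' @param grid common mass grid (see [mass_grid()]).
#' @param bleed_correct subtract estimated sample-channel bleed from the
#'   marker channel before marker detection.
#' @param rotation_search,rotation_step rotation-correction search range and
#'   grid step, degrees.
#' @param standards optional dilution-series data.frame (`moles`,
#'   `intensity`) or CSV path, enabling absolute quantification.
#' @param protein_nmol protein amount loaded per sample lane (nmol; scalar
#'   or one value per lane), required with `standards`.
#' @param n_lysine optional lysines per protein molecule, for the per-lysine
#'   labelling fraction.
#' @param library optional `reference_library` or manifest path, enabling
#'   classification of every sample lane.
#' @param out_dir optional directory; when given, every intermediate is
#'   persisted (JSON/CSV).
#' @return a validated `gel_run_config`.
#' @export
gel_run_config <- function(image, channels = c("700nm", "800nm"),
                           sample_channel = channels[1L],
                           marker_channel = channels[2L],
                           n_lanes, marker_lanes = 1L,
                           ladder = c(250, 150, 100, 75, 50, 37, 25),
                           min_prominence = 0.05, background_window = 51L,
                           grid = mass_grid(), bleed_correct = TRUE,
                           rotation_search = c(-5, 5), rotation_step = 0.1,
                           standards = NULL, protein_nmol = NULL,
                           n_lysine = NULL, library = NULL, out_dir = NULL) {
  if (is.character(image) && !all(file.exists(image)))
    stop("validation: image file not found: ", image)
  if (is.character(standards) && !file.exists(standards))
    stop("validation: standards file not found: ", standards)
  if (is.character(library) && !file.exists(library))
    stop("validation: library file not found: ", library)
  if (is.null(ladder))
    stop("validation: ladder spec required",
         if (!is.null(library)) " (classification needs calibrated profiles)")
  ladder <- ladder_spec(ladder)
  n_lanes <- as.integer(n_lanes)
  if (n_lanes < 1L) stop("validation: n_lanes must be >= 1")
  if (any(!marker_lanes %in% seq_len(n_lanes)))
    stop("validation: marker_lanes outside 1..n_lanes")
  if (min_prominence <= 0 || min_prominence > 1)
    stop("validation: min_prominence must be in (0, 1]")
  if (!is.null(standards) && is.null(protein_nmol))
    stop("validation: quantification requires protein_nmol")
  structure(list(image = image, channels = channels,
                 sample_channel = sample_channel,
                 marker_channel = marker_channel, n_lanes = n_lanes,
                 marker_lanes = marker_lanes, ladder = ladder,
                 min_prominence = min_prominence,
                 background_window = as.integer(background_window),
                 grid = grid, bleed_correct = isTRUE(bleed_correct),
                 rotation_search = rotation_search,
                 rotation_step = rotation_step,
                 standards = standards, protein_nmol = protein_nmol,
                 n_lysine = n_lysine, library = library, out_dir = out_dir),
            class = "gel_run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(name, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the full gel-analysis pipeline
#'
#' Executes, in order: image loading, gel-region detection, rotation
#' correction (with re-detection on the rectified image), optional
#' marker-channel bleed correction, lane segmentation, profile extraction
#' and background subtraction, marker-band detection and mass calibration,
#' rebinning of every sample lane onto the common mass axis, then optional
#' absolute quantification and reference-library classification. The run is
#' deterministic: identical config and inputs give identical outputs. With
#' `out_dir` set, every intermediate is persisted as JSON/CSV.
#'
#' @param cfg a [gel_run_config].
#' @param verbose print one line per stage.
#' @return an object of class `gel_analysis`: list with `geometry`,
#'   `rotation_deg`, `lanes`, `profiles` (per lane/channel, background-
#'   subtracted), `marker_bands`, `anchors`, `calibration`, `mass_profiles`
#'   (sample channel, one per non-marker lane), `band_masses` (detected
#'   sample bands with calibrated masses and extrapolation flags),
#'   `labelling` (optional), `classification` (optional), `config`.
#' @export
run_gel_analysis <- function(cfg, verbose = FALSE) {
  say <- function(...) if (verbose) message("[fluorogel] ", ...)

  img <- .stage("image_prep", {
    if (is.character(cfg$image)) read_gel(cfg$image, cfg$channels)
    else cfg$image
  })
  say("loaded image ", paste(dim(img), collapse = "x"))

  rough <- .stage("image_prep", detect_gel_region(img))
  angle <- .stage("image_prep",
                  estimate_rotation(img, rough, cfg$rotation_search,
                                    cfg$rotation_step))
  if (angle != 0) img <- .stage("image_prep", rectify(img, angle))
  geom <- .stage("image_prep", detect_gel_region(img))
  geom$rotation_deg <- angle
  say("geometry cols [", geom$left_col, ",", geom$right_col,
      "], border row ", geom$resolving_top_row, ", rotation ", angle, " deg")

  lanes <- .stage("lane_analysis", segment_lanes(geom, cfg$n_lanes))
  if (cfg$bleed_correct)
    img <- .stage("calibration",
                  correct_bleed(img, geom, lanes, cfg$marker_lanes,
                                cfg$sample_channel, cfg$marker_channel))

  profiles <- .stage("lane_analysis", {
    out <- list()
    for (ch in unique(c(cfg$sample_channel, cfg$marker_channel)))
      for (i in lanes$index)
        out[[paste0("lane", i, "_", ch)]] <-
          subtract_background(extract_profile(img, geom, lanes[i, ], ch),
                              cfg$background_window)
    out
  })

  cal <- .stage("calibration", {
    ml <- cfg$marker_lanes[1L]
    mp <- profiles[[paste0("lane", ml, "_", cfg$marker_channel)]]
    mbands <- detect_bands(mp, cfg$min_prominence)
    anchors <- assign_marker_masses(mbands, cfg$ladder)
    list(bands = mbands, anchors = anchors,
         curve = fit_calibration(anchors))
  })
  say("calibration: ", nrow(cal$anchors), " anchors")

  sample_lanes <- setdiff(lanes$index, cfg$marker_lanes)
  mass_profiles <- .stage("calibration", {
    out <- list()
    for (i in sample_lanes)
      out[[paste0("lane", i)]] <- profile_to_mass_axis(
        profiles[[paste0("lane", i, "_", cfg$sample_channel)]],
        cal$curve, cfg$grid,
        meta = list(lane = i, channel = cfg$sample_channel))
    out
  })

  band_masses <- .stage("calibration", {
    rows <- lapply(sample_lanes, function(i) {
      b <- detect_bands(profiles[[paste0("lane", i, "_",
                                         cfg$sample_channel)]],
                        cfg$min_prominence)
      if (nrow(b) == 0L) return(NULL)
      m <- predict(cal$curve, b$apex_distance)
      cbind(lane = i, b, mass_kDa = as.numeric(m),
            extrapolated = attr(m, "extrapolated"))
    })
    do.call(rbind, rows)
  })

  labelling <- NULL
  if (!is.null(cfg$standards)) labelling <- .stage("quantify", {
    pts <- if (is.character(cfg$standards))
      utils::read.csv(cfg$standards, comment.char = "#") else cfg$standards
    sc <- fit_standard_curve(pts)
    amounts <- rep_len(cfg$protein_nmol, length(sample_lanes))
    res <- list()
    for (k in seq_along(sample_lanes)) {
      i <- sample_lanes[k]
      pr <- profiles[[paste0("lane", i, "_", cfg$sample_channel)]]
      # unclipped residual total: zero-mean noise cancels instead of
      # accumulating as clipped positive residue
      tot <- if (!is.null(pr$residual_total)) pr$residual_total
             else sum(pr$intensity)
      res[[paste0("lane", i)]] <-
        degree_of_labelling(tot, sc, amounts[k], cfg$n_lysine)
    }
    list(curve = sc, lanes = res)
  })

  classification <- NULL
  if (!is.null(cfg$library)) classification <- .stage("reference_library", {
    lib <- if (is.character(cfg$library)) load_library(cfg$library)
           else cfg$library
    if (!identical(lib$grid, cfg$grid))
      stop("library grid differs from the run's mass grid")
    correlate_sets(mass_profiles, .lib_profiles(lib))
  })

  res <- structure(list(geometry = geom, rotation_deg = angle, lanes = lanes,
                        profiles = profiles, marker_bands = cal$bands,
                        anchors = cal$anchors, calibration = cal$curve,
                        mass_profiles = mass_profiles,
                        band_masses = band_masses, labelling = labelling,
                        classification = classification, config = cfg),
                   class = "gel_analysis")
  if (!is.null(cfg$out_dir)) .stage("orchestration",
                                    write_analysis(res, cfg$out_dir))
  res
}

#' Persist a gel analysis to a directory
#'
#' Writes `geometry.json`, `profiles.csv`, `bands.csv`, `anchors.csv`,
#' `calibration.json`, `mass_profiles.csv`, and, when present,
#' `labelling.json` and `classification.csv`. Deterministic: the same
#' analysis yields byte-identical files.
#'
#' @param res a `gel_analysis`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- res$geometry
  jsonlite::write_json(list(left_col = g$left_col, right_col = g$right_col,
                            resolving_top_row = g$resolving_top_row,
                            bottom_row = g$bottom_row,
                            rotation_deg = g$rotation_deg),
                       file.path(dir, "geometry.json"),
                       auto_unbox = TRUE, digits = NA)
  prof <- do.call(rbind, lapply(res$profiles, function(p)
    data.frame(lane_index = p$lane_index, channel = p$channel,
               distance_px = p$distance, intensity = .fmt17(p$intensity))))
  utils::write.csv(prof, file.path(dir, "profiles.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(res$band_masses)) {
    bm <- res$band_masses
    utils::write.csv(data.frame(lane_index = bm$lane,
                                apex_px = bm$apex_distance,
                                height = .fmt17(bm$height),
                                prominence = .fmt17(bm$prominence),
                                area = .fmt17(bm$area),
                                mass_kDa = .fmt17(bm$mass_kDa),
                                extrapolated = bm$extrapolated),
                     file.path(dir, "bands.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  utils::write.csv(data.frame(distance_px = res$anchors$distance,
                              mass_kDa = res$anchors$mass),
                   file.path(dir, "anchors.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(list(model = "piecewise-linear log10(mass) vs distance",
                            anchors = res$anchors),
                       file.path(dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  mp <- do.call(rbind, lapply(names(res$mass_profiles), function(nm) {
    p <- res$mass_profiles[[nm]]
    data.frame(lane = nm, mass_kDa = .fmt17(p$mass_grid),
               intensity = .fmt17(p$intensity))
  }))
  utils::write.csv(mp, file.path(dir, "mass_profiles.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(res$labelling))
    jsonlite::write_json(lapply(res$labelling$lanes, unclass),
                         file.path(dir, "labelling.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(res$classification))
    utils::write.csv(as.data.frame(res$classification$r2),
                     file.path(dir, "classification.csv"), quote = FALSE)
  invisible(dir)
}

#' @export
print.gel_analysis <- function(x, ...) {
  cat("gel_analysis:\n")
  print(x$geometry)
  cat("  ", nrow(x$lanes), " lanes; ", nrow(x$marker_bands),
      " marker bands; calibration over ",
      x$anchors$mass[nrow(x$anchors)], "-", x$anchors$mass[1L], " kDa\n",
      sep = "")
  if (!is.null(x$band_masses))
    cat("  ", nrow(x$band_masses), " sample bands calibrated\n", sep = "")
  if (!is.null(x$labelling))
    cat("  labelling quantified for ", length(x$labelling$lanes),
        " lanes\n", sep = "")
  if (!is.null(x$classification))
    cat("  classified against ", ncol(x$classification$r2),
        " references\n", sep = "")
  invisible(x)
}

#' @export
summary.gel_analysis <- function(object, ...) {
  print(object)
  if (!is.null(object$band_masses)) {
    cat("\nsample bands:\n")
    bm <- object$band_masses
    print(data.frame(lane = bm$lane, apex_px = bm$apex_distance,
                     mass_kDa = round(bm$mass_kDa, 1),
                     extrapolated = bm$extrapolated), row.names = FALSE)
  }
  if (!is.null(object$labelling))
    for (nm in names(object$labelling$lanes)) {
      cat(nm, ": ", sep = ""); print(object$labelling$lanes[[nm]])
    }
  if (!is.null(object$classification)) print(object$classification)
  invisible(object)
}

#' @export
plot.gel_analysis <- function(x, lanes = NULL, ...) {
  mp <- x$mass_profiles
  if (!is.null(lanes)) mp <- mp[paste0("lane", lanes)]
  ylim <- c(0, max(vapply(mp, function(p) max(p$intensity), numeric(1L))))
  first <- TRUE
  for (nm in names(mp)) {
    p <- mp[[nm]]
    if (first) {
      graphics::plot(p$mass_grid, p$intensity, type = "l", log = "x",
                     xlim = rev(range(p$mass_grid)), ylim = ylim,
                     xlab = "molecular mass (kDa)", ylab = "intensity", ...)
      first <- FALSE
    } else graphics::lines(p$mass_grid, p$intensity,
                           col = which(names(mp) == nm))
  }
  graphics::legend("topright", legend = names(mp), lty = 1,
                   col = seq_along(mp), bty = "n")
  invisible(x)
}
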