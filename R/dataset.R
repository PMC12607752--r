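#' Assemble per-capture feature frames into one record table
#'
#' Binds the per-image data.frames produced by [extract_features()] for a
#' single grid size into the tabular dataset (one row per subregion) and
#' checks integrity: every (image_index, cell_row, cell_col) key must be
#' unique and every sugar level must belong to the design.
#'
#' @param feature_frames list of data.frames for one grid size.
#' @param design the `acquisition_design`, for sugar-level validation.
#' @return a single data.frame.
#' @export
build_table <- function(feature_frames, design = NULL) {
  feature_frames <- Filter(Negate(is.null), feature_frames)
  if (length(feature_frames) == 0L) stop("no records to assemble")
  tab <- do.call(rbind, feature_frames)
  key <- paste(tab$image_index, tab$grid_size, tab$cell_row, tab$cell_col)
  if (anyDuplicated(key))
    stop("integrity error: duplicate (image_index, cell) records")
  if (!is.null(design) && !all(tab$sugar_pct %in% design$sugar_levels))
    stop("integrity error: sugar_pct outside design levels")
  rownames(tab) <- NULL
  tab
}

feature_columns <- function(table) grep("^band_[0-9]+$", names(table), value = TRUE)

feature_matrix <- function(table) {
  as.matrix(table[, feature_columns(table), drop = FALSE])
}

#' Write / read a spectral record table as CSV
#'
#' RFC 4180 CSV with a header row; feature columns `band_0001...` first,
#' metadata columns last. Values are written with 15 significant digits so
#' a round trip is exact to at least 12 significant digits.
#'
#' @param table record table.
#' @param path file path.
#' @return `write_spectral_csv`: invisibly, `path`;
#'   `read_spectral_csv`: the table.
#' @export
write_spectral_csv <- function(table, path) {
  out <- table
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 15, trim = TRUE,
                                                  scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_spectral_csv
#' @export
read_spectral_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Simulate a full synthetic jam dataset
#'
#' Runs the whole acquisition and preprocessing chain for every capture of
#' a design: scene rendering, white/dark calibration, SAM segmentation,
#' ROI + margin + grid subdivision, unit-norm mean-spectrum features; and
#' assembles one record table per requested grid size. Optionally also
#' derives broadband RGB features from the same scenes (using the identical
#' mask and grid), for RGB-versus-HSI comparisons. Per-capture seeds are
#' fanned out from the master seed, so the whole dataset is reproducible
#' from `(design, model, seed)`.
#'
#' @param design an [acquisition_design()].
#' @param model a [spectral_model()].
#' @param grids grid sizes to extract (subset of 1..5).
#' @param seed master integer seed.
#' @param noise_sd reflectance noise; defaults to the model's.
#' @param include_rgb also build RGB feature tables.
#' @param sam_threshold,margin,min_pixels forwarded to [extract_features()].
#' @return list with `hsi` (named list of tables, one per grid) and, when
#'   requested, `rgb` (same layout, 3 feature columns).
#' @export
simulate_dataset <- function(design, model, grids = 1:5, seed = 1L,
                             noise_sd = NULL, include_rgb = FALSE,
                             sam_threshold = 0.2, margin = 0.10,
                             min_pixels = 5L) {
  captures <- enumerate_design(design)
  set.seed(seed)
  capture_seeds <- sample.int(.Machine$integer.max - 1L, nrow(captures))

  hsi_frames <- rep(list(vector("list", nrow(captures))), length(grids))
  names(hsi_frames) <- paste0("g", grids)
  rgb_frames <- if (include_rgb) hsi_frames else NULL

  for (i in seq_len(nrow(captures))) {
    cap <- render_scene(captures[i, ], model, design,
                        seed = capture_seeds[i], noise_sd = noise_sd)
    cube <- calibrate_capture(cap)
    ref <- pick_reference(cube)
    mask <- sam_mask(cube, ref, sam_threshold)
    feats <- extract_features(cube, grids = grids, mask = mask,
                              margin = margin, min_pixels = min_pixels)
    for (gname in names(feats))
      hsi_frames[[gname]][[i]] <- feats[[gname]]
    if (include_rgb) {
      rgb_cube <- render_rgb(cube)
      rfeats <- extract_features(rgb_cube, grids = grids, mask = mask,
                                 margin = margin, min_pixels = min_pixels)
      for (gname in names(rfeats))
        rgb_frames[[gname]][[i]] <- rfeats[[gname]]
    }
  }

  out <- list(hsi = lapply(hsi_frames, build_table, design = design))
  if (include_rgb) out$rgb <- lapply(rgb_frames, build_table, design = design)
  out
}
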