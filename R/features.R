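#' Unit-norm mean-spectrum feature of one grid cell
#'
#' Averages the spectra of the segmented (jam) pixels inside the cell and
#' normalizes the mean to unit Euclidean length. Cells with fewer than
#' `min_pixels` segmented pixels, or whose mean spectrum has zero norm, are
#' dropped (return NULL with a `reason` attribute): a mean over a handful
#' of pixels is noise-dominated.
#'
#' @param cube a `reflectance_cube`.
#' @param mask logical matrix or `jam_mask` of segmented pixels.
#' @param cell an `roi` cell inside the cube.
#' @param min_pixels minimum segmented-pixel count to keep the cell.
#' @return list with `feature` (unit-norm band vector), `n_pixels`,
#'   `cell_row`, `cell_col`; or, when the cell is dropped, a
#'   `dropped_cell` object carrying the reason (test with [is_dropped()]).
#' @export
cell_feature <- function(cube, mask, cell, min_pixels = 5L) {
  stopifnot(inherits(cube, "reflectance_cube"), inherits(cell, "roi"))
  if (inherits(mask, "jam_mask")) mask <- mask$mask
  d <- dim(cube$R)
  if (cell$row_min < 0L || cell$col_min < 0L ||
      cell$row_max > d[1] || cell$col_max > d[2])
    stop("cell outside cube bounds")
  rows <- (cell$row_min + 1L):cell$row_max
  cols <- (cell$col_min + 1L):cell$col_max
  sub <- cube$R[rows, cols, , drop = FALSE]
  m <- mask[rows, cols, drop = FALSE]
  n <- sum(m)
  dropped <- function(reason) {
    structure(list(dropped = TRUE, reason = reason), class = "dropped_cell")
  }
  if (n < min_pixels)
    return(dropped(sprintf("cell (%d,%d): %d segmented pixels < min_pixels = %d",
                           attr(cell, "cell_row"), attr(cell, "cell_col"),
                           n, min_pixels)))
  P <- matrix(sub, length(rows) * length(cols), d[3])[as.vector(m), , drop = FALSE]
  mu <- colMeans(P)
  nrm <- sqrt(sum(mu^2))
  if (nrm == 0)
    return(dropped("zero-norm mean spectrum"))
  list(feature = mu / nrm, n_pixels = n,
       cell_row = attr(cell, "cell_row"), cell_col = attr(cell, "cell_col"))
}

#' Was a grid cell dropped by [cell_feature()]?
#' @param x a [cell_feature()] result.
#' @return TRUE for a dropped cell.
#' @export
is_dropped <- function(x) inherits(x, "dropped_cell")

#' Extract grid features from a calibrated capture
#'
#' Full per-image preprocessing: SAM segmentation (unless a mask is given),
#' bounding-box ROI, fractional margin, g x g subdivision, and one
#' unit-norm mean-spectrum record per surviving cell, for each requested
#' grid size.
#'
#' @param cube a `reflectance_cube` (with `meta` for record metadata).
#' @param grids integer vector of grid sizes, subset of 1..5.
#' @param mask optional precomputed `jam_mask`; by default SAM with a
#'   reference from [pick_reference()].
#' @param sam_threshold SAM threshold in radians.
#' @param margin per-side ROI margin fraction.
#' @param min_pixels minimum segmented pixels per kept cell.
#' @return named list (one element per grid size, `"g1"`, `"g2"`, ...) of
#'   data.frames with feature columns `band_0001...` plus metadata columns;
#'   attribute `dropped` lists reasons for dropped cells.
#' @export
extract_features <- function(cube, grids = 1:5, mask = NULL,
                             sam_threshold = 0.2, margin = 0.10,
                             min_pixels = 5L) {
  stopifnot(inherits(cube, "reflectance_cube"))
  if (is.null(mask)) {
    ref <- pick_reference(cube)
    mask <- sam_mask(cube, ref, sam_threshold)
  }
  box <- apply_margin(roi_from_mask(mask), margin)
  b <- dim(cube$R)[3]
  feat_names <- sprintf("band_%04d", seq_len(b))
  meta <- cube$meta
  dropped <- character(0)

  out <- lapply(grids, function(g) {
    cells <- subdivide(box, g)
    rows <- lapply(cells, function(cell) {
      f <- cell_feature(cube, mask, cell, min_pixels)
      if (is_dropped(f)) {
        dropped <<- c(dropped, f$reason)
        return(NULL)
      }
      rec <- as.list(f$feature)
      names(rec) <- feat_names
      rec$sugar_pct <- meta$sugar_pct
      rec$cultivar <- meta$cultivar
      rec$image_index <- meta$image_index
      rec$grid_size <- g
      rec$cell_row <- f$cell_row
      rec$cell_col <- f$cell_col
      rec$thickness <- meta$thickness
      rec$view <- meta$view
      rec$n_pixels <- f$n_pixels
      as.data.frame(rec, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  names(out) <- paste0("g", grids)
  attr(out, "dropped") <- dropped
  out
}

#' Derive a broadband RGB image from a reflectance cube
#'
#' Boxcar means over three visible windows: blue 400-500 nm, green
#' 500-600 nm, red 600-700 nm (half-open on the right except the red
#' window, which includes 700 nm). This emulates what a broadband colour
#' camera sees of the same scene and is the basis of the RGB-versus-HSI
#' comparison.
#'
#' @param cube a `reflectance_cube` (or plain h x w x bands array, in which
#'   case `wavelengths` must be supplied).
#' @param wavelengths band wavelengths; defaults to the cube's.
#' @return a `reflectance_cube` with 3 bands (1 = blue, 2 = green, 3 = red,
#'   nominal wavelengths 450/550/650 nm) inheriting the input's metadata
#'   and invalid mask.
#' @export
render_rgb <- function(cube, wavelengths = NULL) {
  if (inherits(cube, "reflectance_cube")) {
    if (is.null(wavelengths)) wavelengths <- cube$wavelengths
    R <- cube$R; invalid <- cube$invalid; meta <- cube$meta
  } else {
    R <- cube; invalid <- NULL; meta <- NULL
  }
  if (is.null(wavelengths)) stop("wavelengths required")
  d <- dim(R)
  windows <- list(blue = c(400, 500), green = c(500, 600), red = c(600, 700))
  chans <- lapply(names(windows), function(nm) {
    wlo <- windows[[nm]][1]; whi <- windows[[nm]][2]
    inb <- if (nm == "red") wavelengths >= wlo & wavelengths <= whi
           else wavelengths >= wlo & wavelengths < whi
    if (!any(inb))
      stop("coverage error: no bands inside the ", nm, " window [",
           wlo, ", ", whi, "] nm")
    matrix(rowMeans(matrix(R[, , inb, drop = FALSE], d[1] * d[2], sum(inb))),
           d[1], d[2])
  })
  rgb <- array(0, c(d[1], d[2], 3))
  for (k in 1:3) rgb[, , k] <- chans[[k]]
  structure(list(R = rgb,
                 invalid = if (is.null(invalid)) matrix(FALSE, d[1], d[2]) else invalid,
                 wavelengths = c(450, 550, 650), meta = meta),
            class = "reflectance_cube")
}
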