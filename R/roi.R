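#' Region of interest boxes
#'
#' ROI boxes are half-open integer intervals `[row_min, row_max) x
#' [col_min, col_max)` in 0-based pixel coordinates, the convention used
#' throughout this package.
#'
#' @param row_min,row_max,col_min,col_max box bounds, half-open, 0-based.
#' @return object of class `roi`.
#' @export
roi <- function(row_min, row_max, col_min, col_max) {
  if (row_max <= row_min || col_max <= col_min)
    stop("degenerate ROI: empty box")
  structure(list(row_min = as.integer(row_min), row_max = as.integer(row_max),
                 col_min = as.integer(col_min), col_max = as.integer(col_max)),
            class = "roi")
}

roi_height <- function(x) x$row_max - x$row_min
roi_width <- function(x) x$col_max - x$col_min

#' Tightest bounding box of a segmentation mask
#'
#' @param mask logical matrix or a `jam_mask`.
#' @return the smallest `roi` containing every TRUE pixel.
#' @export
roi_from_mask <- function(mask) {
  if (inherits(mask, "jam_mask")) mask <- mask$mask
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty ROI: mask has no jam pixels")
  roi(min(idx[, 1]) - 1L, max(idx[, 1]),
      min(idx[, 2]) - 1L, max(idx[, 2]))
}

#' Shrink an ROI inward by a fractional margin
#'
#' Removes `floor(fraction * height)` rows from top and bottom and
#' `floor(fraction * width)` columns from left and right, discarding dish
#' edges and residual background that survive the bounding box. The default
#' 10% margin matches the preprocessing this pipeline models.
#'
#' @param x an `roi`.
#' @param fraction per-side margin fraction in [0, 1); a margin that leaves
#'   no pixels raises a degenerate-ROI error.
#' @return the shrunk `roi`.
#' @export
apply_margin <- function(x, fraction = 0.10) {
  stopifnot(inherits(x, "roi"))
  if (fraction < 0 || fraction >= 1) stop("margin fraction must be in [0, 1)")
  dr <- floor(fraction * roi_height(x))
  dc <- floor(fraction * roi_width(x))
  if (x$row_min + dr >= x$row_max - dr || x$col_min + dc >= x$col_max - dc)
    stop("degenerate ROI: margin collapses the box")
  roi(x$row_min + dr, x$row_max - dr, x$col_min + dc, x$col_max - dc)
}

#' Subdivide an ROI into a g x g grid of cells
#'
#' Cells partition the ROI exactly: no overlap, no gap. When a dimension is
#' not divisible by g the remainder pixels are assigned one each to the
#' leading rows/columns, so cell sizes differ by at most one pixel per axis.
#'
#' @param x an `roi`.
#' @param g grid size, integer in 1..5.
#' @return list of g^2 cells in row-major order; each element is an `roi`
#'   with attributes `cell_row` and `cell_col` (0-based grid indices).
#' @export
subdivide <- function(x, g) {
  stopifnot(inherits(x, "roi"))
  g <- as.integer(g)
  if (g < 1L || g > 5L) stop("subdivision error: g must be in 1..5")
  h <- roi_height(x); w <- roi_width(x)
  if (h < g || w < g)
    stop("subdivision error: ROI ", h, "x", w, " smaller than grid ", g)
  splits <- function(n) {
    base <- n %/% g; rem <- n %% g
    sizes <- rep(base, g) + (seq_len(g) <= rem)
    cumsum(c(0L, sizes))
  }
  rs <- splits(h); cs <- splits(w)
  cells <- vector("list", g * g)
  k <- 1L
  for (i in seq_len(g)) for (j in seq_len(g)) {
    cell <- roi(x$row_min + rs[i], x$row_min + rs[i + 1L],
                x$col_min + cs[j], x$col_min + cs[j + 1L])
    attr(cell, "cell_row") <- i - 1L
    attr(cell, "cell_col") <- j - 1L
    cells[[k]] <- cell
    k <- k + 1L
  }
  cells
}
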