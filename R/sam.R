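#' Spectral angle between two spectra
#'
#' theta = arccos( p.r / (|p| |r|) ), the spectral angle mapper (SAM)
#' similarity: scale-invariant in either argument, symmetric, zero for
#' parallel spectra and pi/2 for orthogonal ones. The cosine is clamped to
#' [-1, 1] before arccos so floating-point round-off cannot produce NaN.
#'
#' @param p,r numeric spectra of equal length, neither all-zero.
#' @return angle in radians, in [0, pi].
#' @export
spectral_angle <- function(p, r) {
  if (length(p) != length(r))
    stop("spectra must have equal length")
  np <- sqrt(sum(p^2)); nr <- sqrt(sum(r^2))
  if (np == 0 || nr == 0)
    stop("undefined angle: zero spectrum")
  acos(min(max(sum(p * r) / (np * nr), -1), 1))
}

# Vectorized SAM: angles of every row of matrix `P` to reference `r`.
sam_angles <- function(P, r) {
  nr <- sqrt(sum(r^2))
  np <- sqrt(rowSums(P^2))
  cosv <- as.numeric(P %*% r) / (np * nr)
  ang <- acos(pmin(pmax(cosv, -1), 1))
  ang[np == 0] <- NA_real_
  ang
}

#' Pick a jam reference spectrum from a homogeneous region
#'
#' Returns the per-band median spectrum over a seed region, by default the
#' central 10% x 10% patch of the frame (jam is dish-centred in the
#' acquisitions, so the frame centre is jam with margin to spare). The
#' median makes the reference robust to isolated outlier pixels. Pixels
#' flagged invalid by calibration are excluded.
#'
#' @param cube a `reflectance_cube`.
#' @param seed_region optional list/vector `(row_min, row_max, col_min,
#'   col_max)`, half-open, 0-based; default central patch.
#' @return per-band reference spectrum.
#' @export
pick_reference <- function(cube, seed_region = NULL) {
  stopifnot(inherits(cube, "reflectance_cube"))
  d <- dim(cube$R)
  if (is.null(seed_region)) {
    hh <- max(1L, floor(0.1 * d[1])); ww <- max(1L, floor(0.1 * d[2]))
    r0 <- (d[1] - hh) %/% 2L; c0 <- (d[2] - ww) %/% 2L
    seed_region <- c(r0, r0 + hh, c0, c0 + ww)
  }
  sr <- as.integer(unlist(seed_region))
  if (sr[2] <= sr[1] || sr[4] <= sr[3])
    stop("empty seed region")
  if (sr[1] < 0L || sr[3] < 0L || sr[2] > d[1] || sr[4] > d[2])
    stop("seed region outside image bounds")
  rows <- (sr[1] + 1L):sr[2]; cols <- (sr[3] + 1L):sr[4]
  sub <- cube$R[rows, cols, , drop = FALSE]
  keep <- !cube$invalid[rows, cols, drop = FALSE]
  if (!any(keep)) stop("empty seed region: all pixels invalid")
  P <- matrix(sub, length(rows) * length(cols), d[3])[as.vector(keep), , drop = FALSE]
  apply(P, 2, stats::median)
}

#' Segment jam pixels with the spectral angle mapper
#'
#' Marks as jam every valid pixel whose spectral angle to the reference is
#' at or below the threshold (inclusive comparison; boundary pixels at
#' exactly the threshold count as jam). Default threshold 0.2 rad.
#'
#' @param cube a `reflectance_cube`.
#' @param reference per-band reference spectrum, e.g. [pick_reference()].
#' @param threshold angle threshold in radians, in (0, pi/2).
#' @return object of class `jam_mask`: list with `mask` (h x w logical),
#'   `reference`, `threshold`.
#' @export
sam_mask <- function(cube, reference, threshold = 0.2) {
  stopifnot(inherits(cube, "reflectance_cube"))
  d <- dim(cube$R)
  if (length(reference) != d[3])
    stop("reference length must equal band count")
  if (sum(reference^2) == 0) stop("undefined angle: zero reference spectrum")
  if (threshold <= 0 || threshold >= pi / 2)
    stop("threshold must lie in (0, pi/2)")
  P <- matrix(cube$R, d[1] * d[2], d[3])
  ang <- sam_angles(P, reference)
  mask <- matrix(!is.na(ang) & ang <= threshold, d[1], d[2])
  mask[cube$invalid] <- FALSE
  structure(list(mask = mask, reference = reference, threshold = threshold),
            class = "jam_mask")
}
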