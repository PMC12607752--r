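#' White/dark reference reflectance calibration
#'
#' Converts a raw intensity cube to unitless reflectance via
#' R = (I - D) / (W - D), the standard two-point radiometric correction for
#' push-broom VNIR cameras: the dark frame D captures sensor offset, the
#' white frame W the illumination profile over a reference surface. The
#' denominator is guarded by `eps`; pixels where any band has W - D <= eps
#' are flagged invalid (an imperfect white reference can otherwise make
#' overexposed areas masquerade as dark regions). Reflectance is clipped to
#' [0, clip_max]: values slightly above 1 are legitimate where the sample
#' outshines the reference dish.
#'
#' @param I raw intensity cube, h x w x bands array.
#' @param D dark reference: per-band vector or array matching `I`.
#' @param W white reference: same shape rules as `D`.
#' @param eps positive denominator guard (default 1e-6).
#' @param clip_max upper reflectance clip (default 2; use `Inf` to disable).
#' @param wavelengths optional band wavelengths carried on the result.
#' @param meta optional capture metadata carried on the result.
#' @return object of class `reflectance_cube`: list with `R` (h x w x bands),
#'   `invalid` (h x w logical), `wavelengths`, `meta`.
#' @export
calibrate <- function(I, D, W, eps = 1e-6, clip_max = 2,
                      wavelengths = NULL, meta = NULL) {
  if (length(dim(I)) != 3L) stop("dimension error: I must be h x w x bands")
  d <- dim(I); b <- d[3]
  if (eps <= 0) stop("eps must be positive")
  expand <- function(x, what) {
    if (is.null(dim(x))) {
      if (length(x) != b)
        stop("dimension error: ", what, " has ", length(x),
             " bands, I has ", b)
      aperm(array(x, c(b, d[1], d[2])), c(2, 3, 1))
    } else {
      if (!identical(dim(x), d))
        stop("dimension error: ", what, " shape differs from I")
      x
    }
  }
  Da <- expand(D, "D"); Wa <- expand(W, "W")
  denom <- Wa - Da
  invalid <- matrix(rowSums(matrix(denom <= eps, d[1] * d[2], b)) > 0, d[1], d[2])
  R <- (I - Da) / pmax(denom, eps)
  R <- pmin(pmax(R, 0), clip_max)
  structure(list(R = R, invalid = invalid,
                 wavelengths = wavelengths, meta = meta),
            class = "reflectance_cube")
}

#' Calibrate a raw synthetic capture
#'
#' Convenience wrapper applying [calibrate()] to a `raw_capture`, carrying
#' its wavelength axis and metadata through.
#'
#' @param capture a `raw_capture` from [render_scene()].
#' @param ... passed to [calibrate()].
#' @return a `reflectance_cube`.
#' @export
calibrate_capture <- function(capture, ...) {
  stopifnot(inherits(capture, "raw_capture"))
  out <- calibrate(capture$I, capture$D, capture$W,
                   wavelengths = capture$wavelengths,
                   meta = capture$meta, ...)
  out$truth <- capture$truth
  out
}
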