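#' Render a raw synthetic capture of a jam sample
#'
#' Places an ellipse of jam (pixel spectra drawn from the model for the
#' capture's cultivar and sugar level) on a bright white-dish background,
#' then synthesizes the sensor side of the acquisition: a per-band dark
#' current frame D, a white reference frame W and a raw intensity cube
#' I = D + R * (W - D), so that white/dark calibration recovers the
#' underlying reflectance exactly (up to the reflectance noise itself).
#' The jam ellipse covers roughly 40% of the frame and is centred, matching
#' dish-centred acquisitions.
#'
#' @param meta one row of [enumerate_design()] (or an equivalent list with
#'   `cultivar`, `sugar_pct`, `image_index`, `thickness`, `view`, `distance`).
#' @param model a [spectral_model()].
#' @param design the [acquisition_design()] the metadata came from.
#' @param seed integer seed; the capture is bit-reproducible given it.
#' @param noise_sd reflectance noise level; defaults to the model's.
#'
#' @return An object of class `raw_capture`: list with `I` (h x w x bands
#'   intensity array), `D` and `W` (per-band reference spectra),
#'   `wavelengths`, `meta`, and `truth` (the ground-truth jam mask and
#'   noiseless jam spectrum, for validation only).
#' @export
render_scene <- function(meta, model, design, seed = NULL, noise_sd = NULL) {
  stopifnot(inherits(model, "spectral_model"), inherits(design, "acquisition_design"))
  meta <- as.list(meta)
  if (is.null(noise_sd)) noise_sd <- model$noise_sd
  h <- design$spatial_size[1]; wd <- design$spatial_size[2]
  b <- design$bands
  if (h < 4L || wd < 4L)
    stop("geometry error: frame ", h, "x", wd, " too small to place a jam region")

  cy <- (h + 1) / 2; cx <- (wd + 1) / 2
  ry <- 0.35 * h; rx <- 0.35 * wd
  rows <- matrix(seq_len(h), h, wd)
  cols <- matrix(seq_len(wd), h, wd, byrow = TRUE)
  jam <- ((rows - cy) / ry)^2 + ((cols - cx) / rx)^2 <= 1
  if (sum(jam) < 0.10 * h * wd)
    stop("geometry error: jam region covers < 10% of the frame")

  if (!is.null(seed)) set.seed(seed)
  n_jam <- sum(jam); n_bg <- h * wd - n_jam
  mu_jam <- expected_spectrum(model, meta$cultivar, meta$sugar_pct)

  px <- matrix(0, h * wd, b)
  if (noise_sd > 0) {
    px[jam, ] <- matrix(mu_jam, n_jam, b, byrow = TRUE) +
      matrix(stats::rnorm(n_jam * b, sd = noise_sd), n_jam)
    px[!jam, ] <- matrix(model$background_spectrum, n_bg, b, byrow = TRUE) +
      matrix(stats::rnorm(n_bg * b, sd = noise_sd), n_bg)
    px <- pmin(pmax(px, 0), 1)
  } else {
    px[jam, ] <- matrix(mu_jam, n_jam, b, byrow = TRUE)
    px[!jam, ] <- matrix(model$background_spectrum, n_bg, b, byrow = TRUE)
  }
  R <- array(px, c(h, wd, b))

  # Sensor model: smooth illumination/gain curve and dark current, in counts.
  wl <- model$wavelengths
  gain <- 2000 * (0.55 + 0.45 * stats::plogis((wl - 520) / 90))
  D <- 60 + 0.04 * (wl - wl[1])
  W <- D + gain
  I <- sweep(R, 3, gain, `*`)
  I <- sweep(I, 3, D, `+`)

  structure(list(
    I = I, D = D, W = W,
    wavelengths = wl,
    meta = meta,
    truth = list(jam_mask = jam, jam_spectrum = mu_jam)
  ), class = "raw_capture")
}
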