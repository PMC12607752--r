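#' Generative spectral model for synthetic jam scenes
#'
#' Builds the reflectance model used by the scene simulator. Each cultivar
#' gets a smooth baseline reflectance template over the design's wavelength
#' axis with the shape characteristic of apple jam in the VNIR range: a
#' local minimum (pigment absorption dip) inside 400-500 nm and elevated
#' reflectance across 700-900 nm. Added sugar perturbs the baseline through
#' a compactly supported near-infrared bump whose amplitude grows linearly
#' with sugar concentration, so the expected spectrum is strictly monotone
#' in sugar at the affected bands and untouched elsewhere. The white dish
#' background is a bright, nearly flat template that is spectrally distant
#' (in angle) from any jam spectrum.
#'
#' @param design an [acquisition_design()].
#' @param sugar_window length-2 numeric, wavelength window (nm) carrying the
#'   sugar effect; default 780-960 nm, i.e. outside the visible range.
#' @param sugar_magnitude peak additive reflectance change at 100% sugar;
#'   the effect at concentration s is `sugar_magnitude * s / 100`.
#' @param sugar_direction `+1` (default) or `-1`, sign of the effect.
#' @param noise_sd per-band additive Gaussian noise standard deviation on
#'   reflectance (sensor noise); default 0.01.
#'
#' @return An object of class `spectral_model` with elements
#'   `wavelengths`, `cultivar_baselines` (bands x cultivars matrix),
#'   `sugar_window`, `sugar_magnitude`, `sugar_direction`, `sugar_bump`
#'   (unit-peak bump profile over bands), `noise_sd`, `background_spectrum`.
#' @export
spectral_model <- function(design,
                           sugar_window = c(780, 960),
                           sugar_magnitude = 0.12,
                           sugar_direction = 1,
                           noise_sd = 0.01) {
  stopifnot(inherits(design, "acquisition_design"))
  if (length(sugar_window) != 2L || sugar_window[2] <= sugar_window[1])
    stop("sugar_window must be an increasing wavelength pair")
  if (sugar_magnitude <= 0) stop("sugar_magnitude must be positive")
  if (!sugar_direction %in% c(-1, 1)) stop("sugar_direction must be +1 or -1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")

  w <- design_wavelengths(design)
  n_cult <- length(design$cultivars)

  # Cultivar baselines: per-cultivar offset + sigmoidal NIR shoulder at
  # ~700 nm - Gaussian absorption dip near 450 nm - roll-off beyond 950 nm.
  # Parameters drift deterministically with cultivar index so templates are
  # distinct but share the family shape.
  baselines <- vapply(seq_len(n_cult), function(i) {
    base <- 0.26 + 0.025 * (i - 1)
    rise <- 0.28 + 0.010 * ((i - 1) %% 3)
    dip_depth <- 0.16 + 0.012 * ((i - 1) %% 4)
    dip_centre <- 445 + 3 * (i - 1)
    t <- base +
      rise * stats::plogis((w - 700) / 35) -
      dip_depth * exp(-((w - dip_centre) / 35)^2) -
      0.10 * stats::plogis((w - 955) / 25)
    t
  }, numeric(length(w)))
  colnames(baselines) <- design$cultivars
  if (any(baselines <= 0) || any(baselines >= 1))
    stop("internal: baseline templates left [0, 1]")

  # Unit-peak Hann bump with compact support: exactly zero outside the window.
  centre <- mean(sugar_window)
  width <- diff(sugar_window)
  inside <- w > sugar_window[1] & w < sugar_window[2]
  bump <- numeric(length(w))
  bump[inside] <- 0.5 * (1 + cos(2 * pi * (w[inside] - centre) / width))

  background <- 0.92 - 2e-5 * (w - 400)

  structure(list(
    wavelengths = w,
    cultivar_baselines = baselines,
    sugar_window = as.numeric(sugar_window),
    sugar_magnitude = sugar_magnitude,
    sugar_direction = sugar_direction,
    sugar_bump = bump,
    noise_sd = noise_sd,
    background_spectrum = background
  ), class = "spectral_model")
}

#' Expected (noiseless) jam reflectance spectrum
#'
#' Baseline template of the cultivar plus the sugar-dependent NIR bump,
#' without sensor noise. This is the oracle the simulator, calibration and
#' feature extraction are tested against.
#'
#' @param model a `spectral_model`.
#' @param cultivar cultivar name present in the model.
#' @param sugar_pct sugar concentration in (0, 100), percent w/w.
#' @return numeric reflectance vector over the model's bands, in [0, 1].
#' @export
expected_spectrum <- function(model, cultivar, sugar_pct) {
  stopifnot(inherits(model, "spectral_model"))
  if (!cultivar %in% colnames(model$cultivar_baselines))
    stop("unknown cultivar: ", cultivar)
  if (sugar_pct <= 0 || sugar_pct >= 100)
    stop("sugar_pct must lie in (0, 100)")
  s <- model$cultivar_baselines[, cultivar] +
    model$sugar_direction * model$sugar_magnitude * (sugar_pct / 100) * model$sugar_bump
  pmin(pmax(s, 0), 1)
}

#' Simulate noisy jam reflectance spectra
#'
#' Draws `n` reflectance spectra: the expected spectrum of
#' [expected_spectrum()] plus i.i.d. per-band Gaussian noise of standard
#' deviation `noise_sd`, clipped to [0, 1]. Deterministic given `seed`.
#'
#' @inheritParams expected_spectrum
#' @param n number of spectra to draw.
#' @param seed optional integer seed; when supplied the draw is reproducible.
#' @param noise_sd noise level; defaults to the model's `noise_sd`.
#' @return if `n == 1` a numeric vector of length bands, else an
#'   `n x bands` matrix.
#' @export
simulate_spectrum <- function(model, cultivar, sugar_pct, n = 1L,
                              seed = NULL, noise_sd = NULL) {
  mu <- expected_spectrum(model, cultivar, sugar_pct)
  if (is.null(noise_sd)) noise_sd <- model$noise_sd
  if (!is.null(seed)) set.seed(seed)
  b <- length(mu)
  if (noise_sd > 0) {
    x <- matrix(mu, nrow = n, ncol = b, byrow = TRUE) +
      matrix(stats::rnorm(n * b, sd = noise_sd), nrow = n)
    x <- pmin(pmax(x, 0), 1)
  } else {
    x <- matrix(mu, nrow = n, ncol = b, byrow = TRUE)
  }
  if (n == 1L) drop(x) else x
}
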