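#' Acquisition design for a jam imaging campaign
#'
#' Describes the factorial layout of a VNIR hyperspectral acquisition: which
#' apple cultivars were processed into jam, which sugar concentrations
#' (% w/w) were prepared, how many camera views were taken per sample
#' thickness, and the camera's spectral and spatial configuration. The
#' default reproduces the campaign this pipeline targets: 8 cultivars,
#' 11 sugar levels from 25% to 75% in 5% steps, and layer thicknesses of
#' 0.5/1/2 cm imaged from 6, 7 and 7 views respectively, i.e. 1760 captures.
#'
#' @param cultivars character vector of cultivar names.
#' @param sugar_levels strictly increasing sugar concentrations in (0, 100),
#'   percent w/w.
#' @param views_per_thickness named numeric vector mapping thickness in cm
#'   (names) to the number of views acquired at that thickness.
#' @param distances camera distances in cm, cycled over views and carried as
#'   per-view metadata only.
#' @param bands number of spectral bands (>= 4).
#' @param wavelength_range length-2 numeric, min and max wavelength in nm.
#' @param spatial_size height and width of a frame in pixels.
#'
#' @return An object of class `acquisition_design`.
#' @seealso [enumerate_design()], [spectral_model()], [simulate_dataset()]
#' @export
#' @examples
#' d <- acquisition_design()
#' nrow(enumerate_design(d))  # 1760
acquisition_design <- function(cultivars = default_cultivars(),
                               sugar_levels = seq(25, 75, by = 5),
                               views_per_thickness = c("0.5" = 6, "1" = 7, "2" = 7),
                               distances = c(20, 30, 40),
                               bands = 204L,
                               wavelength_range = c(400, 1000),
                               spatial_size = c(64L, 64L)) {
  if (length(cultivars) < 1L || anyDuplicated(cultivars))
    stop("invalid design: need at least one cultivar, without duplicates")
  if (length(sugar_levels) < 1L)
    stop("invalid design: need at least one sugar level")
  if (any(diff(sugar_levels) <= 0))
    stop("invalid design: sugar_levels must be strictly increasing")
  if (any(sugar_levels <= 0 | sugar_levels >= 100))
    stop("invalid design: sugar_levels must lie in (0, 100)")
  if (length(views_per_thickness) < 1L || any(views_per_thickness < 1))
    stop("invalid design: every thickness needs >= 1 view")
  if (is.null(names(views_per_thickness)) || any(!nzchar(names(views_per_thickness))))
    stop("invalid design: views_per_thickness must be named by thickness (cm)")
  bands <- as.integer(bands)
  if (bands < 4L) stop("invalid design: bands must be >= 4")
  if (length(wavelength_range) != 2L || wavelength_range[2] <= wavelength_range[1])
    stop("invalid design: wavelength max must exceed min")
  spatial_size <- as.integer(spatial_size)
  if (length(spatial_size) != 2L || any(spatial_size < 1L))
    stop("invalid design: spatial_size must be two positive integers")

  structure(list(
    cultivars = as.character(cultivars),
    sugar_levels = as.numeric(sugar_levels),
    views_per_thickness = views_per_thickness,
    distances = as.numeric(distances),
    bands = bands,
    wavelength_range = as.numeric(wavelength_range),
    spatial_size = spatial_size
  ), class = "acquisition_design")
}

#' The eight Central Asian apple cultivars of the default campaign
#' @return character vector of cultivar names.
#' @export
default_cultivars <- function() {
  c("aport", "gala", "golden", "granny_smith",
    "idared", "prince", "simirenko", "starcrimson")
}

#' Wavelength axis of a design
#'
#' Band centres are spaced evenly across the design's wavelength range.
#'
#' @param design an `acquisition_design`.
#' @return numeric vector of band-centre wavelengths in nm.
#' @export
design_wavelengths <- function(design) {
  stopifnot(inherits(design, "acquisition_design"))
  seq(design$wavelength_range[1], design$wavelength_range[2],
      length.out = design$bands)
}

#' Enumerate every capture of an acquisition design
#'
#' Expands the factorial design into one row per capture: every combination
#' of cultivar, sugar level, thickness and view. The number of rows equals
#' |cultivars| x |sugar_levels| x sum(views per thickness); for the default
#' design this is 8 x 11 x (6 + 7 + 7) = 1760. Camera distance is assigned
#' by cycling the design's distance list over the view index and is metadata
#' only.
#'
#' @param design an `acquisition_design`.
#' @return data.frame with columns `image_index`, `cultivar`, `sugar_pct`,
#'   `thickness`, `view`, `distance`.
#' @export
enumerate_design <- function(design) {
  stopifnot(inherits(design, "acquisition_design"))
  thick <- as.numeric(names(design$views_per_thickness))
  views <- lapply(seq_along(thick), function(i) {
    v <- seq_len(design$views_per_thickness[[i]])
    data.frame(thickness = thick[i], view = v,
               distance = design$distances[(v - 1L) %% length(design$distances) + 1L])
  })
  views <- do.call(rbind, views)

  grid <- expand.grid(view_row = seq_len(nrow(views)),
                      sugar_pct = design$sugar_levels,
                      cultivar = design$cultivars,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(
    image_index = seq_len(nrow(grid)),
    cultivar = grid$cultivar,
    sugar_pct = grid$sugar_pct,
    thickness = views$thickness[grid$view_row],
    view = views$view[grid$view_row],
    distance = views$distance[grid$view_row]
  )
  out
}
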