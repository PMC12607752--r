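#' Min-max scaler fitted on the training fold only
#'
#' Learns per-feature and target minima/maxima from training records and
#' maps them affinely to [0, 1]. Validation and test records transformed
#' with a training-fitted scaler may fall outside [0, 1]; they are not
#' clipped. Fitting on anything but the training fold is a leakage bug, so
#' the scaler records the provenance fold and model-training routines
#' assert it.
#'
#' @param X training feature matrix (records x features).
#' @param y training target vector (% sugar).
#' @param provenance fold the scaler was fitted on (recorded, asserted
#'   downstream).
#' @return object of class `minmax_scaler`.
#' @export
fit_scaler <- function(X, y, provenance = "train") {
  X <- as.matrix(X)
  fmin <- apply(X, 2, min); fmax <- apply(X, 2, max)
  const <- fmax - fmin <= 0
  if (any(const))
    stop("degenerate scale in column(s): ",
         paste(colnames(X)[const], collapse = ", "))
  if (length(unique(y)) < 2L)
    stop("degenerate scale in target: fewer than 2 distinct values")
  structure(list(feat_min = fmin, feat_max = fmax,
                 y_min = min(y), y_max = max(y),
                 provenance = provenance),
            class = "minmax_scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted `minmax_scaler`.
#' @export
apply_scaler <- function(scaler, X) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  X <- as.matrix(X)
  sweep(sweep(X, 2, scaler$feat_min, `-`), 2,
        scaler$feat_max - scaler$feat_min, `/`)
}

#' @rdname fit_scaler
#' @export
scale_target <- function(scaler, y) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  (y - scaler$y_min) / (scaler$y_max - scaler$y_min)
}

#' @rdname fit_scaler
#' @param y_scaled scaled targets to map back to percent sugar.
#' @export
invert_target <- function(scaler, y_scaled) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  y_scaled * (scaler$y_max - scaler$y_min) + scaler$y_min
}
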