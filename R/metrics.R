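#' Regression metrics: R-squared, RMSE, MAE
#'
#' r2 = 1 - SS_res / SS_tot (SS_tot about the mean of `y_true`),
#' rmse = sqrt(mean squared error), mae = mean absolute error. R-squared is
#' undefined for a constant truth vector; in that case `r2` is NA and a
#' warning is raised (rmse/mae are still returned).
#'
#' @param y_true,y_pred numeric vectors of equal, nonzero length.
#' @return named list with `r2`, `rmse`, `mae`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal nonzero length")
  res <- y_true - y_pred
  rmse <- sqrt(mean(res^2))
  mae <- mean(abs(res))
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    warning("r2 undefined: y_true is constant")
    r2 <- NA_real_
  } else {
    r2 <- 1 - sum(res^2) / ss_tot
  }
  list(r2 = r2, rmse = rmse, mae = mae)
}

#' Mean absolute error per sugar level
#'
#' MAE restricted to the records of each concentration level; levels with
#' no records are omitted. This is the per-class error profile used to
#' compare splitting strategies.
#'
#' @param y_true true sugar % (every value must be one of `levels`).
#' @param y_pred predictions.
#' @param levels the design's sugar levels.
#' @return named numeric vector, one MAE per represented level.
#' @export
per_class_mae <- function(y_true, y_pred, levels) {
  if (!all(y_true %in% levels))
    stop("y_true contains values outside the given levels")
  present <- levels[levels %in% y_true]
  out <- vapply(present, function(lv) {
    i <- y_true == lv
    mean(abs(y_true[i] - y_pred[i]))
  }, numeric(1))
  names(out) <- format(present, trim = TRUE)
  out
}
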