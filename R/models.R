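#' Model configurations
#'
#' Fixed hyperparameter sets for the two classical baselines. The SVM uses
#' an RBF kernel with C = 110, epsilon = 0.1 and gamma = 0.01 (gamma is the
#' literal kernel coefficient, not a data-driven heuristic). Gradient
#' boosting uses learning rate 0.10, depth 5, column subsampling 0.95, up
#' to 400 rounds with early stopping after 40 rounds without validation
#' RMSE improvement, squared-error objective.
#'
#' @param cost,epsilon,gamma SVM hyperparameters (all positive).
#' @return a config list.
#' @export
svm_config <- function(cost = 110, epsilon = 0.1, gamma = 0.01) {
  stopifnot(cost > 0, epsilon > 0, gamma > 0)
  list(kernel = "radial", cost = cost, epsilon = epsilon, gamma = gamma)
}

#' @rdname svm_config
#' @param learning_rate,max_depth,colsample,max_rounds,early_stop_rounds
#'   boosting hyperparameters.
#' @export
xgb_config <- function(learning_rate = 0.10, max_depth = 5L, colsample = 0.95,
                       max_rounds = 400L, early_stop_rounds = 40L) {
  stopifnot(max_rounds >= early_stop_rounds)
  list(learning_rate = learning_rate, max_depth = as.integer(max_depth),
       colsample = colsample, max_rounds = as.integer(max_rounds),
       early_stop_rounds = as.integer(early_stop_rounds),
       objective = "reg:squarederror")
}

# Shared fold extraction + scaling front-end for all three model types.
# Fits the min-max scaler on the training fold only.
prepare_folds <- function(table, split) {
  stopifnot(inherits(split, "split_assignment"))
  if (length(split$fold) != nrow(table))
    stop("split does not match table: ", length(split$fold), " folds for ",
         nrow(table), " records")
  X <- feature_matrix(table)
  y <- table$sugar_pct
  tr <- split$fold == "train"
  if (!any(tr)) stop("empty training fold")
  scaler <- fit_scaler(X[tr, , drop = FALSE], y[tr], provenance = "train")
  list(X = X, y = y, scaler = scaler,
       train = which(tr), val = which(split$fold == "val"),
       test = which(split$fold == "test"))
}

assert_scaler_provenance <- function(scaler) {
  if (!identical(scaler$provenance, "train"))
    stop("leakage: scaler was fitted on fold '", scaler$provenance, "'")
  invisible(TRUE)
}

#' Train the RBF support vector regressor
#'
#' Min-max scales features and targets on the training fold, fits an
#' epsilon-insensitive support vector regression with an RBF kernel, and
#' returns a model whose predictions are reported back on the percent
#' sugar scale.
#'
#' @param table record table.
#' @param split a `split_assignment` for the table.
#' @param config an [svm_config()].
#' @return object of class `jam_model`.
#' @export
train_svm <- function(table, split, config = svm_config()) {
  pf <- prepare_folds(table, split)
  assert_scaler_provenance(pf$scaler)
  Xs <- apply_scaler(pf$scaler, pf$X[pf$train, , drop = FALSE])
  ys <- scale_target(pf$scaler, pf$y[pf$train])
  fit <- e1071::svm(x = Xs, y = ys, type = "eps-regression",
                    kernel = config$kernel, cost = config$cost,
                    epsilon = config$epsilon, gamma = config$gamma,
                    scale = FALSE)
  structure(list(kind = "svm", fit = fit, scaler = pf$scaler,
                 config = config),
            class = "jam_model")
}

#' Train the gradient-boosted tree regressor
#'
#' Requires a validation fold: boosting stops early once validation RMSE
#' has not improved for `early_stop_rounds` rounds. Deterministic given
#' `seed` (single thread).
#'
#' @inheritParams train_svm
#' @param config an [xgb_config()].
#' @param seed integer seed for column subsampling.
#' @return a `jam_model`.
#' @export
train_xgb <- function(table, split, config = xgb_config(), seed = 1L) {
  pf <- prepare_folds(table, split)
  assert_scaler_provenance(pf$scaler)
  if (length(pf$val) == 0L)
    stop("missing validation fold: early stopping needs one")
  Xtr <- apply_scaler(pf$scaler, pf$X[pf$train, , drop = FALSE])
  ytr <- scale_target(pf$scaler, pf$y[pf$train])
  Xva <- apply_scaler(pf$scaler, pf$X[pf$val, , drop = FALSE])
  yva <- scale_target(pf$scaler, pf$y[pf$val])
  dtr <- xgboost::xgb.DMatrix(Xtr, label = ytr)
  dva <- xgboost::xgb.DMatrix(Xva, label = yva)
  params <- xgboost::xgb.params(
    objective = config$objective,
    eta = config$learning_rate,
    max_depth = config$max_depth,
    colsample_bytree = config$colsample,
    nthread = 1L,
    seed = as.integer(seed)
  )
  fit <- xgboost::xgb.train(params = params, data = dtr,
                            nrounds = config$max_rounds,
                            evals = list(val = dva),
                            early_stopping_rounds = config$early_stop_rounds,
                            verbose = 0)
  structure(list(kind = "xgb", fit = fit, scaler = pf$scaler,
                 config = config,
                 best_iteration = xgboost::xgb.attr(fit, "best_iteration")),
            class = "jam_model")
}

#' Predict sugar concentration from a trained model
#'
#' Applies the model's training-fitted scaler to the records' features,
#' predicts on the scaled scale, and inverts the target scaling, so
#' predictions are always percent sugar.
#'
#' @param object a `jam_model`.
#' @param newdata record table (or feature matrix).
#' @param ... unused.
#' @return numeric vector of predicted sugar % w/w.
#' @export
predict.jam_model <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) feature_matrix(newdata) else as.matrix(newdata)
  Xs <- apply_scaler(object$scaler, X)
  ys <- switch(object$kind,
    svm = as.numeric(stats::predict(object$fit, Xs)),
    xgb = as.numeric(stats::predict(object$fit, xgboost::xgb.DMatrix(Xs))),
    resnet = resnet_predict_scaled(object, Xs),
    stop("unknown model kind: ", object$kind))
  invert_target(object$scaler, ys)
}
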