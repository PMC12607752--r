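#' Train one model on one table under one split
#'
#' Dispatch front-end shared by the sweep: `"svm"`, `"xgb"` or `"resnet"`.
#'
#' @param model one of `"svm"`, `"xgb"`, `"resnet"`.
#' @param table record table.
#' @param split a `split_assignment`.
#' @param seed integer seed (ignored by the deterministic SVM).
#' @param batch_size ResNet minibatch size.
#' @param resnet_cfg,svm_cfg,xgb_cfg optional config overrides.
#' @return a `jam_model`.
#' @export
train_model <- function(model, table, split, seed = 1L, batch_size = 64L,
                        resnet_cfg = resnet_config(), svm_cfg = svm_config(),
                        xgb_cfg = xgb_config()) {
  switch(model,
    svm = train_svm(table, split, svm_cfg),
    xgb = train_xgb(table, split, xgb_cfg, seed = seed),
    resnet = train_resnet(table, split, resnet_cfg,
                          batch_size = batch_size, seed = seed),
    stop("unknown model: ", model))
}

#' Sweep models x grids x runs on prebuilt record tables
#'
#' Trains every requested model on every requested grid table `n_runs`
#' times (run seeds fanned out from the master seed), evaluates each run on
#' the evaluation fold, and appends one mean-aggregated row per
#' (model, grid, batch size) group. Per-run rows are retained; the
#' aggregate row has `run = NA` and `aggregate = TRUE`. Predictions and
#' per-sugar-level MAE profiles of every run are returned alongside for
#' scatter and per-class reporting. Deterministic given the master seed.
#'
#' @param tables named list of record tables (`"g1"`, `"g2"`, ... as from
#'   [simulate_dataset()]).
#' @param split_fn function(table) -> `split_assignment`; applied per grid
#'   so folds always match the table being swept.
#' @param models subset of `c("svm", "xgb", "resnet")`.
#' @param grids grid sizes to sweep (must exist in `tables`).
#' @param batch_sizes ResNet batch sizes to sweep (other models ignore
#'   batch size and are swept once with `batch_size = NA`).
#' @param n_runs independent repetitions per configuration.
#' @param seed master seed.
#' @param eval_fold fold used for metric computation (default `"val"`;
#'   use `"test"` for final reporting).
#' @param keep_predictions retain per-run predictions for scatter plots.
#' @param ... forwarded to [train_model()] (config overrides).
#' @return object of class `sweep_result`: list with `results` (per-run +
#'   aggregate rows), `per_class` (per-level MAE rows), `predictions`
#'   (optional), and `manifest` (seeds, folds, configuration).
#' @export
run_sweep <- function(tables, split_fn, models = c("svm", "xgb", "resnet"),
                      grids = as.integer(sub("^g", "", names(tables))),
                      batch_sizes = 64L, n_runs = 5L, seed = 1L,
                      eval_fold = c("val", "test"),
                      keep_predictions = TRUE, ...) {
  eval_fold <- match.arg(eval_fold)
  models <- match.arg(models, c("svm", "xgb", "resnet"), several.ok = TRUE)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)

  rows <- list(); preds <- list(); pclass <- list()
  for (g in grids) {
    gname <- paste0("g", g)
    table <- tables[[gname]]
    if (is.null(table)) stop("missing table for grid ", g)
    split <- split_fn(table)
    hold <- split$fold == eval_fold
    y_true <- table$sugar_pct[hold]
    levels_all <- sort(unique(table$sugar_pct))
    for (model in models) {
      bsizes <- if (model == "resnet") batch_sizes else NA_integer_
      for (bs in bsizes) {
        for (run in seq_len(n_runs)) {
          fit <- train_model(model, table, split, seed = run_seeds[run],
                             batch_size = if (is.na(bs)) 64L else bs, ...)
          y_pred <- predict(fit, table[hold, , drop = FALSE])
          m <- regression_metrics(y_true, y_pred)
          rows[[length(rows) + 1L]] <- data.frame(
            model = model, grid = g, batch_size = bs, run = run,
            aggregate = FALSE, r2 = m$r2, rmse = m$rmse, mae = m$mae)
          pc <- per_class_mae(y_true, y_pred, levels_all)
          pclass[[length(pclass) + 1L]] <- data.frame(
            model = model, grid = g, batch_size = bs, run = run,
            sugar_pct = levels_all[levels_all %in% y_true],
            mae = as.numeric(pc))
          if (keep_predictions)
            preds[[length(preds) + 1L]] <- data.frame(
              model = model, grid = g, batch_size = bs, run = run,
              y_true = y_true, y_pred = y_pred)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  agg_key <- paste(results$model, results$grid, results$batch_size)
  agg <- do.call(rbind, lapply(
    split(results, agg_key),
    function(d) data.frame(model = d$model[1], grid = d$grid[1],
                           batch_size = d$batch_size[1], run = NA_integer_,
                           aggregate = TRUE, r2 = mean(d$r2),
                           rmse = mean(d$rmse), mae = mean(d$mae))))
  rownames(agg) <- NULL
  structure(list(
    results = rbind(results, agg),
    per_class = do.call(rbind, pclass),
    predictions = if (keep_predictions) do.call(rbind, preds) else NULL,
    manifest = list(seed = seed, run_seeds = run_seeds, models = models,
                    grids = grids, batch_sizes = batch_sizes,
                    n_runs = n_runs, eval_fold = eval_fold)
  ), class = "sweep_result")
}

#' Paired RGB-versus-hyperspectral comparison
#'
#' Runs the identical sweep on hyperspectral feature tables and on
#' broadband RGB feature tables derived from the same scenes (same masks,
#' same grids, same splits, same seeds) and pairs the aggregate metrics per
#' (model, grid, batch size). When the sugar signal lives in the
#' near-infrared, the RGB arm is blind to it and its R-squared collapses
#' while the hyperspectral arm's does not.
#'
#' @param hsi_tables,rgb_tables table lists as returned in
#'   [simulate_dataset()]'s `hsi` and `rgb` slots.
#' @param ... forwarded to [run_sweep()] (same arguments for both arms).
#' @return list with the two `sweep_result`s and `paired`, a data.frame of
#'   aggregate metrics with `_hsi` / `_rgb` suffixes.
#' @export
rgb_vs_hsi <- function(hsi_tables, rgb_tables, ...) {
  hsi <- run_sweep(hsi_tables, ...)
  rgb <- run_sweep(rgb_tables, ...)
  pick <- function(s) {
    d <- s$results[s$results$aggregate, c("model", "grid", "batch_size",
                                          "r2", "rmse", "mae")]
    rownames(d) <- NULL
    d
  }
  paired <- merge(pick(hsi), pick(rgb),
                  by = c("model", "grid", "batch_size"),
                  suffixes = c("_hsi", "_rgb"))
  list(hsi = hsi, rgb = rgb, paired = paired)
}
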