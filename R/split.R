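#' Cultivar-based train/validation/test split
#'
#' Holds out one whole cultivar for validation and another for testing;
#' the remaining cultivars train. With the default 8 cultivars this is the
#' strict 6/1/1 (75% / 12.5% / 12.5%) partition in which the model never
#' sees the evaluation cultivars during training. Because the split key is
#' the cultivar, all records of any one image share a fold, so there is no
#' image-level leakage either.
#'
#' @param table record table with `cultivar` and `image_index` columns.
#' @param val_cultivar,test_cultivar held-out cultivars; when NULL they are
#'   drawn (distinct) from the table's cultivars using `seed`.
#' @param seed integer seed for the random fallback choice.
#' @return object of class `split_assignment`: list with `strategy`,
#'   `fold` (factor train/val/test per record), `manifest`, `seed`.
#' @export
split_by_cultivar <- function(table, val_cultivar = NULL, test_cultivar = NULL,
                              seed = NULL) {
  cultivars <- sort(unique(table$cultivar))
  if (is.null(val_cultivar) || is.null(test_cultivar)) {
    if (!is.null(seed)) set.seed(seed)
    pick <- sample(cultivars, 2L)
    if (is.null(val_cultivar)) val_cultivar <- setdiff(pick, test_cultivar)[1]
    if (is.null(test_cultivar)) test_cultivar <- setdiff(pick, val_cultivar)[1]
  }
  if (!val_cultivar %in% cultivars) stop("unknown cultivar: ", val_cultivar)
  if (!test_cultivar %in% cultivars) stop("unknown cultivar: ", test_cultivar)
  if (identical(val_cultivar, test_cultivar))
    stop("validation and test cultivars must differ")

  fold <- factor(ifelse(table$cultivar == test_cultivar, "test",
                 ifelse(table$cultivar == val_cultivar, "val", "train")),
                 levels = c("train", "val", "test"))
  out <- structure(list(
    strategy = "cultivar",
    fold = fold,
    manifest = list(val_cultivar = val_cultivar,
                    test_cultivar = test_cultivar,
                    train_cultivars = setdiff(cultivars, c(val_cultivar, test_cultivar)),
                    cultivar_fractions = round(100 * c(
                      train = length(cultivars) - 2, val = 1, test = 1
                    ) / length(cultivars), 1)),
    seed = seed
  ), class = "split_assignment")
  assert_no_leakage(table, out)
  out
}

#' Default concentration hold-out map
#'
#' Assigns, per cultivar, a deterministic rotating pattern of held-out
#' sugar concentrations: the first 6 cultivars contribute 2 test
#' concentrations each and the last 2 contribute 1 (14 test cells), the
#' first 4 contribute 2 validation concentrations and the last 4 contribute
#' 1 (12 validation cells). Out of the default 8 x 11 = 88
#' (cultivar, concentration) cells this leaves 62 in training:
#' 70.5% / 15.9% / 13.6% to one decimal. The rotation offsets (multiples of
#' 3, steps of 4 within a cultivar, modulo the number of levels) spread the
#' held-out concentrations over the whole 25-75% range. The same map ships
#' as a YAML config (`system.file("extdata", "holdout_default.yaml",
#' package = "hsijam")`).
#'
#' @param cultivars cultivar names (order fixes the rotation).
#' @param sugar_levels the design's sugar levels.
#' @param n_test,n_val total held-out cell counts.
#' @return named list: per cultivar a list with `test` and `val`
#'   concentration vectors.
#' @export
default_holdout_map <- function(cultivars = default_cultivars(),
                                sugar_levels = seq(25, 75, by = 5),
                                n_test = 14L, n_val = 12L) {
  C <- length(cultivars); L <- length(sugar_levels)
  if (n_test + n_val >= C * L - C)
    stop("hold-out map too large: a cultivar would lose all training cells")
  per <- function(total) {
    base <- total %/% C; rem <- total %% C
    rep(base, C) + (seq_len(C) <= rem)
  }
  nt <- per(n_test); nv <- per(n_val)
  out <- vector("list", C); names(out) <- cultivars
  for (i in seq_len(C)) {
    # Deterministic rotation: start at 3*(i-1), step by 4, modulo L.
    idx <- (3 * (i - 1) + 4 * (seq_len(nt[i] + nv[i]) - 1L)) %% L + 1L
    if (anyDuplicated(idx))
      idx <- unique(c(idx, setdiff(seq_len(L), idx)))[seq_len(nt[i] + nv[i])]
    out[[i]] <- list(test = sugar_levels[idx[seq_len(nt[i])]],
                     val = sugar_levels[idx[nt[i] + seq_len(nv[i])]])
  }
  out
}

#' Read a concentration hold-out map from YAML
#'
#' @param path YAML file mapping cultivar names to `test` / `val`
#'   concentration lists; default the packaged map.
#' @return hold-out map in the format of [default_holdout_map()].
#' @export
read_holdout_config <- function(path = system.file("extdata", "holdout_default.yaml",
                                                   package = "hsijam")) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(x) list(test = as.numeric(x$test), val = as.numeric(x$val)))
}

#' Concentration-based train/validation/test split
#'
#' Every cultivar is seen in training, but specific (cultivar,
#' concentration) cells are held out entirely for validation or testing, so
#' the evaluated concentrations of a cultivar are absent from training.
#' The fold key is the (cultivar, concentration) pair, which again implies
#' image-level disjointness.
#'
#' @param table record table with `cultivar`, `sugar_pct`, `image_index`.
#' @param held_out_map per-cultivar list of `test` and `val` concentration
#'   vectors; default [default_holdout_map()] restricted to the table's
#'   cultivars and levels.
#' @param seed recorded in the assignment (the default map is
#'   deterministic; the seed only matters for user-supplied random maps).
#' @return a `split_assignment`; its manifest reports the cell fractions
#'   rounded to one decimal (percent).
#' @export
split_by_concentration <- function(table, held_out_map = NULL, seed = NULL) {
  cultivars <- sort(unique(table$cultivar))
  levels_all <- sort(unique(table$sugar_pct))
  if (is.null(held_out_map))
    held_out_map <- default_holdout_map(cultivars, levels_all)

  cell_key <- function(cult, conc) paste(cult, conc, sep = "@")
  test_cells <- character(0); val_cells <- character(0)
  for (cult in names(held_out_map)) {
    hm <- held_out_map[[cult]]
    if (length(intersect(hm$test, hm$val)))
      stop("hold-out overlap: cultivar ", cult,
           " assigns a concentration to both test and val")
    test_cells <- c(test_cells, cell_key(cult, hm$test))
    val_cells <- c(val_cells, cell_key(cult, hm$val))
  }
  n_cells <- length(cultivars) * length(levels_all)
  for (cult in cultivars) {
    held <- length(held_out_map[[cult]]$test) + length(held_out_map[[cult]]$val)
    if (held >= length(levels_all))
      stop("cultivar ", cult, " has no training concentration left")
  }

  key <- cell_key(table$cultivar, table$sugar_pct)
  fold <- factor(ifelse(key %in% test_cells, "test",
                 ifelse(key %in% val_cells, "val", "train")),
                 levels = c("train", "val", "test"))
  fr <- round(100 * c(train = n_cells - length(test_cells) - length(val_cells),
                      val = length(val_cells),
                      test = length(test_cells)) / n_cells, 1)
  out <- structure(list(
    strategy = "concentration",
    fold = fold,
    manifest = list(held_out_map = held_out_map,
                    n_cells = n_cells,
                    n_test_cells = length(test_cells),
                    n_val_cells = length(val_cells),
                    cell_fractions = fr),
    seed = seed
  ), class = "split_assignment")
  assert_no_leakage(table, out)
  if (!all(cultivars %in% unique(table$cultivar[fold == "train"])))
    stop("leakage check failed: a cultivar is absent from training")
  out
}

# Image-level leakage guard: the image_index sets of the three folds must
# be pairwise disjoint. Called by every split constructor.
assert_no_leakage <- function(table, assignment) {
  ids <- split(table$image_index, assignment$fold)
  if (length(intersect(ids$train, ids$val)) ||
      length(intersect(ids$train, ids$test)) ||
      length(intersect(ids$val, ids$test)))
    stop("leakage check failed: an image_index appears in two folds")
  invisible(TRUE)
}
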