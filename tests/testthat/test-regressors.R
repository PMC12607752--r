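test_that("min-max scaler maps train to [0,1], inverts exactly, never clips", {
  set.seed(8)
  X <- matrix(runif(40, 2, 5), 10, 4,
              dimnames = list(NULL, paste0("band_000", 1:4)))
  y <- seq(25, 75, length.out = 10)
  sc <- fit_scaler(X, y)
  Xs <- apply_scaler(sc, X)
  expect_equal(range(Xs), c(0, 1))
  expect_equal(scale_target(sc, c(25, 50, 75)), c(0, 0.5, 1))
  yy <- runif(20, -10, 110)
  expect_equal(invert_target(sc, scale_target(sc, yy)), yy, tolerance = 1e-12)
  expect_equal(scale_target(sc, 80), 1.1)   # extrapolation, no clipping

  Xc <- X; Xc[, 2] <- 1
  expect_error(fit_scaler(Xc, y), "band_0002")
  expect_error(fit_scaler(X, rep(50, 10)), "target")
})

test_that("SVM predictions are order-invariant and near-optimal for a linear signal", {
  tab <- make_linear_table()
  sp <- fixed_split(tab)
  fit <- train_svm(tab, sp)
  pred <- predict(fit, tab)

  # permuting training record order changes nothing beyond solver tolerance
  perm <- sample(nrow(tab))
  fit2 <- train_svm(tab[perm, ], structure(list(
    strategy = "fixed", fold = sp$fold[perm], manifest = list(), seed = NULL),
    class = "split_assignment"))
  expect_lt(max(abs(predict(fit2, tab) - pred)), 0.1)  # % sugar

  # exact linear relation: all predictions within the epsilon tube of truth
  # (epsilon on the scaled target, mapped back to percent)
  eps_pct <- 0.1 * (max(tab$sugar_pct[sp$fold == "train"]) -
                    min(tab$sugar_pct[sp$fold == "train"]))
  tr <- sp$fold == "train"
  expect_lt(max(abs(pred[tr] - tab$sugar_pct[tr])), eps_pct + 1.0)

  # optimality certificate: the fitted function must not have a larger
  # primal objective than the plain linear solution it should approximate
  svmfit <- fit$fit
  Xs <- apply_scaler(fit$scaler, as.matrix(tab[tr, sprintf("band_%04d", 1:8)]))
  ys <- (tab$sugar_pct[tr] - fit$scaler$y_min) /
    (fit$scaler$y_max - fit$scaler$y_min)
  K <- exp(-0.01 * as.matrix(stats::dist(Xs))^2)
  alpha <- rep(0, sum(tr))
  sv_idx <- svmfit$index
  alpha[sv_idx] <- svmfit$coefs
  f_sv <- as.numeric(K %*% alpha) - svmfit$rho
  primal <- function(f, a) {
    0.5 * sum(a * (K %*% a)) + 110 * sum(pmax(abs(f - ys) - 0.1, 0))
  }
  expect_lte(primal(f_sv, alpha), primal(rep(mean(ys), sum(tr)), rep(0, sum(tr))) + 1e-8)

  expect_error(train_svm(tab, structure(list(strategy = "x",
    fold = factor(rep("test", nrow(tab)), levels = c("train", "val", "test")),
    manifest = list(), seed = NULL), class = "split_assignment")),
    "empty training fold")
})

test_that("XGBoost fits constants exactly, respects the round cap, needs a validation fold", {
  tab <- make_linear_table(n = 50)
  tab$sugar_pct <- 50 + 0 * tab$sugar_pct + c(rep(0, 25), rep(1e-9, 25))
  sp <- fixed_split(tab)
  # constant target within float tolerance -> constant prediction
  fit <- suppressWarnings(train_xgb(tab, sp, seed = 3))
  pred <- predict(fit, tab)
  expect_lt(max(abs(pred - 50)), 1e-5)

  tab2 <- make_linear_table(n = 80, seed = 4)
  sp2 <- fixed_split(tab2)
  fit2 <- train_xgb(tab2, sp2, seed = 3)
  expect_lte(as.integer(fit2$best_iteration), 400)
  pv <- predict(fit2, tab2[sp2$fold == "val", ])
  m <- regression_metrics(tab2$sugar_pct[sp2$fold == "val"], pv)
  expect_gt(m$r2, 0.9)

  no_val <- fixed_split(tab2, frac_val = 0)
  expect_error(train_xgb(tab2, no_val), "validation fold")
})

test_that("XGBoost training is reproducible given a seed", {
  tab <- make_linear_table(n = 80, seed = 6)
  sp <- fixed_split(tab)
  p1 <- predict(train_xgb(tab, sp, seed = 11), tab)
  p2 <- predict(train_xgb(tab, sp, seed = 11), tab)
  expect_identical(p1, p2)
})

test_that("scaler provenance is asserted before any fit", {
  tab <- make_linear_table()
  sp <- fixed_split(tab)
  pf_bad <- fit_scaler(as.matrix(tab[, sprintf("band_%04d", 1:8)]),
                       tab$sugar_pct, provenance = "train+test")
  expect_error(hsijam:::assert_scaler_provenance(pf_bad), "leakage")
})
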