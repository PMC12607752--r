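test_that("record tables have one row per surviving subregion and round-trip through CSV", {
  d <- tiny_design(spatial = c(32L, 32L))
  m <- spectral_model(d, noise_sd = 0)
  ds <- simulate_dataset(d, m, grids = c(1, 2), seed = 4)
  n_caps <- nrow(enumerate_design(d))
  expect_equal(nrow(ds$hsi$g1), n_caps)          # no drops at noise 0
  expect_equal(nrow(ds$hsi$g2), n_caps * 4)
  expect_true(all(sprintf("band_%04d", 1:24) %in% names(ds$hsi$g1)))

  path <- tempfile(fileext = ".csv")
  write_spectral_csv(ds$hsi$g1[1:10, ], path)
  back <- read_spectral_csv(path)
  fm0 <- as.matrix(ds$hsi$g1[1:10, sprintf("band_%04d", 1:24)])
  fm1 <- as.matrix(back[, sprintf("band_%04d", 1:24)])
  expect_equal(fm1, fm0, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$cultivar, ds$hsi$g1$cultivar[1:10])

  # duplicate (image_index, cell) keys are an integrity error
  dup <- list(ds$hsi$g1[1, ], ds$hsi$g1[1, ])
  expect_error(build_table(dup, d), "integrity error")
})

test_that("image_index is stable across grid configurations", {
  d <- tiny_design(spatial = c(32L, 32L))
  m <- spectral_model(d, noise_sd = 0)
  ds <- simulate_dataset(d, m, grids = c(1, 3), seed = 4)
  expect_setequal(unique(ds$hsi$g3$image_index), ds$hsi$g1$image_index)
})

test_that("cultivar split holds out whole cultivars with no image leakage", {
  d <- acquisition_design(spatial_size = c(8L, 8L))  # table built directly
  caps <- enumerate_design(d)
  # synthesize a minimal record table without rendering: one row per capture
  tab <- data.frame(band_0001 = 1, sugar_pct = caps$sugar_pct,
                    cultivar = caps$cultivar, image_index = caps$image_index)
  sp <- split_by_cultivar(tab, val_cultivar = "gala", test_cultivar = "idared")
  expect_equal(sp$manifest$cultivar_fractions[["train"]], 75)
  expect_equal(sum(sp$fold == "test"), 11 * 20)      # one cultivar's records
  expect_equal(sum(sp$fold == "test") / nrow(tab), 0.125)
  expect_false(any(tab$cultivar[sp$fold == "train"] %in% c("gala", "idared")))

  # every image's records share a fold
  by_img <- tapply(sp$fold, tab$image_index, function(f) length(unique(f)))
  expect_true(all(by_img == 1))

  # folds are image-disjoint
  ids <- split(tab$image_index, sp$fold)
  expect_length(intersect(ids$train, ids$test), 0)
  expect_length(intersect(ids$train, ids$val), 0)

  expect_error(split_by_cultivar(tab, "gala", "gala"), "differ")
  expect_error(split_by_cultivar(tab, "nosuch", "gala"), "unknown cultivar")

  # seeded random fallback is reproducible
  s1 <- split_by_cultivar(tab, seed = 9)
  s2 <- split_by_cultivar(tab, seed = 9)
  expect_identical(s1$manifest, s2$manifest)
})

test_that("concentration split reproduces the 70.5 / 15.9 / 13.6 cell fractions", {
  d <- acquisition_design()
  caps <- enumerate_design(d)
  tab <- data.frame(band_0001 = 1, sugar_pct = caps$sugar_pct,
                    cultivar = caps$cultivar, image_index = caps$image_index)
  sp <- split_by_concentration(tab)
  fr <- sp$manifest$cell_fractions
  expect_equal(fr[["train"]], 70.5)
  expect_equal(fr[["test"]], 15.9)
  expect_equal(fr[["val"]], 13.6)
  expect_equal(sp$manifest$n_test_cells, 14)
  expect_equal(sp$manifest$n_val_cells, 12)

  # every cultivar appears in training
  expect_setequal(unique(tab$cultivar[sp$fold == "train"]), d$cultivars)

  # held-out cells are truly absent from training
  hm <- sp$manifest$held_out_map
  for (cult in names(hm)) {
    tr_levels <- unique(tab$sugar_pct[sp$fold == "train" & tab$cultivar == cult])
    expect_length(intersect(tr_levels, c(hm[[cult]]$test, hm[[cult]]$val)), 0)
  }

  # empty hold-out map -> everything trains
  empty <- lapply(d$cultivars, function(x) list(test = numeric(0), val = numeric(0)))
  names(empty) <- d$cultivars
  sp0 <- split_by_concentration(tab, held_out_map = empty)
  expect_true(all(sp0$fold == "train"))

  # overlap between test and val cells is an error
  bad <- empty
  bad$gala <- list(test = 50, val = 50)
  expect_error(split_by_concentration(tab, held_out_map = bad), "overlap")
})

test_that("packaged hold-out YAML matches the in-code default map", {
  skip_if_not(nzchar(system.file("extdata", "holdout_default.yaml",
                                 package = "hsijam")))
  from_yaml <- read_holdout_config()
  from_code <- default_holdout_map()
  expect_identical(names(from_yaml), names(from_code))
  for (cult in names(from_code)) {
    expect_equal(from_yaml[[cult]]$test, as.numeric(from_code[[cult]]$test))
    expect_equal(from_yaml[[cult]]$val, as.numeric(from_code[[cult]]$val))
  }
})
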