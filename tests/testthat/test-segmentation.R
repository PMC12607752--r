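test_that("spectral angle: identities, symmetry, scale invariance", {
  set.seed(5)
  expect_equal(spectral_angle(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(spectral_angle(c(1, 0), c(1, 1)), pi / 4)
  for (i in 1:10) {
    p <- runif(8); r <- runif(8)
    expect_lt(spectral_angle(p, p), 1e-7)   # acos round-off near cos = 1
    expect_equal(spectral_angle(p, r), spectral_angle(r, p))
    a <- runif(1, 0.1, 10)
    expect_equal(spectral_angle(a * p, r), spectral_angle(p, r))
  }
  expect_error(spectral_angle(rep(0, 4), runif(4)), "zero spectrum")
  expect_error(spectral_angle(runif(3), runif(4)), "equal length")
})

test_that("vectorized SAM mask equals the brute-force per-pixel oracle", {
  set.seed(77)
  for (rep in 1:20) {
    cube <- structure(list(R = array(runif(16 * 16 * 8), c(16, 16, 8)),
                           invalid = matrix(runif(256) < 0.05, 16, 16)),
                      class = "reflectance_cube")
    r <- runif(8)
    thr <- runif(1, 0.05, 1.0)
    fast <- sam_mask(cube, r, thr)$mask
    slow <- sam_mask_bruteforce(cube, r, thr)
    expect_identical(fast, slow)
  }
})

test_that("noiseless synthetic scenes segment to the exact ground truth", {
  sc <- tiny_scene(noise_sd = 0)
  ref <- pick_reference(sc$cube)
  msk <- sam_mask(sc$cube, ref, 0.2)
  expect_identical(msk$mask, sc$cap$truth$jam_mask)
})

test_that("pick_reference takes a robust per-band median", {
  cube <- structure(list(R = array(0.4, c(6, 6, 4)),
                         invalid = matrix(FALSE, 6, 6)),
                    class = "reflectance_cube")
  expect_equal(pick_reference(cube, c(1, 4, 1, 4)), rep(0.4, 4))

  cube$R[2, 2, ] <- 9  # single outlier inside the region, killed by median
  expect_equal(pick_reference(cube, c(1, 4, 1, 4)), rep(0.4, 4))
  expect_error(pick_reference(cube, c(2, 2, 1, 4)), "empty seed region")
})

test_that("reference from the central patch is close to the jam template under noise", {
  sc <- tiny_scene(noise_sd = 0.01, seed = 19,
                   design = tiny_design(bands = 48L, spatial = c(48L, 48L)))
  ref <- pick_reference(sc$cube)
  expect_lt(spectral_angle(ref, sc$cap$truth$jam_spectrum), 0.05)
})

test_that("ROI from mask is the tightest box; margin shrinks by floor(fraction * size)", {
  m <- matrix(FALSE, 10, 10)
  m[4, 6] <- TRUE                 # 0-based (3, 5)
  box <- roi_from_mask(m)
  expect_equal(unclass(box)[c("row_min", "row_max", "col_min", "col_max")],
               list(row_min = 3L, row_max = 4L, col_min = 5L, col_max = 6L))
  expect_error(roi_from_mask(matrix(FALSE, 3, 3)), "empty ROI")

  big <- roi(0, 100, 0, 60)
  shr <- apply_margin(big, 0.10)
  expect_equal(c(shr$row_min, shr$row_max, shr$col_min, shr$col_max),
               c(10L, 90L, 6L, 54L))
  expect_equal(apply_margin(big, 0), big)
  expect_error(apply_margin(roi(0, 2, 0, 10), 0.6), "collapses")
})

test_that("grid subdivision partitions the ROI exactly for every g and size", {
  # brute-force pixel membership over all sizes 5..40 x grid 1..5
  for (g in 1:5) {
    for (n in seq(5L, 40L, by = 5L)) {
      box <- roi(2, 2 + n, 3, 3 + n + 1)     # height n, width n + 1
      cells <- subdivide(box, g)
      expect_length(cells, g^2)
      cover <- matrix(0L, n, n + 1L)
      for (cell in cells) {
        rows <- (cell$row_min - box$row_min + 1L):(cell$row_max - box$row_min)
        cols <- (cell$col_min - box$col_min + 1L):(cell$col_max - box$col_min)
        cover[rows, cols] <- cover[rows, cols] + 1L
        expect_lte(diff(range(roi_height(cell), n %/% g)), 1)
      }
      expect_true(all(cover == 1L))
    }
  }
  # documented examples
  expect_equal(vapply(subdivide(roi(0, 512, 0, 512), 4), roi_height, 1L),
               rep(128L, 16))
  expect_equal(subdivide(roi(1, 11, 2, 12), 1)[[1]]$row_max, 11L)
  sizes <- vapply(subdivide(roi(0, 10, 0, 10), 3)[1:3], roi_width, 1L)
  expect_equal(sizes, c(4L, 3L, 3L))
  expect_error(subdivide(roi(0, 2, 0, 10), 3), "smaller than grid")
  expect_error(subdivide(roi(0, 10, 0, 10), 6), "1..5")
})

test_that("cell features are unit-norm masked means; small cells are dropped", {
  b <- 4L
  R <- array(0, c(6, 6, b))
  s <- c(3, 4, 0, 0)
  for (k in seq_len(b)) R[, , k] <- s[k]
  cube <- structure(list(R = R, invalid = matrix(FALSE, 6, 6)),
                    class = "reflectance_cube")
  mask <- matrix(TRUE, 6, 6)
  cell <- roi(0, 6, 0, 6)
  attr(cell, "cell_row") <- 0L; attr(cell, "cell_col") <- 0L
  f <- cell_feature(cube, mask, cell, min_pixels = 5)
  expect_equal(f$feature, c(0.6, 0.8, 0, 0))
  expect_equal(sqrt(sum(f$feature^2)), 1, tolerance = 1e-9)

  # masked vs unmasked means differ when background enters the cell
  R2 <- R; R2[1, , ] <- 5
  cube2 <- structure(list(R = R2, invalid = matrix(FALSE, 6, 6)),
                     class = "reflectance_cube")
  mask2 <- matrix(TRUE, 6, 6); mask2[1, ] <- FALSE
  f_masked <- cell_feature(cube2, mask2, cell)
  expect_equal(f_masked$feature, c(0.6, 0.8, 0, 0))
  f_all <- cell_feature(cube2, matrix(TRUE, 6, 6), cell)
  expect_false(isTRUE(all.equal(f_all$feature, f_masked$feature)))

  few <- matrix(FALSE, 6, 6); few[1, 1:3] <- TRUE
  dropped <- cell_feature(cube, few, cell, min_pixels = 5)
  expect_true(is_dropped(dropped))
  expect_match(dropped$reason, "min_pixels")
})

test_that("noiseless end-to-end features equal the unit-normalized template everywhere", {
  sc <- tiny_scene(noise_sd = 0, design = tiny_design(bands = 32L, spatial = c(48L, 48L)))
  feats <- extract_features(sc$cube, grids = 1:5)
  tmpl <- sc$cap$truth$jam_spectrum
  tmpl <- tmpl / sqrt(sum(tmpl^2))
  for (g in 1:5) {
    fm <- as.matrix(feats[[paste0("g", g)]][, sprintf("band_%04d", 1:32)])
    expect_lt(max(abs(sweep(fm, 2, tmpl))), 1e-10)
  }
})
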