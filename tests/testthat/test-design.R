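test_that("design enumeration matches the closed-form product", {
  d <- acquisition_design()
  caps <- enumerate_design(d)
  expect_equal(nrow(caps), 8 * 11 * (6 + 7 + 7))
  expect_equal(nrow(unique(caps[c("cultivar", "sugar_pct")])), 88)
  expect_equal(length(unique(caps$sugar_pct)), 11)

  # identity case and a small product, against explicit nested loops
  d1 <- acquisition_design(cultivars = "gala", sugar_levels = 50,
                           views_per_thickness = c("0.5" = 1))
  expect_equal(nrow(enumerate_design(d1)), 1)

  d2 <- acquisition_design(cultivars = c("a", "b"), sugar_levels = c(30, 40, 50),
                           views_per_thickness = c("0.5" = 2, "1" = 2))
  caps2 <- enumerate_design(d2)
  n_oracle <- 0L
  for (cu in d2$cultivars) for (s in d2$sugar_levels)
    for (th in names(d2$views_per_thickness))
      for (v in seq_len(d2$views_per_thickness[[th]])) n_oracle <- n_oracle + 1L
  expect_equal(nrow(caps2), n_oracle)
  expect_equal(nrow(caps2), 24)
  expect_equal(caps2$image_index, seq_len(24))
})

test_that("invalid designs are rejected", {
  expect_error(acquisition_design(cultivars = character(0)), "cultivar")
  expect_error(acquisition_design(sugar_levels = c(50, 40)), "increasing")
  expect_error(acquisition_design(sugar_levels = c(0, 50)), "\\(0, 100\\)")
  expect_error(acquisition_design(bands = 3), "bands")
  expect_error(acquisition_design(wavelength_range = c(1000, 400)), "exceed")
  expect_error(acquisition_design(views_per_thickness = c("0.5" = 0)), "view")
})

test_that("simulated spectra are deterministic given a seed and differ only on the sugar window", {
  d <- tiny_design(bands = 64L)
  m <- spectral_model(d, noise_sd = 0.02)
  a <- simulate_spectrum(m, "gala", 50, seed = 9)
  b <- simulate_spectrum(m, "gala", 50, seed = 9)
  expect_identical(a, b)

  lo <- expected_spectrum(m, "gala", 30)
  hi <- expected_spectrum(m, "gala", 70)
  w <- m$wavelengths
  inside <- w > m$sugar_window[1] & w < m$sugar_window[2]
  expect_true(all(lo[!inside] == hi[!inside]))
  expect_true(all(hi[inside] > lo[inside]))  # monotone increase with sugar
  expect_true(all(lo >= 0 & lo <= 1) && all(hi >= 0 & hi <= 1))

  expect_error(simulate_spectrum(m, "braeburn", 50), "unknown cultivar")
  expect_error(expected_spectrum(m, "gala", 0), "sugar_pct")
})

test_that("cultivar baselines have the VNIR jam shape", {
  d <- acquisition_design()
  m <- spectral_model(d)
  w <- m$wavelengths
  for (cult in colnames(m$cultivar_baselines)) {
    t <- m$cultivar_baselines[, cult]
    win <- which(w >= 400 & w <= 500)
    imin <- win[which.min(t[win])]
    expect_gt(imin, min(win))   # interior local minimum of the dip window
    expect_lt(imin, max(win))
    expect_gt(mean(t[w >= 700 & w <= 900]), mean(t))
    expect_true(all(t > 0 & t < 1))
  }
})

test_that("mean of noisy draws converges to the noiseless spectrum", {
  d <- tiny_design(bands = 32L)
  noise_sd <- 0.05
  m <- spectral_model(d, noise_sd = noise_sd)
  mu <- expected_spectrum(m, "idared", 40)
  n <- 1000
  draws <- simulate_spectrum(m, "idared", 40, n = n, seed = 31)
  expect_lt(max(abs(colMeans(draws) - mu)), 4 * noise_sd / sqrt(n))
})

test_that("rendered scenes invert exactly under calibration and are seed-stable", {
  sc <- tiny_scene(noise_sd = 0)
  truth <- sc$cap$truth
  ij <- which(truth$jam_mask, arr.ind = TRUE)
  i <- ij[1, 1]; j <- ij[1, 2]
  expect_equal(sc$cube$R[i, j, ], truth$jam_spectrum, tolerance = 1e-12)

  cap2 <- render_scene(sc$cap$meta, sc$model, sc$design, seed = 7)
  expect_identical(sc$cap$I, cap2$I)
  expect_identical(sc$cap$W, cap2$W)

  # jam covers >= 10% of the frame; too-small frames error
  expect_gte(sum(truth$jam_mask), 0.10 * prod(sc$design$spatial_size))
  d_small <- tiny_design(spatial = c(2L, 2L))
  m_small <- spectral_model(d_small)
  expect_error(render_scene(sc$cap$meta, m_small, d_small, seed = 1),
               "geometry error")
})

test_that("background and jam pixels sit on opposite sides of the SAM threshold", {
  sc <- tiny_scene(noise_sd = 0.01, seed = 3)
  truth <- sc$cap$truth
  r <- truth$jam_spectrum
  d <- dim(sc$cube$R)
  P <- matrix(sc$cube$R, d[1] * d[2], d[3])
  ang <- apply(P, 1, spectral_angle, r = r)
  expect_true(all(ang[as.vector(truth$jam_mask)] <= 0.2))
  expect_true(all(ang[!as.vector(truth$jam_mask)] > 0.2))
})

test_that("render_rgb averages the three visible windows", {
  wl <- seq(400, 1000, length.out = 30)
  cube <- array(0.5, c(4, 4, 30))
  rgb <- render_rgb(cube, wl)
  expect_equal(dim(rgb$R), c(4, 4, 3))
  expect_true(all(abs(rgb$R - 0.5) < 1e-12))

  nir_only <- array(0, c(4, 4, 30))
  nir_only[, , wl > 700] <- 1
  expect_true(all(render_rgb(nir_only, wl)$R == 0))

  one_band <- array(0, c(2, 2, 30))
  k450 <- which.min(abs(wl - 450))
  one_band[, , k450] <- 1
  out <- render_rgb(one_band, wl)
  expect_true(all(out$R[, , 1] > 0))
  expect_true(all(out$R[, , 2:3] == 0))

  expect_error(render_rgb(array(1, c(2, 2, 3)), c(800, 900, 1000)),
               "coverage error")
})
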