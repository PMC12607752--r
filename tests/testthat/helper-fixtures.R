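# Small designs/scenes shared across test files. Everything is generated in
# code; nothing is read from disk.

tiny_design <- function(cultivars = c("gala", "idared"),
                        sugar_levels = c(30, 50, 70),
                        bands = 24L, spatial = c(24L, 24L)) {
  acquisition_design(cultivars = cultivars, sugar_levels = sugar_levels,
                     views_per_thickness = c("0.5" = 1),
                     bands = bands, spatial_size = spatial)
}

tiny_scene <- function(noise_sd = 0, seed = 7, design = tiny_design(),
                       cultivar = "gala", sugar = 50) {
  model <- spectral_model(design, noise_sd = noise_sd)
  meta <- list(cultivar = cultivar, sugar_pct = sugar, image_index = 1L,
               thickness = 0.5, view = 1L, distance = 20)
  cap <- render_scene(meta, model, design, seed = seed)
  list(design = design, model = model, cap = cap,
       cube = calibrate_capture(cap))
}

# Lazily-built dataset for the heavier recovery checks; built once per run.
.fixture_env <- new.env(parent = emptyenv())

recovery_dataset <- function() {
  if (is.null(.fixture_env$recovery)) {
    design <- acquisition_design(views_per_thickness = c("0.5" = 1, "1" = 1))
    model <- spectral_model(design)
    ds <- simulate_dataset(design, model, grids = 2, seed = 202)
    .fixture_env$recovery <- list(design = design, model = model,
                                  table = ds$hsi$g2)
  }
  .fixture_env$recovery
}

# Toy table with an exact linear feature -> sugar relation, plus a
# position-based split, for regressor unit tests.
make_linear_table <- function(n = 60, bands = 8, seed = 2) {
  set.seed(seed)
  X <- matrix(runif(n * bands), n, bands)
  y <- 25 + 50 * X[, 1]
  tab <- as.data.frame(X)
  names(tab) <- sprintf("band_%04d", seq_len(bands))
  tab$sugar_pct <- y
  tab$cultivar <- rep(c("a", "b", "c"), length.out = n)
  tab$image_index <- seq_len(n)
  tab
}

fixed_split <- function(tab, frac_val = 0.2, frac_test = 0.2) {
  n <- nrow(tab)
  fold <- rep("train", n)
  fold[seq_len(floor(n * frac_val))] <- "val"
  fold[n - seq_len(floor(n * frac_test)) + 1] <- "test"
  structure(list(strategy = "fixed",
                 fold = factor(fold, levels = c("train", "val", "test")),
                 manifest = list(), seed = NULL),
            class = "split_assignment")
}

# Brute-force SAM oracle: per-pixel double loop with the scalar angle.
sam_mask_bruteforce <- function(cube, reference, threshold) {
  d <- dim(cube$R)
  out <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (cube$invalid[i, j]) next
    out[i, j] <- spectral_angle(cube$R[i, j, ], reference) <= threshold
  }
  out
}
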