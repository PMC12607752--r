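#' Configuration of the 1-D residual network
#'
#' The network maps a spectrum (1 channel x n_bands) to one scalar. A
#' custom-padded stem convolution (padding floor(k/2) left and
#' k - 1 - floor(k/2) right, so stride-1 convolutions preserve length for
#' any kernel size, odd or even) is followed by `n_blocks` residual blocks.
#' Each block is conv-BN-ReLU-dropout-conv-BN plus a skip connection and a
#' final ReLU. Every `downsample_every`-th block convolves with stride 2
#' and doubles the filter count; its skip is a 1x1 stride-2 projection
#' convolution with batch normalization (an identity skip is
#' shape-incompatible there). The head is global average pooling and one
#' fully connected output unit. Training uses Adam on mean absolute error
#' of min-max-scaled targets, with early stopping that restores the best
#' validation weights; "improve" means a strict decrease of at least 1e-6.
#'
#' @param n_blocks number of residual blocks.
#' @param base_filters stem/first-block filter count; doubles at each
#'   downsampling block.
#' @param kernel_size block convolution kernel length.
#' @param stem_kernel stem convolution kernel length.
#' @param dropout_p dropout probability inside each block.
#' @param downsample_every apply stride-2 downsampling at every this-many
#'   blocks (default 2: blocks 2, 4, 6, 8).
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty on convolution and dense weights.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience in epochs.
#' @param batch_size minibatch size (the sweep explores 32/64/128/256).
#' @return a config list of class `resnet_config`.
#' @export
resnet_config <- function(n_blocks = 8L, base_filters = 16L, kernel_size = 3L,
                          stem_kernel = 7L, dropout_p = 0.1,
                          downsample_every = 2L, lr = 1e-3,
                          weight_decay = 1e-4, max_epochs = 30L,
                          patience = 5L, batch_size = 64L) {
  stopifnot(n_blocks >= 1L, base_filters >= 1L, kernel_size >= 1L,
            stem_kernel >= 1L, dropout_p >= 0, dropout_p < 1,
            downsample_every >= 1L, lr > 0, weight_decay >= 0,
            max_epochs >= 1L, patience >= 1L, batch_size >= 1L)
  structure(list(n_blocks = as.integer(n_blocks),
                 base_filters = as.integer(base_filters),
                 kernel_size = as.integer(kernel_size),
                 stem_kernel = as.integer(stem_kernel),
                 dropout_p = dropout_p,
                 downsample_every = as.integer(downsample_every),
                 lr = lr, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size)),
            class = "resnet_config")
}

#' Output length of a length-preserving padded 1-D convolution
#'
#' With padding floor(k/2) + (k - 1 - floor(k/2)) the padded length is
#' L + k - 1, so the output length is floor((L - 1) / stride) + 1: exactly
#' L at stride 1 and ceiling(L / 2) at stride 2 (204 -> 102 -> 51 -> 26
#' -> 13 across four downsamplings).
#'
#' @param L input length.
#' @param stride convolution stride.
#' @return output length.
#' @export
conv_out_len <- function(L, stride = 1L) (L - 1L) %/% stride + 1L

# ---- low-level layers --------------------------------------------------
# Activations are channel-first (C, L, N) arrays: with channels on the
# fastest-varying axis, per-channel affine operations are plain recycled
# arithmetic and im2col needs no transposes. Convolution weights are
# (C_in * k, C_out) matrices with rows ordered kernel-tap-major (tap 1
# channels, tap 2 channels, ...).

conv1d_fwd <- function(X, W, b, k, stride) {
  d <- dim(X); C <- d[1]; L <- d[2]; N <- d[3]
  padL <- k %/% 2L; padR <- k - 1L - padL
  Lp <- L + padL + padR
  Xp <- array(0, c(C, Lp, N))
  Xp[, (padL + 1L):(padL + L), ] <- X
  Lout <- (Lp - k) %/% stride + 1L
  pos0 <- (seq_len(Lout) - 1L) * stride
  M <- matrix(0, C * k, Lout * N)
  for (kk in seq_len(k)) {
    sub <- Xp[, pos0 + kk, , drop = FALSE]                    # C x Lout x N
    dim(sub) <- c(C, Lout * N)
    M[((kk - 1L) * C + 1L):(kk * C), ] <- sub
  }
  Y <- crossprod(W, M) + b                                    # F x (Lout*N)
  dim(Y) <- c(ncol(W), Lout, N)
  list(out = Y, cache = list(M = M, W = W, k = k, stride = stride,
                             N = N, C = C, L = L, Lp = Lp, Lout = Lout,
                             padL = padL))
}

conv1d_bwd <- function(dout, cache) {
  W <- cache$W; M <- cache$M
  N <- cache$N; C <- cache$C; L <- cache$L
  Lp <- cache$Lp; Lout <- cache$Lout
  k <- cache$k; stride <- cache$stride; padL <- cache$padL
  dY <- dout
  dim(dY) <- c(ncol(W), Lout * N)
  dW <- tcrossprod(M, dY)
  db <- rowSums(dY)
  dM <- W %*% dY                                              # (C*k) x (Lout*N)
  dXp <- array(0, c(C, Lp, N))
  pos0 <- (seq_len(Lout) - 1L) * stride
  for (kk in seq_len(k)) {
    dsub <- dM[((kk - 1L) * C + 1L):(kk * C), , drop = FALSE]
    dim(dsub) <- c(C, Lout, N)
    dXp[, pos0 + kk, ] <- dXp[, pos0 + kk, , drop = FALSE] + dsub
  }
  dX <- dXp[, (padL + 1L):(padL + L), , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

bn_fwd <- function(X, gamma, beta, run_mean, run_var, training,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(X); C <- d[1]; L <- d[2]; N <- d[3]
  Xm <- X
  dim(Xm) <- c(C, L * N)
  if (training) {
    mu <- rowMeans(Xm)
    va <- rowMeans(Xm^2) - mu^2
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    # unbiased running variance, matching the usual framework convention
    nn <- L * N
    run_var <- (1 - momentum) * run_var + momentum * va * nn / max(nn - 1, 1)
  } else {
    mu <- run_mean; va <- run_var
  }
  ivar <- 1 / sqrt(va + eps)
  xhat <- (X - mu) * ivar          # per-channel recycling along dim 1
  out <- xhat * gamma + beta
  list(out = out,
       cache = list(xhat = xhat, ivar = ivar, gamma = gamma,
                    C = C, L = L, N = N),
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(dout, cache) {
  xhat <- cache$xhat; ivar <- cache$ivar; gamma <- cache$gamma
  C <- cache$C; m <- cache$L * cache$N
  sum_c <- function(A) { dim(A) <- c(C, m); rowSums(A) }
  dgamma <- sum_c(dout * xhat)
  dbeta <- sum_c(dout)
  dxhat <- dout * gamma
  t1 <- sum_c(dxhat)
  t2 <- sum_c(dxhat * xhat)
  dX <- (dxhat - t1 / m - xhat * (t2 / m)) * ivar
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- architecture ------------------------------------------------------

resnet_arch <- function(config, n_bands) {
  n_down <- config$n_blocks %/% config$downsample_every
  if (n_bands < 2^n_down)
    stop("n_bands (", n_bands, ") must be >= 2^", n_down,
         " so every downsampled length stays positive")
  blocks <- vector("list", config$n_blocks)
  ch <- config$base_filters
  for (i in seq_len(config$n_blocks)) {
    down <- i %% config$downsample_every == 0L
    out_ch <- if (down) 2L * ch else ch
    blocks[[i]] <- list(in_ch = ch, out_ch = out_ch,
                        stride = if (down) 2L else 1L, project = down)
    ch <- out_ch
  }
  list(n_bands = n_bands, stem_ch = config$base_filters, blocks = blocks,
       head_ch = ch)
}

he_init <- function(fan_in, n_out) {
  matrix(stats::rnorm(fan_in * n_out, sd = sqrt(2 / fan_in)), fan_in, n_out)
}

#' Build an untrained 1-D residual network
#'
#' Initializes all parameters (He-normal convolution weights, unit/zero
#' batch-norm affine parameters) for the architecture described by
#' [resnet_config()] at a given band count. Deterministic given `seed`.
#'
#' @param config a [resnet_config()].
#' @param n_bands spectrum length the network will consume.
#' @param seed integer seed for weight initialization.
#' @return object of class `resnet1d` with flat parameter and batch-norm
#'   state lists plus the architecture description.
#' @export
build_resnet1d <- function(config, n_bands, seed = NULL) {
  stopifnot(inherits(config, "resnet_config"))
  if (!is.null(seed)) set.seed(seed)
  arch <- resnet_arch(config, n_bands)
  params <- list(); bn <- list()
  add_conv <- function(name, in_ch, k, out_ch) {
    params[[paste0(name, ".W")]] <<- he_init(in_ch * k, out_ch)
    params[[paste0(name, ".b")]] <<- numeric(out_ch)
  }
  add_bn <- function(name, ch) {
    params[[paste0(name, ".gamma")]] <<- rep(1, ch)
    params[[paste0(name, ".beta")]] <<- numeric(ch)
    bn[[paste0(name, ".mean")]] <<- numeric(ch)
    bn[[paste0(name, ".var")]] <<- rep(1, ch)
  }
  add_conv("stem.conv", 1L, config$stem_kernel, arch$stem_ch)
  add_bn("stem.bn", arch$stem_ch)
  for (i in seq_along(arch$blocks)) {
    bl <- arch$blocks[[i]]
    p <- sprintf("b%d", i)
    add_conv(paste0(p, ".conv1"), bl$in_ch, config$kernel_size, bl$out_ch)
    add_bn(paste0(p, ".bn1"), bl$out_ch)
    add_conv(paste0(p, ".conv2"), bl$out_ch, config$kernel_size, bl$out_ch)
    add_bn(paste0(p, ".bn2"), bl$out_ch)
    if (bl$project) {
      add_conv(paste0(p, ".proj"), bl$in_ch, 1L, bl$out_ch)
      add_bn(paste0(p, ".projbn"), bl$out_ch)
    }
  }
  params[["fc.W"]] <- matrix(stats::rnorm(arch$head_ch, sd = sqrt(1 / arch$head_ch)),
                             arch$head_ch, 1)
  params[["fc.b"]] <- 0
  structure(list(config = config, arch = arch, params = params, bn = bn),
            class = "resnet1d")
}

#' Number of trainable parameters of a network
#' @param model a `resnet1d`.
#' @return integer parameter count.
#' @export
resnet_n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# Forward pass. Returns predictions (length N), caches for backprop when
# `training`, and updated batch-norm running state.
resnet_forward <- function(model, X, training = FALSE, dropout_mask_rng = TRUE) {
  cfg <- model$config; arch <- model$arch
  P <- model$params; bn <- model$bn
  caches <- list()
  get_bn <- function(name) list(mean = bn[[paste0(name, ".mean")]],
                                var = bn[[paste0(name, ".var")]])
  run_bn <- function(name, X) {
    st <- get_bn(name)
    r <- bn_fwd(X, P[[paste0(name, ".gamma")]], P[[paste0(name, ".beta")]],
                st$mean, st$var, training)
    bn[[paste0(name, ".mean")]] <<- r$run_mean
    bn[[paste0(name, ".var")]] <<- r$run_var
    caches[[name]] <<- r$cache
    r$out
  }
  run_conv <- function(name, X, k, stride) {
    r <- conv1d_fwd(X, P[[paste0(name, ".W")]], P[[paste0(name, ".b")]], k, stride)
    caches[[name]] <<- r$cache
    r$out
  }

  h <- run_conv("stem.conv", X, cfg$stem_kernel, 1L)
  h <- run_bn("stem.bn", h)
  caches[["stem.relu"]] <- h > 0
  h <- h * caches[["stem.relu"]]

  for (i in seq_along(arch$blocks)) {
    bl <- arch$blocks[[i]]; p <- sprintf("b%d", i)
    x_in <- h
    h <- run_conv(paste0(p, ".conv1"), h, cfg$kernel_size, bl$stride)
    h <- run_bn(paste0(p, ".bn1"), h)
    caches[[paste0(p, ".relu1")]] <- h > 0
    h <- h * caches[[paste0(p, ".relu1")]]
    if (training && cfg$dropout_p > 0 && dropout_mask_rng) {
      mask <- array(stats::runif(length(h)) >= cfg$dropout_p, dim(h)) /
        (1 - cfg$dropout_p)
      caches[[paste0(p, ".drop")]] <- mask
      h <- h * mask
    }
    h <- run_conv(paste0(p, ".conv2"), h, cfg$kernel_size, 1L)
    h <- run_bn(paste0(p, ".bn2"), h)
    if (bl$project) {
      s <- run_conv(paste0(p, ".proj"), x_in, 1L, bl$stride)
      s <- run_bn(paste0(p, ".projbn"), s)
    } else {
      s <- x_in
    }
    h <- h + s
    caches[[paste0(p, ".relu2")]] <- h > 0
    h <- h * caches[[paste0(p, ".relu2")]]
  }

  d <- dim(h)                                   # (C, L, N)
  caches[["gap.L"]] <- d[2]
  g <- t(colSums(aperm(h, c(2, 1, 3))) / d[2])  # N x C
  caches[["gap.in_dim"]] <- d
  caches[["fc.in"]] <- g
  pred <- as.numeric(g %*% P[["fc.W"]]) + P[["fc.b"]]
  list(pred = pred, caches = caches, bn = bn)
}

# Backward pass for MAE loss; returns flat gradient list matching params.
resnet_backward <- function(model, caches, dpred) {
  cfg <- model$config; arch <- model$arch
  P <- model$params
  grads <- list()
  g <- caches[["fc.in"]]
  grads[["fc.W"]] <- crossprod(g, matrix(dpred, ncol = 1))
  grads[["fc.b"]] <- sum(dpred)
  dg <- matrix(dpred, ncol = 1) %*% t(P[["fc.W"]])            # N x C

  d <- caches[["gap.in_dim"]]                                 # (C, L, N)
  dh <- aperm(array(t(dg) / d[2], c(d[1], d[3], d[2])), c(1, 3, 2))

  bwd_bn <- function(name, dout) {
    r <- bn_bwd(dout, caches[[name]])
    grads[[paste0(name, ".gamma")]] <<- r$dgamma
    grads[[paste0(name, ".beta")]] <<- r$dbeta
    r$dX
  }
  bwd_conv <- function(name, dout) {
    r <- conv1d_bwd(dout, caches[[name]])
    grads[[paste0(name, ".W")]] <<- r$dW
    grads[[paste0(name, ".b")]] <<- r$db
    r$dX
  }

  for (i in rev(seq_along(arch$blocks))) {
    bl <- arch$blocks[[i]]; p <- sprintf("b%d", i)
    dh <- dh * caches[[paste0(p, ".relu2")]]
    dskip <- dh
    dmain <- bwd_bn(paste0(p, ".bn2"), dh)
    dmain <- bwd_conv(paste0(p, ".conv2"), dmain)
    mask <- caches[[paste0(p, ".drop")]]
    if (!is.null(mask)) dmain <- dmain * mask
    dmain <- dmain * caches[[paste0(p, ".relu1")]]
    dmain <- bwd_bn(paste0(p, ".bn1"), dmain)
    dmain <- bwd_conv(paste0(p, ".conv1"), dmain)
    if (bl$project) {
      ds <- bwd_bn(paste0(p, ".projbn"), dskip)
      ds <- bwd_conv(paste0(p, ".proj"), ds)
    } else {
      ds <- dskip
    }
    dh <- dmain + ds
  }

  dh <- dh * caches[["stem.relu"]]
  dh <- bwd_bn("stem.bn", dh)
  bwd_conv("stem.conv", dh)
  grads
}

# One Adam update in place; decay applies to conv/dense weight matrices only.
adam_step <- function(params, grads, state, lr, weight_decay, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (weight_decay > 0 && grepl("\\.W$", nm))
      g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

to_input_array <- function(X) {
  X <- as.matrix(X)
  array(t(X), c(1L, ncol(X), nrow(X)))                        # 1 x bands x N
}

resnet_predict_scaled <- function(object, Xs, chunk = 512L) {
  n <- nrow(Xs)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- resnet_forward(object$net, to_input_array(Xs[idx, , drop = FALSE]),
                         training = FALSE)
    out[idx] <- fw$pred
  }
  out
}

#' Train the 1-D residual network on a record table
#'
#' Min-max scales features and targets on the training fold, then runs
#' minibatch Adam on mean absolute error for up to `max_epochs` epochs with
#' shuffling. After each epoch the validation MAE (eval mode: batch-norm
#' running statistics, no dropout) is computed; training stops once it has
#' failed to improve by at least 1e-6 for `patience` consecutive epochs,
#' and the best-validation weights are restored. Reproducible given `seed`
#' (weight init, shuffling and dropout all draw from the seeded RNG).
#'
#' @param table record table.
#' @param split a `split_assignment` with a non-empty validation fold.
#' @param config a [resnet_config()].
#' @param batch_size overrides the config's batch size when given.
#' @param seed master integer seed.
#' @return a `jam_model` (kind `"resnet"`) with the trained network and a
#'   `history` data.frame of per-epoch train/val MAE (% sugar scale is NOT
#'   used here: history is on the scaled [0, 1] target).
#' @export
train_resnet <- function(table, split, config = resnet_config(),
                         batch_size = NULL, seed = 1L) {
  pf <- prepare_folds(table, split)
  assert_scaler_provenance(pf$scaler)
  if (length(pf$val) == 0L)
    stop("missing validation fold: early stopping needs one")
  if (is.null(batch_size)) batch_size <- config$batch_size
  n_tr <- length(pf$train)
  if (batch_size > n_tr)
    stop("batch size ", batch_size, " exceeds training set size ", n_tr)

  Xtr <- apply_scaler(pf$scaler, pf$X[pf$train, , drop = FALSE])
  ytr <- scale_target(pf$scaler, pf$y[pf$train])
  Xva <- apply_scaler(pf$scaler, pf$X[pf$val, , drop = FALSE])
  yva <- scale_target(pf$scaler, pf$y[pf$val])

  set.seed(seed)
  net <- build_resnet1d(config, ncol(Xtr))
  state <- list(m = lapply(net$params, function(p) p * 0),
                v = lapply(net$params, function(p) p * 0))
  t_step <- 0L
  best <- list(mae = Inf, params = net$params, bn = net$bn, epoch = 0L)
  wait <- 0L
  history <- data.frame(epoch = integer(0), train_mae = numeric(0),
                        val_mae = numeric(0))
  eval_mae <- function() {
    obj <- list(net = net)
    mean(abs(resnet_predict_scaled(obj, Xva) - yva))
  }

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_tr)
    starts <- seq(1L, n_tr, by = batch_size)
    epoch_abs <- 0
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, n_tr)]
      Xb <- to_input_array(Xtr[idx, , drop = FALSE])
      yb <- ytr[idx]
      fw <- resnet_forward(net, Xb, training = TRUE)
      net$bn <- fw$bn
      resid <- fw$pred - yb
      epoch_abs <- epoch_abs + sum(abs(resid))
      dpred <- sign(resid) / length(yb)
      grads <- resnet_backward(net, fw$caches, dpred)
      t_step <- t_step + 1L
      upd <- adam_step(net$params, grads, state, config$lr,
                       config$weight_decay, t_step)
      net$params <- upd$params
      state <- upd$state
    }
    val_mae <- eval_mae()
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_mae = epoch_abs / n_tr,
                                         val_mae = val_mae))
    if (!is.finite(val_mae))
      stop("non-finite validation loss at epoch ", epoch,
           "; last train MAE = ", epoch_abs / n_tr)
    if (val_mae < best$mae - 1e-6) {
      best <- list(mae = val_mae, params = net$params, bn = net$bn,
                   epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  net$params <- best$params
  net$bn <- best$bn

  structure(list(kind = "resnet", net = net, scaler = pf$scaler,
                 config = config, batch_size = batch_size, seed = seed,
                 history = history, best_epoch = best$epoch),
            class = "jam_model")
}
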