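# Residual convolutional denoising autoencoder.
#
# Activations live in arrays of shape (channels, length, samples); the 1-D
# convolutions are BLAS-backed C++ (src/conv_ops.cpp), everything else
# (ReLU, layer/batch norm, pooling, dropout, Adam) is vectorised R.
#
# Fixed topology (channel counts per conv layer input: 3,32,64,64,128,64,64,32):
#   conv1 conv2 [pool] conv3+skip conv4 [pool] conv5
#   [up] conv6+skip conv7 [up] conv8 -> 3 score channels
# ReLU + normalisation follow conv1..7; at the residual blocks the norm sits
# before the identity addition. Dropout follows the two pooled encoder
# stages and the bottleneck. Internal lengths are padded to a multiple of 4
# so the two pool/upsample pairs preserve length; padding is cropped on
# output and excluded from the loss.

CH_IN <- c(3L, 32L, 64L, 64L, 128L, 64L, 64L, 32L)
CH_OUT <- c(32L, 64L, 64L, 128L, 64L, 64L, 32L, 3L)
POOL_AFTER <- c(2L, 4L)
UP_BEFORE <- c(6L, 8L)
RES_AT <- c(3L, 6L)
DROP_AFTER <- c(2L, 4L, 5L)

#' Missing-rate-dependent dropout rate
#'
#' The regularisation strength is tied to the fraction of missing
#' genotypes `mr` in the corrupted training input by the empirical rule
#' `0.3 - (mr - 0.1) / 8` (clamped to `[0, 1)`): windows with more
#' corruption get slightly less dropout, since masking itself already
#' regularises.
#'
#' @param mr missing genotype fraction in `[0, 1]`.
#' @return dropout probability.
#' @examples
#' dropout_rate(0.1) # 0.3
#' @export
dropout_rate <- function(mr) {
  if (any(mr < 0 | mr > 1)) stop("mr must lie in [0, 1]")
  pmin(pmax(0.3 - (mr - 0.1) / 8, 0), 1 - 1e-12)
}

#' Autoencoder and training hyperparameters
#'
#' Collects the network and optimisation settings. Defaults follow the
#' reference configuration: kernel 15 (padding 7), training window of 1000
#' markers, batch size 64, at most 150 epochs of Adam (lr 1e-3, eps 1e-8,
#' weight decay 1e-5), and from epoch 101 a plateau schedule that
#' multiplies the learning rate by 0.9 after every epoch without
#' improvement of the monitored loss (patience 0, min mode). The ablation
#' flags reproduce the reduced variants: `residual`, `layernorm`,
#' `batchnorm` (replaces layer with batch normalisation), `dynamic_lr`,
#' `matching` (random masks instead of automatic matching) and
#' `augmentation` (no stacking of KNN-imputed testing rows).
#'
#' @param window training window size in markers.
#' @param kernel convolution kernel size (odd).
#' @param batch minibatch size.
#' @param max_epochs maximum training epochs.
#' @param lr0 initial Adam learning rate.
#' @param adam_eps Adam epsilon.
#' @param weight_decay L2 weight decay added to gradients.
#' @param sched_factor learning-rate reduction factor on plateau.
#' @param sched_patience epochs without improvement tolerated before a
#'   reduction.
#' @param sched_start_epoch epoch after which the schedule activates.
#' @param knn_k neighbour count for the KNN augmentation fill.
#' @param loss_scope `"known"` (cross-entropy over all positions with
#'   known clean genotype; default) or `"masked"` (masked positions only).
#' @param residual,layernorm,batchnorm,dynamic_lr,matching,augmentation
#'   ablation flags.
#' @param remask_per_epoch regenerate the matched masks every epoch
#'   instead of once per window.
#' @param seed integer seed controlling weight init, shuffling and dropout.
#' @param verbose print per-window progress to stderr.
#' @return object of class `network_config`.
#' @export
network_config <- function(window = 1000L, kernel = 15L, batch = 64L,
                           max_epochs = 150L, lr0 = 1e-3, adam_eps = 1e-8,
                           weight_decay = 1e-5, sched_factor = 0.9,
                           sched_patience = 0L, sched_start_epoch = 100L,
                           knn_k = 5L, loss_scope = c("known", "masked"),
                           residual = TRUE, layernorm = TRUE,
                           batchnorm = FALSE, dynamic_lr = TRUE,
                           matching = TRUE, augmentation = TRUE,
                           remask_per_epoch = FALSE,
                           seed = 1L, verbose = FALSE) {
  stopifnot(window >= 4L, kernel %% 2L == 1L, batch >= 1L, max_epochs >= 1L)
  structure(list(channels = CH_IN, window = as.integer(window),
                 kernel = as.integer(kernel),
                 padding = as.integer(kernel %/% 2L),
                 batch = as.integer(batch), max_epochs = as.integer(max_epochs),
                 lr0 = lr0, adam_eps = adam_eps, weight_decay = weight_decay,
                 sched_factor = sched_factor,
                 sched_patience = as.integer(sched_patience),
                 sched_start_epoch = as.integer(sched_start_epoch),
                 knn_k = as.integer(knn_k),
                 loss_scope = match.arg(loss_scope),
                 residual = residual, layernorm = layernorm,
                 batchnorm = batchnorm, dynamic_lr = dynamic_lr,
                 matching = matching, augmentation = augmentation,
                 remask_per_epoch = remask_per_epoch,
                 seed = as.integer(seed), verbose = verbose),
            class = "network_config")
}

#' Initialise an untrained autoencoder
#'
#' He-normal weight initialisation for the eight convolution layers plus
#' per-channel normalisation gain/bias. Uses the current RNG state.
#'
#' @param cfg a [network_config()].
#' @return object of class `dae_net` (parameter list + config).
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  k <- cfg$kernel
  layers <- lapply(seq_along(CH_IN), function(l) {
    fan_in <- CH_IN[l] * k
    list(W = matrix(rnorm(CH_OUT[l] * fan_in, sd = sqrt(2 / fan_in)),
                    CH_OUT[l], fan_in),
         b = numeric(CH_OUT[l]),
         gamma = rep(1, CH_OUT[l]), beta = numeric(CH_OUT[l]),
         run_mean = numeric(CH_OUT[l]), run_var = rep(1, CH_OUT[l]))
  })
  structure(list(layers = layers, cfg = cfg), class = "dae_net")
}

#' @export
print.dae_net <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b) +
                     length(l$gamma) + length(l$beta), 0))
  cat("residual convolutional denoising autoencoder:",
      length(x$layers), "conv layers,", np, "parameters\n")
  invisible(x)
}

n_parameters <- function(net) {
  sum(vapply(net$layers, function(l) length(l$W) + length(l$b), 0))
}

relu_fwd <- function(x) relu_cpp(x)
relu_fwd_r <- function(x) {
  x[x < 0] <- 0
  x
}

ln_fwd <- function(x, gamma, beta, eps = 1e-5) {
  layernorm_forward(x, gamma, beta, eps)
}

ln_bwd <- function(dy, cache, gamma) {
  layernorm_backward(dy, cache$xhat, cache$inv, gamma)
}

bn_fwd <- function(x, gamma, beta, run_mean, run_var, train, eps = 1e-5,
                   momentum = 0.1) {
  # normalise each channel over (positions, samples)
  d <- dim(x)
  nel <- d[2] * d[3]
  if (train) {
    mu <- rowMeans(x, dims = 1)
    xc <- x - array(mu, d)
    v <- rowMeans(xc * xc, dims = 1)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v * nel / max(nel - 1, 1)
  } else {
    mu <- run_mean
    v <- run_var
    xc <- x - array(mu, d)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * array(inv, d)
  list(y = xhat * array(gamma, d) + array(beta, d), xhat = xhat, inv = inv,
       run_mean = run_mean, run_var = run_var, train = train)
}

bn_bwd <- function(dy, cache, gamma) {
  d <- dim(dy)
  xhat <- cache$xhat
  dxhat <- dy * array(gamma, d)
  dgamma <- rowSums(dy * xhat, dims = 1)
  dbeta <- rowSums(dy, dims = 1)
  if (cache$train) {
    m1 <- rowMeans(dxhat, dims = 1)
    m2 <- rowMeans(dxhat * xhat, dims = 1)
    dx <- (dxhat - array(m1, d) - xhat * array(m2, d)) * array(cache$inv, d)
  } else {
    dx <- dxhat * array(cache$inv, d)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

pool_fwd <- function(x) {
  d <- dim(x)
  a <- x[, seq(1, d[2], 2), , drop = FALSE]
  b <- x[, seq(2, d[2], 2), , drop = FALSE]
  first <- a >= b # ties take the earlier position
  list(y = pmax(a, b), first = first)
}

pool_bwd <- function(dy, cache, L_in) {
  d <- dim(dy)
  dx <- array(0, c(d[1], L_in, d[3]))
  dx[, seq(1, L_in, 2), ] <- dy * cache$first
  dx[, seq(2, L_in, 2), ] <- dy * !cache$first
  dx
}

up_fwd <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

up_bwd <- function(dy) {
  d <- dim(dy)
  dy[, seq(1, d[2], 2), , drop = FALSE] + dy[, seq(2, d[2], 2), , drop = FALSE]
}

net_forward <- function(net, X, train = FALSE, drop_rate = 0,
                        keep_cache = FALSE) {
  cfg <- net$cfg
  cache <- if (keep_cache) vector("list", 8L) else NULL
  h <- X
  for (l in 1:8) {
    st <- list()
    if (l %in% UP_BEFORE) {
      h <- up_fwd(h)
    }
    if (cfg$residual && l %in% RES_AT) st$res_in <- h
    st$conv_in <- h
    h <- conv1d_forward(h, net$layers[[l]]$W, net$layers[[l]]$b, cfg$kernel)
    if (l < 8L) {
      st$pre_relu <- h
      h <- relu_fwd(h)
      if (cfg$batchnorm) {
        st$norm <- bn_fwd(h, net$layers[[l]]$gamma, net$layers[[l]]$beta,
                          net$layers[[l]]$run_mean, net$layers[[l]]$run_var,
                          train)
        if (train) {
          net$layers[[l]]$run_mean <- st$norm$run_mean
          net$layers[[l]]$run_var <- st$norm$run_var
        }
        h <- st$norm$y
      } else if (cfg$layernorm) {
        st$norm <- ln_fwd(h, net$layers[[l]]$gamma, net$layers[[l]]$beta)
        h <- st$norm$y
      }
      if (cfg$residual && l %in% RES_AT) h <- h + st$res_in
      if (l %in% POOL_AFTER) {
        st$pool_Lin <- dim(h)[2]
        st$pool <- pool_fwd(h)
        h <- st$pool$y
      }
      if (train && drop_rate > 0 && l %in% DROP_AFTER) {
        st$drop_mask <- array(runif(length(h)) >= drop_rate, dim(h)) /
          (1 - drop_rate)
        h <- h * st$drop_mask
      }
    }
    if (keep_cache) cache[[l]] <- st
  }
  list(scores = h, cache = cache, net = net)
}

net_backward <- function(net, fwd, dscores) {
  cfg <- net$cfg
  grads <- vector("list", 8L)
  dh <- dscores
  for (l in 8:1) {
    st <- fwd$cache[[l]]
    if (l < 8L) {
      if (!is.null(st$drop_mask)) dh <- dh * st$drop_mask
      if (l %in% POOL_AFTER) dh <- pool_bwd(dh, st$pool, st$pool_Lin)
      dres <- NULL
      if (cfg$residual && l %in% RES_AT) dres <- dh
      if (cfg$batchnorm) {
        nb <- bn_bwd(dh, st$norm, net$layers[[l]]$gamma)
        dh <- nb$dx; dgamma <- nb$dgamma; dbeta <- nb$dbeta
      } else if (cfg$layernorm) {
        nb <- ln_bwd(dh, st$norm, net$layers[[l]]$gamma)
        dh <- nb$dx; dgamma <- nb$dgamma; dbeta <- nb$dbeta
      } else {
        dgamma <- NULL; dbeta <- NULL
      }
      dh <- dh * (st$pre_relu > 0)
    } else {
      dgamma <- NULL; dbeta <- NULL
      dres <- NULL
    }
    cb <- conv1d_backward(st$conv_in, net$layers[[l]]$W, dh, cfg$kernel)
    grads[[l]] <- list(dW = cb$dW, db = as.numeric(cb$db),
                       dgamma = dgamma, dbeta = dbeta)
    dh <- cb$dX
    if (!is.null(dres)) dh <- dh + dres
    if (l %in% UP_BEFORE) dh <- up_bwd(dh)
  }
  grads
}

# cross-entropy over 3 genotype classes at weighted positions.
# Y: one-hot target cube; Wt: weight cube (nonzero where the loss applies).
ce_loss_grad <- function(scores, Y, Wt, grad = TRUE) {
  d <- dim(scores)
  mx <- apply(scores, c(2, 3), max)
  e <- exp(scores - rep(mx, each = d[1]))
  Z <- colSums(e, dims = 1)
  P <- e / rep(Z, each = d[1])
  nw <- sum(Wt) / 3 # Wt repeats the position weight over channels
  loss <- -sum(Y * log(pmax(P, 1e-12)) * Wt) / nw
  if (!grad) return(list(loss = loss))
  list(loss = loss, dscores = (P - Y) * Wt / nw)
}

codes_to_cube <- function(codes) {
  # (3, markers, samples) one-hot; code 0 -> zero channel triple
  n <- nrow(codes); p <- ncol(codes)
  arr <- array(0, c(3L, p, n))
  tc <- t(codes)
  for (k in 1:3) arr[k, , ] <- (tc == k) * 1
  arr
}

pad_len <- function(L, mult = 4L) as.integer(ceiling(L / mult) * mult)

pad_cube <- function(x, Lp) {
  d <- dim(x)
  if (d[2] == Lp) return(x)
  out <- array(0, c(d[1], Lp, d[3]))
  out[, seq_len(d[2]), ] <- x
  out
}

adam_init <- function(net) {
  lapply(net$layers, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0,
         mg = l$gamma * 0, vg = l$gamma * 0, mB = l$beta * 0, vB = l$beta * 0))
}

adam_step <- function(net, grads, state, lr, t, cfg) {
  b1 <- 0.9; b2 <- 0.999
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  upd <- function(p, g, m, v) {
    g <- g + cfg$weight_decay * p
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    p <- p - lr * (m / c1) / (sqrt(v / c2) + cfg$adam_eps)
    list(p = p, m = m, v = v)
  }
  for (l in 1:8) {
    gl <- grads[[l]]
    u <- upd(net$layers[[l]]$W, gl$dW, state[[l]]$mW, state[[l]]$vW)
    net$layers[[l]]$W <- u$p; state[[l]]$mW <- u$m; state[[l]]$vW <- u$v
    u <- upd(net$layers[[l]]$b, gl$db, state[[l]]$mb, state[[l]]$vb)
    net$layers[[l]]$b <- u$p; state[[l]]$mb <- u$m; state[[l]]$vb <- u$v
    if (!is.null(gl$dgamma)) {
      u <- upd(net$layers[[l]]$gamma, gl$dgamma, state[[l]]$mg, state[[l]]$vg)
      net$layers[[l]]$gamma <- u$p; state[[l]]$mg <- u$m; state[[l]]$vg <- u$v
      u <- upd(net$layers[[l]]$beta, gl$dbeta, state[[l]]$mB, state[[l]]$vB)
      net$layers[[l]]$beta <- u$p; state[[l]]$mB <- u$m; state[[l]]$vB <- u$v
    }
  }
  list(net = net, state = state)
}

#' Train the denoising autoencoder on one marker window
#'
#' Minimises the 3-class cross-entropy between the network's output scores
#' on the corrupted input and the clean genotype classes, at positions
#' where the clean genotype is genuinely known (originally missing
#' positions are excluded; with `loss_scope = "masked"` only the masked
#' positions enter). Optimisation is Adam with minibatches; the monitored
#' loss is the full training-set loss recomputed after every epoch, the
#' parameters are checkpointed whenever it improves, and after
#' `sched_start_epoch` epochs the learning rate is multiplied by
#' `sched_factor` on every epoch without improvement. The checkpointed
#' best model is returned.
#'
#' @param clean integer code matrix (rows x window markers), the clean
#'   training genotypes.
#' @param corrupted same shape, with masked entries set to 0.
#' @param cfg a [network_config()].
#' @param known optional logical matrix marking entries of `clean` that
#'   are genuine observations (defaults to `clean != 0`).
#' @param seed RNG seed for weight init, shuffling and dropout (defaults
#'   to `cfg$seed`).
#' @param corrupt_fn optional `function(epoch)` returning a fresh
#'   corrupted code matrix, for mask regeneration per epoch (matched
#'   masks are deterministic given the data, so this only changes
#'   behaviour for stochastic masking schemes).
#' @return object of class `trained_window`: checkpointed parameters,
#'   `best_loss`, `epochs_run` and a per-epoch `history` (loss, lr).
#' @export
train_window <- function(clean, corrupted, cfg = network_config(),
                         known = NULL, seed = cfg$seed, corrupt_fn = NULL) {
  if (inherits(clean, "genomat")) clean <- clean$codes
  if (inherits(corrupted, "genomat")) corrupted <- corrupted$codes
  stopifnot(identical(dim(clean), dim(corrupted)))
  if (is.null(known)) known <- clean != 0L
  known <- known & clean != 0L
  masked <- known & corrupted == 0L & clean != 0L
  loss_sel <- if (cfg$loss_scope == "masked" && any(masked)) masked else known
  if (!any(loss_sel)) stop("no known genotypes in this window to train on")
  n <- nrow(clean); w <- ncol(clean)
  Lp <- pad_len(w)
  Xc <- pad_cube(codes_to_cube(corrupted), Lp)
  Y <- pad_cube(codes_to_cube(clean), Lp)
  Wt <- array(0, c(3L, Lp, n))
  sel <- array(FALSE, c(Lp, n)); sel[seq_len(w), ] <- t(loss_sel)
  for (k in 1:3) Wt[k, , ] <- sel * 1
  mr <- mean(corrupted == 0L)
  dr <- dropout_rate(mr)
  set.seed(seed)
  net <- build_network(cfg)
  state <- adam_init(net)
  lr <- cfg$lr0
  best_loss <- Inf; best_net <- NULL
  stale <- 0L
  hist <- data.frame(epoch = integer(), loss = numeric(), lr = numeric())
  t_adam <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    if (!is.null(corrupt_fn) && epoch > 1L)
      Xc <- pad_cube(codes_to_cube(corrupt_fn(epoch)), Lp)
    perm <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch)
    for (s in starts) {
      idx <- perm[s:min(s + cfg$batch - 1L, n)]
      fwd <- net_forward(net, Xc[, , idx, drop = FALSE], train = TRUE,
                         drop_rate = dr, keep_cache = TRUE)
      net <- fwd$net # batchnorm running stats
      lg <- ce_loss_grad(fwd$scores, Y[, , idx, drop = FALSE],
                         Wt[, , idx, drop = FALSE])
      grads <- net_backward(net, fwd, lg$dscores)
      t_adam <- t_adam + 1L
      au <- adam_step(net, grads, state, lr, t_adam, cfg)
      net <- au$net; state <- au$state
    }
    ev <- net_forward(net, Xc, train = FALSE)
    mon <- ce_loss_grad(ev$scores, Y, Wt, grad = FALSE)$loss
    hist <- rbind(hist, data.frame(epoch = epoch, loss = mon, lr = lr))
    if (mon < best_loss) {
      best_loss <- mon
      best_net <- net
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (cfg$dynamic_lr && epoch > cfg$sched_start_epoch &&
          stale > cfg$sched_patience) {
        lr <- lr * cfg$sched_factor
        stale <- 0L
      }
    }
  }
  structure(list(net = best_net, cfg = cfg, best_loss = best_loss,
                 epochs_run = nrow(hist), history = hist,
                 mr = mr, drop_rate = dr, width = w, seed = seed),
            class = "trained_window")
}

#' @export
print.trained_window <- function(x, ...) {
  cat(sprintf(paste0("trained window model: %d markers, %d epochs, ",
                     "best loss %.5f (mr %.3f, dropout %.3f)\n"),
              x$width, x$epochs_run, x$best_loss, x$mr, x$drop_rate))
  invisible(x)
}

#' Impute a window with a trained model
#'
#' Runs the checkpointed best network on the corrupted input; each
#' position's genotype is the argmax of the three output score channels
#' (codes 1..3), and observed input positions are passed through
#' unchanged.
#'
#' @param model a [train_window()] result.
#' @param corrupted integer code matrix (rows x window markers), the rows
#'   to impute (0 = missing).
#' @return integer code matrix with no remaining 0 entries.
#' @export
predict_window <- function(model, corrupted) {
  if (inherits(corrupted, "genomat")) corrupted <- corrupted$codes
  if (ncol(corrupted) != model$width)
    stop("input width ", ncol(corrupted), " != model window width ",
         model$width)
  Lp <- pad_len(model$width)
  X <- pad_cube(codes_to_cube(corrupted), Lp)
  scores <- net_forward(model$net, X, train = FALSE)$scores
  d <- dim(scores)
  flat <- matrix(aperm(scores, c(2, 3, 1)), d[2] * d[3], 3L)
  pred <- matrix(max.col(flat, ties.method = "first"), d[2], d[3])
  pred <- t(pred)[, seq_len(model$width), drop = FALSE]
  out <- corrupted
  out[out == 0L] <- pred[out == 0L]
  storage.mode(out) <- "integer"
  out
}
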