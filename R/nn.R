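# Minimal neural-network engine for the residual SE classifier.
#
# Feature maps are stored as dense matrices of shape (T * B) x C, where T is
# the current temporal length, B = 12 * N is the number of independent
# series (lead-of-sample; the (K, 1) kernels never mix leads, so each lead
# is an independent time series until the squeeze stage), and C the channel
# count.  Rows are series-major with time contiguous within a series.
# Convolutions are K GEMMs (one per kernel tap) against a zero-padded copy,
# which keeps everything inside BLAS.  Layers are environments so that
# forward caches, gradients and momentum buffers update in place.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  for (nm in names(list(...))) assign(nm, list(...)[[nm]], envir = e)
  e
}

# He-style truncated-normal initialization (resampled beyond 2 sd).
init_weights <- function(n, fan_in) {
  sd <- sqrt(2 / fan_in)
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

new_conv <- function(kernel, c_in, c_out, stride) {
  W <- lapply(seq_len(kernel), function(k) {
    matrix(init_weights(c_in * c_out, kernel * c_in), c_in, c_out)
  })
  new_layer("conv", kernel = kernel, c_in = c_in, c_out = c_out,
            stride = stride, W = W, b = numeric(c_out),
            vW = lapply(W, function(w) w * 0), vb = numeric(c_out))
}

conv_fwd <- function(ly, X, T, B) {
  K <- ly$kernel; s <- ly$stride
  if (T %% s != 0L) {
    stop(sprintf("temporal length %d not divisible by stride %d", T, s))
  }
  T_out <- T %/% s
  pad <- K - s
  if (pad < 0L) stop("kernel smaller than stride")
  pl <- pad %/% 2L
  Tp <- T + pad
  Xp <- matrix(0, Tp * B, ly$c_in)
  place <- rep((seq_len(B) - 1L) * Tp, each = T) + pl + seq_len(T)
  Xp[place, ] <- X
  base <- rep((seq_len(B) - 1L) * Tp, each = T_out) +
    rep((seq_len(T_out) - 1L) * s, times = B)
  Y <- matrix(0, T_out * B, ly$c_out)
  for (k in seq_len(K)) {
    Y <- Y + Xp[base + k, , drop = FALSE] %*% ly$W[[k]]
  }
  Y <- sweep(Y, 2L, ly$b, `+`)
  ly$cache <- list(Xp = Xp, T = T, B = B, T_out = T_out, Tp = Tp,
                   place = place, base = base)
  list(Y = Y, T = T_out)
}

conv_bwd <- function(ly, dY) {
  cc <- ly$cache
  dXp <- matrix(0, nrow(cc$Xp), ly$c_in)
  gW <- vector("list", ly$kernel)
  for (k in seq_len(ly$kernel)) {
    rows <- cc$base + k
    gW[[k]] <- crossprod(cc$Xp[rows, , drop = FALSE], dY)
    dXp[rows, ] <- dXp[rows, , drop = FALSE] + dY %*% t(ly$W[[k]])
  }
  ly$gW <- gW
  ly$gb <- colSums(dY)
  dXp[cc$place, , drop = FALSE]
}

new_bn <- function(c) {
  new_layer("bn", gamma = rep(1, c), beta = numeric(c),
            run_mean = numeric(c), run_var = rep(1, c), momentum = 0.9,
            eps = 1e-5, vgamma = numeric(c), vbeta = numeric(c))
}

bn_fwd <- function(ly, X, train) {
  if (train) {
    mu <- colMeans(X)
    Xc <- sweep(X, 2L, mu)
    v <- colMeans(Xc^2)
    ly$run_mean <- ly$momentum * ly$run_mean + (1 - ly$momentum) * mu
    ly$run_var <- ly$momentum * ly$run_var + (1 - ly$momentum) * v
  } else {
    mu <- ly$run_mean; v <- ly$run_var
    Xc <- sweep(X, 2L, mu)
  }
  inv <- 1 / sqrt(v + ly$eps)
  Xh <- sweep(Xc, 2L, inv, `*`)
  if (train) ly$cache <- list(Xh = Xh, inv = inv)
  sweep(sweep(Xh, 2L, ly$gamma, `*`), 2L, ly$beta, `+`)
}

bn_bwd <- function(ly, dY) {
  cc <- ly$cache
  n <- nrow(dY)
  ly$ggamma <- colSums(dY * cc$Xh)
  ly$gbeta <- colSums(dY)
  dXh <- sweep(dY, 2L, ly$gamma, `*`)
  # standard batch-norm backward
  t1 <- sweep(dXh, 2L, colMeans(dXh))
  t2 <- sweep(cc$Xh, 2L, colMeans(dXh * cc$Xh), `*`)
  sweep(t1 - t2, 2L, cc$inv, `*`)
}

new_relu <- function() new_layer("relu")
relu_fwd <- function(ly, X, train) {
  m <- X > 0
  if (train) ly$mask <- m
  X * m
}
relu_bwd <- function(ly, dY) dY * ly$mask

new_dropout <- function(rate) new_layer("dropout", rate = rate)
dropout_fwd <- function(ly, X, train) {
  if (!train || ly$rate <= 0) return(X)
  keep <- 1 - ly$rate
  m <- matrix(stats::runif(length(X)) < keep, nrow(X)) / keep
  ly$mask <- m
  X * m
}
dropout_bwd <- function(ly, dY) {
  if (ly$rate <= 0) dY else dY * ly$mask
}

new_dense <- function(c_in, c_out) {
  new_layer("dense", c_in = c_in, c_out = c_out,
            W = matrix(init_weights(c_in * c_out, c_in), c_in, c_out),
            b = numeric(c_out),
            vW = matrix(0, c_in, c_out), vb = numeric(c_out))
}
dense_fwd <- function(ly, X, train) {
  if (train) ly$cache <- X
  sweep(X %*% ly$W, 2L, ly$b, `+`)
}
dense_bwd <- function(ly, dY) {
  ly$gW <- crossprod(ly$cache, dY)
  ly$gb <- colSums(dY)
  dY %*% t(ly$W)
}

# (2, 1) max pool over time with optional zero-padded channel growth: the
# shortcut path of a dimension-changing residual block.
pool_fwd <- function(X, T, c_out) {
  a <- X[seq(1L, nrow(X), by = 2L), , drop = FALSE]
  b <- X[seq(2L, nrow(X), by = 2L), , drop = FALSE]
  m <- a >= b
  Y <- a * m + b * (!m)
  if (c_out > ncol(X)) Y <- cbind(Y, matrix(0, nrow(Y), c_out - ncol(X)))
  list(Y = Y, mask = m, T = T %/% 2L, c_in = ncol(X))
}
pool_bwd <- function(cache, dY) {
  dYc <- dY[, seq_len(cache$c_in), drop = FALSE]
  dX <- matrix(0, 2L * nrow(dYc), cache$c_in)
  dX[seq(1L, nrow(dX), by = 2L), ] <- dYc * cache$mask
  dX[seq(2L, nrow(dX), by = 2L), ] <- dYc * (!cache$mask)
  dX
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# SGD with momentum on every parameterized layer.
sgd_step <- function(layers, lr, momentum) {
  for (ly in layers) {
    if (ly$type == "conv") {
      for (k in seq_along(ly$W)) {
        ly$vW[[k]] <- momentum * ly$vW[[k]] - lr * ly$gW[[k]]
        ly$W[[k]] <- ly$W[[k]] + ly$vW[[k]]
      }
      ly$vb <- momentum * ly$vb - lr * ly$gb
      ly$b <- ly$b + ly$vb
    } else if (ly$type == "dense") {
      ly$vW <- momentum * ly$vW - lr * ly$gW
      ly$W <- ly$W + ly$vW
      ly$vb <- momentum * ly$vb - lr * ly$gb
      ly$b <- ly$b + ly$vb
    } else if (ly$type == "bn") {
      ly$vgamma <- momentum * ly$vgamma - lr * ly$ggamma
      ly$gamma <- ly$gamma + ly$vgamma
      ly$vbeta <- momentum * ly$vbeta - lr * ly$gbeta
      ly$beta <- ly$beta + ly$vbeta
    }
  }
}

layer_params <- function(ly) {
  switch(ly$type,
         conv = c(ly$W, list(ly$b)),
         dense = list(ly$W, ly$b),
         bn = list(ly$gamma, ly$beta, ly$run_mean, ly$run_var),
         list())
}

snapshot_params <- function(layers) lapply(layers, layer_params)

restore_params <- function(layers, snap) {
  for (i in seq_along(layers)) {
    ly <- layers[[i]]; p <- snap[[i]]
    if (ly$type == "conv") {
      ly$W <- p[seq_len(ly$kernel)]
      ly$b <- p[[ly$kernel + 1L]]
    } else if (ly$type == "dense") {
      ly$W <- p[[1L]]; ly$b <- p[[2L]]
    } else if (ly$type == "bn") {
      ly$gamma <- p[[1L]]; ly$beta <- p[[2L]]
      ly$run_mean <- p[[3L]]; ly$run_var <- p[[4L]]
    }
  }
  invisible(layers)
}
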