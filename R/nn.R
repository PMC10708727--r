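#' @title Minimal neural-network engine
#' @description Base-R layers (input standardization, 1D convolution, LSTM,
#'   batch normalization, residual block, global average pooling, dense) with
#'   hand-derived backpropagation and an Adam optimizer. Batches are 3D
#'   arrays `(batch, time, features)`. Deliberately desk-scale: dense matrix
#'   algebra, single-threaded, deterministic under a seed.
#' @name nn
#' @keywords internal
NULL

.mat2 <- function(X) {           # (B,T,F) -> (B*T, F), rows vary batch fastest
  d <- dim(X)
  dim(X) <- c(d[1L] * d[2L], d[3L])
  X
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- layer constructors -----------------------------------------------------

.layer_input_norm <- function(n_features) {
  list(type = "input_norm", trainable = FALSE,
       params = list(),
       mu = rep(0, n_features), sd = rep(1, n_features), fitted = FALSE)
}

.layer_conv1d <- function(k, f_in, f_out, activation = "relu") {
  sc <- sqrt(2 / (k * f_in))
  list(type = "conv1d", trainable = TRUE, activation = activation, k = k,
       params = list(W = array(stats::rnorm(k * f_in * f_out, 0, sc),
                               c(k, f_in, f_out)),
                     b = rep(0, f_out)))
}

.layer_lstm <- function(f_in, units, return_seq = TRUE) {
  list(type = "lstm", trainable = TRUE, units = units, return_seq = return_seq,
       params = list(
         Wx = matrix(stats::rnorm(f_in * 4L * units, 0, sqrt(1 / f_in)),
                     f_in, 4L * units),
         Wh = matrix(stats::rnorm(units * 4L * units, 0, sqrt(1 / units)),
                     units, 4L * units),
         b = c(rep(0, units), rep(1, units), rep(0, 2L * units))))  # forget bias 1
}

.layer_batchnorm <- function(channels, momentum = 0.9, eps = 1e-5) {
  list(type = "batchnorm", trainable = TRUE, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, channels), beta = rep(0, channels)),
       running_mean = rep(0, channels), running_var = rep(1, channels))
}

.layer_activation <- function() {
  list(type = "activation", trainable = FALSE, params = list())
}

.layer_gap <- function() list(type = "gap", trainable = FALSE, params = list())

.layer_dense <- function(f_in, f_out) {
  sc <- sqrt(6 / (f_in + f_out))
  list(type = "dense", trainable = TRUE,
       params = list(W = matrix(stats::runif(f_in * f_out, -sc, sc),
                                f_in, f_out),
                     b = rep(0, f_out)))
}

.layer_resblock <- function(k, f_in, f_out) {
  proj <- if (f_in != f_out) .layer_conv1d(1L, f_in, f_out, "linear") else NULL
  list(type = "resblock", trainable = TRUE, k = k,
       params = list(),
       conv1 = .layer_conv1d(k, f_in, f_out, "relu"),
       conv2 = .layer_conv1d(k, f_out, f_out, "relu"),
       conv3 = .layer_conv1d(k, f_out, f_out, "linear"),
       bn = .layer_batchnorm(f_out),
       proj = proj)
}

# ---- forward ----------------------------------------------------------------

.fw_input_norm <- function(layer, X) {
  d <- dim(X)
  Xm <- .mat2(X)
  Xm <- sweep(Xm, 2L, layer$mu, "-")
  Xm <- sweep(Xm, 2L, layer$sd, "/")
  dim(Xm) <- d
  list(out = Xm, cache = NULL)
}

.fw_conv1d <- function(layer, X) {
  d <- dim(X); B <- d[1L]; Tt <- d[2L]; Fin <- d[3L]
  K <- layer$k; Fout <- dim(layer$params$W)[3L]
  pl <- (K - 1L) %/% 2L
  Xp <- array(0, c(B, Tt + K - 1L, Fin))
  Xp[, pl + seq_len(Tt), ] <- X
  Z <- matrix(0, B * Tt, Fout)
  for (j in seq_len(K)) {
    Xj <- Xp[, j:(j + Tt - 1L), , drop = FALSE]
    dim(Xj) <- c(B * Tt, Fin)
    Wj <- layer$params$W[j, , , drop = FALSE]
    dim(Wj) <- c(Fin, Fout)
    Z <- Z + Xj %*% Wj
  }
  Z <- sweep(Z, 2L, layer$params$b, "+")
  if (layer$activation == "relu") {
    mask <- Z > 0
    Z <- Z * mask
  } else mask <- NULL
  out <- Z
  dim(out) <- c(B, Tt, Fout)
  list(out = out, cache = list(Xp = Xp, mask = mask, B = B, Tt = Tt,
                               Fin = Fin))
}

.bw_conv1d <- function(layer, cache, dOut) {
  B <- cache$B; Tt <- cache$Tt; Fin <- cache$Fin
  K <- layer$k; Fout <- dim(layer$params$W)[3L]
  dZ <- dOut
  dim(dZ) <- c(B * Tt, Fout)
  if (!is.null(cache$mask)) dZ <- dZ * cache$mask
  dW <- array(0, dim(layer$params$W))
  dXp <- array(0, dim(cache$Xp))
  for (j in seq_len(K)) {
    Xj <- cache$Xp[, j:(j + Tt - 1L), , drop = FALSE]
    dim(Xj) <- c(B * Tt, Fin)
    dW[j, , ] <- crossprod(Xj, dZ)
    Wj <- layer$params$W[j, , , drop = FALSE]
    dim(Wj) <- c(Fin, Fout)
    dXj <- tcrossprod(dZ, Wj)
    dim(dXj) <- c(B, Tt, Fin)
    dXp[, j:(j + Tt - 1L), ] <- dXp[, j:(j + Tt - 1L), , drop = FALSE] + dXj
  }
  pl <- (K - 1L) %/% 2L
  list(dX = dXp[, pl + seq_len(Tt), , drop = FALSE],
       grads = list(W = dW, b = colSums(dZ)))
}

.fw_lstm <- function(layer, X) {
  d <- dim(X); B <- d[1L]; Tt <- d[2L]
  H <- layer$units
  Wx <- layer$params$Wx; Wh <- layer$params$Wh; b <- layer$params$b
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  gates <- vector("list", Tt); cs <- vector("list", Tt)
  hs <- vector("list", Tt); tanhc <- vector("list", Tt)
  cprev <- vector("list", Tt); hprev <- vector("list", Tt)
  out_seq <- if (layer$return_seq) array(0, c(B, Tt, H)) else NULL
  ih <- seq_len(H)
  for (t in seq_len(Tt)) {
    Xt <- X[, t, , drop = FALSE]
    dim(Xt) <- c(B, d[3L])
    A <- Xt %*% Wx + h %*% Wh
    A <- sweep(A, 2L, b, "+")
    i <- .sigmoid(A[, ih, drop = FALSE])
    f <- .sigmoid(A[, H + ih, drop = FALSE])
    g <- tanh(A[, 2L * H + ih, drop = FALSE])
    o <- .sigmoid(A[, 3L * H + ih, drop = FALSE])
    cprev[[t]] <- cc; hprev[[t]] <- h
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    gates[[t]] <- list(i = i, f = f, g = g, o = o)
    cs[[t]] <- cc; tanhc[[t]] <- tc; hs[[t]] <- h
    if (layer$return_seq) out_seq[, t, ] <- h
  }
  out <- if (layer$return_seq) out_seq else h
  list(out = out,
       cache = list(X = X, gates = gates, cs = cs, tanhc = tanhc,
                    cprev = cprev, hprev = hprev, B = B, Tt = Tt))
}

.bw_lstm <- function(layer, cache, dOut) {
  B <- cache$B; Tt <- cache$Tt; H <- layer$units
  Wx <- layer$params$Wx; Wh <- layer$params$Wh
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- rep(0, 4L * H)
  dX <- array(0, dim(cache$X))
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tt))) {
    dh <- dh_next
    if (layer$return_seq) {
      dh <- dh + array(dOut[, t, ], c(B, H))
    } else if (t == Tt) {
      dh <- dh + dOut
    }
    gt <- cache$gates[[t]]
    tc <- cache$tanhc[[t]]
    do_ <- dh * tc
    dc <- dc_next + dh * gt$o * (1 - tc^2)
    di <- dc * gt$g
    dg <- dc * gt$i
    df <- dc * cache$cprev[[t]]
    dc_next <- dc * gt$f
    dA <- cbind(di * gt$i * (1 - gt$i),
                df * gt$f * (1 - gt$f),
                dg * (1 - gt$g^2),
                do_ * gt$o * (1 - gt$o))
    Xt <- cache$X[, t, , drop = FALSE]
    dim(Xt) <- c(B, dim(cache$X)[3L])
    dWx <- dWx + crossprod(Xt, dA)
    dWh <- dWh + crossprod(cache$hprev[[t]], dA)
    db <- db + colSums(dA)
    dX[, t, ] <- tcrossprod(dA, Wx)
    dh_next <- tcrossprod(dA, Wh)
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

.fw_batchnorm <- function(layer, X, training) {
  d <- dim(X)
  Xm <- .mat2(X)
  if (training) {
    mu <- colMeans(Xm)
    xm <- sweep(Xm, 2L, mu, "-")
    v <- colMeans(xm^2)
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
    xm <- sweep(Xm, 2L, mu, "-")
  }
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(xm, 2L, inv, "*")
  out <- sweep(sweep(xhat, 2L, layer$params$gamma, "*"), 2L,
               layer$params$beta, "+")
  dim(out) <- d
  list(out = out,
       cache = list(xhat = xhat, inv = inv, d = d, mu = mu, v = v),
       new_running = if (training) {
         mm <- layer$momentum
         list(mean = mm * layer$running_mean + (1 - mm) * mu,
              var = mm * layer$running_var + (1 - mm) * v)
       } else NULL)
}

.bw_batchnorm <- function(layer, cache, dOut) {
  d <- cache$d
  dY <- .mat2(dOut)
  N <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, layer$params$gamma, "*")
  dx <- sweep(
    N * dxhat -
      matrix(colSums(dxhat), N, ncol(dY), byrow = TRUE) -
      xhat * matrix(colSums(dxhat * xhat), N, ncol(dY), byrow = TRUE),
    2L, cache$inv / N, "*")
  dim(dx) <- d
  list(dX = dx, grads = list(gamma = dgamma, beta = dbeta))
}

.fw_gap <- function(layer, X) {
  d <- dim(X)
  out <- matrix(apply(X, c(1L, 3L), mean), d[1L], d[3L])
  list(out = out, cache = list(d = d))
}

.bw_gap <- function(layer, cache, dOut) {
  d <- cache$d
  dX <- array(0, d)
  for (t in seq_len(d[2L])) dX[, t, ] <- dOut / d[2L]
  list(dX = dX, grads = list())
}

.fw_dense <- function(layer, X) {
  out <- sweep(X %*% layer$params$W, 2L, layer$params$b, "+")
  list(out = out, cache = list(X = X))
}

.bw_dense <- function(layer, cache, dOut) {
  list(dX = tcrossprod(dOut, layer$params$W),
       grads = list(W = crossprod(cache$X, dOut), b = colSums(dOut)))
}

.fw_activation <- function(layer, X) {
  mask <- X > 0
  list(out = X * mask, cache = list(mask = mask))
}

.fw_resblock <- function(layer, X, training) {
  r1 <- .fw_conv1d(layer$conv1, X)
  r2 <- .fw_conv1d(layer$conv2, r1$out)
  r3 <- .fw_conv1d(layer$conv3, r2$out)
  rb <- .fw_batchnorm(layer$bn, r3$out, training)
  if (!is.null(layer$proj)) {
    rp <- .fw_conv1d(layer$proj, X)
    skip <- rp$out
  } else rp <- NULL
  s <- rb$out + if (is.null(rp)) X else rp$out
  mask <- s > 0
  list(out = s * mask,
       cache = list(c1 = r1$cache, c2 = r2$cache, c3 = r3$cache,
                    bn = rb$cache, proj = if (is.null(rp)) NULL else rp$cache,
                    mask = mask),
       new_running = rb$new_running)
}

.bw_resblock <- function(layer, cache, dOut) {
  dS <- dOut * cache$mask
  gb <- .bw_batchnorm(layer$bn, cache$bn, dS)
  g3 <- .bw_conv1d(layer$conv3, cache$c3, gb$dX)
  g2 <- .bw_conv1d(layer$conv2, cache$c2, g3$dX)
  g1 <- .bw_conv1d(layer$conv1, cache$c1, g2$dX)
  grads <- list(conv1 = g1$grads, conv2 = g2$grads, conv3 = g3$grads,
                bn = gb$grads)
  if (!is.null(layer$proj)) {
    gp <- .bw_conv1d(layer$proj, cache$proj, dS)
    grads$proj <- gp$grads
    dX <- g1$dX + gp$dX
  } else {
    dX <- g1$dX + dS
  }
  list(dX = dX, grads = grads)
}

.layer_forward <- function(layer, X, training = FALSE) {
  switch(layer$type,
         input_norm = .fw_input_norm(layer, X),
         conv1d = .fw_conv1d(layer, X),
         lstm = .fw_lstm(layer, X),
         batchnorm = .fw_batchnorm(layer, X, training),
         activation = .fw_activation(layer, X),
         gap = .fw_gap(layer, X),
         dense = .fw_dense(layer, X),
         resblock = .fw_resblock(layer, X, training),
         stop("unknown layer type: ", layer$type))
}

.layer_backward <- function(layer, cache, dOut) {
  switch(layer$type,
         input_norm = list(dX = NULL, grads = list()),
         conv1d = .bw_conv1d(layer, cache, dOut),
         lstm = .bw_lstm(layer, cache, dOut),
         batchnorm = .bw_batchnorm(layer, cache, dOut),
         activation = list(dX = dOut * cache$mask, grads = list()),
         gap = .bw_gap(layer, cache, dOut),
         dense = .bw_dense(layer, cache, dOut),
         resblock = .bw_resblock(layer, cache, dOut),
         stop("unknown layer type: ", layer$type))
}

# ---- Adam -------------------------------------------------------------------

.adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

.adam_step <- function(params, grads, state, lr, t, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state[[nm]]$m <- b1 * state[[nm]]$m + (1 - b1) * g
    state[[nm]]$v <- b2 * state[[nm]]$v + (1 - b2) * g^2
    mhat <- state[[nm]]$m / (1 - b1^t)
    vhat <- state[[nm]]$v / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# apply an Adam update to a (possibly composite) layer
.layer_update <- function(layer, grads, lr, t) {
  if (layer$type == "resblock") {
    for (sub in c("conv1", "conv2", "conv3", "bn", "proj")) {
      if (is.null(layer[[sub]])) next
      layer[[sub]] <- .layer_update(layer[[sub]], grads[[sub]], lr, t)
    }
    return(layer)
  }
  if (length(layer$params) == 0L) return(layer)
  if (is.null(layer$opt)) layer$opt <- .adam_init(layer$params)
  res <- .adam_step(layer$params, grads, layer$opt, lr, t)
  layer$params <- res$params
  layer$opt <- res$state
  layer
}
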