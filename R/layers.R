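#' Neural-network layer primitives
#'
#' A compact layer framework with hand-written forward and backward passes,
#' used to build the TCN / attention / LSTM estimators. There is no
#' automatic differentiation in this stack, so every layer implements its
#' own exact gradient; correctness is enforced by numeric gradient checks
#' in the test suite.
#'
#' Tensor convention: a batch is an array of dimension `(N, T, C)` --
#' window, time step, channel. Layers are environments carrying `params`,
#' `grads`, per-parameter Adam state and a forward cache.
#'
#' @name layers
#' @keywords internal
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

# time slice as a guaranteed N x C matrix
slice_t <- function(X, t) matrix(X[, t, ], nrow = dim(X)[1])

mat3 <- function(X) matrix(X, nrow = dim(X)[1] * dim(X)[2])
unmat3 <- function(M, d) array(M, d)

# shift a (N,T,C) tensor right in time by `lag`, zero-filling the front
shift_time <- function(X, lag) {
  if (lag == 0) return(X)
  d <- dim(X)
  Y <- array(0, d)
  if (lag < d[2]) Y[, (lag + 1):d[2], ] <- X[, 1:(d[2] - lag), , drop = FALSE]
  Y
}

# adjoint of shift_time
shift_time_back <- function(G, lag) {
  if (lag == 0) return(G)
  d <- dim(G)
  Y <- array(0, d)
  if (lag < d[2]) Y[, 1:(d[2] - lag), ] <- G[, (lag + 1):d[2], , drop = FALSE]
  Y
}

new_layer <- function(.kind, ...) {
  l <- new.env(parent = emptyenv())
  l$kind <- .kind
  l$params <- list()
  l$grads <- list()
  l$cache <- list()
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = l)
  class(l) <- c(paste0("layer_", .kind), "layer")
  l
}

uinit <- function(fan_in, dims) {
  b <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -b, b), dims)
}

## ---- causal dilated convolution ------------------------------------------

layer_conv1d <- function(cin, cout, K, d = 1L) {
  l <- new_layer("conv1d", cin = cin, cout = cout, K = as.integer(K),
                 d = as.integer(d))
  l$params$W <- lapply(seq_len(K), function(k) uinit(K * cin, c(cin, cout)))
  l$params$b <- numeric(cout)
  l
}

conv1d_forward <- function(l, X) {
  d <- dim(X)
  Y <- matrix(rep(l$params$b, each = d[1] * d[2]), d[1] * d[2], l$cout)
  for (k in seq_len(l$K)) {
    lag <- (k - 1L) * l$d
    Y <- Y + mat3(shift_time(X, lag)) %*% l$params$W[[k]]
  }
  l$cache$X <- X
  unmat3(Y, c(d[1], d[2], l$cout))
}

conv1d_backward <- function(l, dY) {
  X <- l$cache$X
  d <- dim(X)
  dYm <- mat3(dY)
  l$grads$b <- colSums(dYm)
  dW <- vector("list", l$K)
  dX <- array(0, d)
  for (k in seq_len(l$K)) {
    lag <- (k - 1L) * l$d
    dW[[k]] <- crossprod(mat3(shift_time(X, lag)), dYm)
    G <- unmat3(dYm %*% t(l$params$W[[k]]), d)
    dX <- dX + shift_time_back(G, lag)
  }
  l$grads$W <- dW
  dX
}

## ---- batch normalization --------------------------------------------------

layer_batchnorm <- function(C, momentum = 0.1, eps = 1e-5) {
  l <- new_layer("batchnorm", C = C, momentum = momentum, eps = eps)
  l$params$gamma <- rep(1, C)
  l$params$beta <- rep(0, C)
  l$run_mean <- rep(0, C)
  l$run_var <- rep(1, C)
  l
}

batchnorm_forward <- function(l, X, train) {
  d <- dim(X)
  Xm <- mat3(X)
  if (train) {
    mu <- colMeans(Xm)
    xc <- sweep(Xm, 2, mu)
    v <- colMeans(xc^2)
    ivar <- 1 / sqrt(v + l$eps)
    xhat <- sweep(xc, 2, ivar, "*")
    l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
    l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * v
    l$cache <- list(xhat = xhat, ivar = ivar, d = d, train = TRUE)
  } else {
    ivar <- 1 / sqrt(l$run_var + l$eps)
    xhat <- sweep(sweep(Xm, 2, l$run_mean), 2, ivar, "*")
    l$cache <- list(xhat = xhat, ivar = ivar, d = d, train = FALSE)
  }
  Y <- sweep(sweep(xhat, 2, l$params$gamma, "*"), 2, l$params$beta, "+")
  unmat3(Y, d)
}

batchnorm_backward <- function(l, dY) {
  cc <- l$cache
  dYm <- mat3(dY)
  xhat <- cc$xhat
  l$grads$gamma <- colSums(dYm * xhat)
  l$grads$beta <- colSums(dYm)
  dxhat <- sweep(dYm, 2, l$params$gamma, "*")
  if (cc$train) {
    M <- nrow(dYm)
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), "*")
    dX <- sweep(t1 - t2, 2, cc$ivar, "*")
  } else {
    dX <- sweep(dxhat, 2, cc$ivar, "*")
  }
  unmat3(dX, cc$d)
}

## ---- relu / dropout -------------------------------------------------------

layer_relu <- function() new_layer("relu")

relu_forward <- function(l, X) {
  l$cache$mask <- X > 0
  X * l$cache$mask
}

relu_backward <- function(l, dY) dY * l$cache$mask

layer_dropout <- function(p) new_layer("dropout", p = p)

dropout_forward <- function(l, X, train) {
  if (!train || l$p <= 0) {
    l$cache$mask <- NULL
    return(X)
  }
  m <- array(stats::runif(length(X)) >= l$p, dim(X)) / (1 - l$p)
  l$cache$mask <- m
  X * m
}

dropout_backward <- function(l, dY) {
  if (is.null(l$cache$mask)) dY else dY * l$cache$mask
}

## ---- residual block -------------------------------------------------------

# two (conv -> BN -> ReLU -> dropout) stages plus identity / 1x1 shortcut,
# ReLU after the addition
layer_residual <- function(cin, cout, K, d, dropout = 0.2) {
  main <- list(
    layer_conv1d(cin, cout, K, d), layer_batchnorm(cout), layer_relu(),
    layer_dropout(dropout),
    layer_conv1d(cout, cout, K, d), layer_batchnorm(cout), layer_relu(),
    layer_dropout(dropout))
  shortcut <- if (cin != cout) layer_conv1d(cin, cout, 1L, 1L) else NULL
  new_layer("residual", main = main, shortcut = shortcut)
}

residual_forward <- function(l, X, train) {
  h <- X
  for (sub in l$main) h <- layer_forward(sub, h, train)
  s <- if (is.null(l$shortcut)) X else layer_forward(l$shortcut, X, train)
  z <- h + s
  l$cache$mask <- z > 0
  z * l$cache$mask
}

residual_backward <- function(l, dY) {
  dz <- dY * l$cache$mask
  dh <- dz
  for (sub in rev(l$main)) dh <- layer_backward(sub, dh)
  ds <- if (is.null(l$shortcut)) dz else layer_backward(l$shortcut, dz)
  dh + ds
}

## ---- CBAM: channel then temporal ("spatial") attention --------------------

# Channel attention: temporal avg- and max-pooled descriptors through a
# shared two-layer MLP (C -> k -> C, no biases), summed, sigmoid.
# Spatial attention: channel-wise avg/max pooling to a 2-channel map,
# width-`kernel` convolution (symmetric zero padding) to one channel,
# sigmoid. `bypass = TRUE` turns the module into an exact identity
# (attention weights forced to 1), used for architectural ablation.
layer_cbam <- function(C, k = max(C %/% 8L, 1L), kernel = 3L,
                       bypass = FALSE) {
  l <- new_layer("cbam", C = C, k = as.integer(k), kernel = as.integer(kernel),
                 bypass = bypass)
  l$params$W0 <- uinit(C, c(C, k))
  l$params$W1 <- uinit(k, c(k, C))
  l$params$wconv <- uinit(2L * kernel, c(kernel, 2L))
  l$params$bconv <- 0
  l
}

cbam_forward <- function(l, X, train) {
  if (l$bypass) {
    l$cache <- list(bypass = TRUE)
    return(X)
  }
  d <- dim(X); N <- d[1]; T_ <- d[2]; C <- d[3]
  # temporal pooling
  A <- colMeans(aperm(X, c(2, 1, 3)), dims = 1)      # (N, C) avg over T
  A <- matrix(A, N, C)
  Mx <- slice_t(X, 1); idx <- matrix(1L, N, C)
  if (T_ > 1) for (t in 2:T_) {
    sl <- slice_t(X, t); upd <- sl > Mx
    Mx[upd] <- sl[upd]; idx[upd] <- t
  }
  za <- A %*% l$params$W0;  Ha <- pmax(za, 0)
  zm <- Mx %*% l$params$W0; Hm <- pmax(zm, 0)
  S <- Ha %*% l$params$W1 + Hm %*% l$params$W1
  Mc <- sigmoid(S)                                    # (N, C)
  mc3 <- aperm(array(Mc, c(N, C, T_)), c(1, 3, 2))
  F1 <- X * mc3
  # channel pooling
  F1m <- mat3(F1)                                     # (N*T, C)
  A2 <- matrix(rowMeans(F1m), N, T_)
  m2 <- F1m[, 1]; idx2 <- rep(1L, N * T_)
  if (C > 1) for (ch in 2:C) {
    v <- F1m[, ch]; upd <- v > m2
    m2[upd] <- v[upd]; idx2[upd] <- ch
  }
  M2 <- matrix(m2, N, T_)
  # width-`kernel` conv over time, symmetric zero padding
  half <- (l$kernel - 1L) %/% 2L
  pad <- function(M) cbind(matrix(0, N, half), M, matrix(0, N, half))
  A2p <- pad(A2); M2p <- pad(M2)
  s <- matrix(l$params$bconv, N, T_)
  for (j in seq_len(l$kernel)) {
    s <- s + l$params$wconv[j, 1] * A2p[, j:(j + T_ - 1), drop = FALSE] +
             l$params$wconv[j, 2] * M2p[, j:(j + T_ - 1), drop = FALSE]
  }
  Ms <- sigmoid(s)                                    # (N, T)
  out <- F1 * array(Ms, c(N, T_, C))
  l$cache <- list(bypass = FALSE, X = X, A = A, Mx = Mx, idx = idx,
                  za = za, zm = zm, Ha = Ha, Hm = Hm, Mc = Mc, mc3 = mc3,
                  F1 = F1, A2p = A2p, M2p = M2p, idx2 = idx2, Ms = Ms,
                  d = d, half = half)
  out
}

cbam_backward <- function(l, dY) {
  cc <- l$cache
  if (isTRUE(cc$bypass)) {
    l$grads <- lapply(l$params, function(p) array(0, dim(p) %||% length(p)))
    return(dY)
  }
  d <- cc$d; N <- d[1]; T_ <- d[2]; C <- d[3]
  ms3 <- array(cc$Ms, c(N, T_, C))
  dF1 <- dY * ms3
  dMs <- matrix(rowSums(mat3(dY) * mat3(cc$F1)), N, T_)
  ds <- dMs * cc$Ms * (1 - cc$Ms)
  # conv grads and input grads
  dwconv <- matrix(0, l$kernel, 2)
  dA2p <- matrix(0, N, T_ + 2L * cc$half)
  dM2p <- matrix(0, N, T_ + 2L * cc$half)
  for (j in seq_len(l$kernel)) {
    cols <- j:(j + T_ - 1)
    dwconv[j, 1] <- sum(ds * cc$A2p[, cols, drop = FALSE])
    dwconv[j, 2] <- sum(ds * cc$M2p[, cols, drop = FALSE])
    dA2p[, cols] <- dA2p[, cols] + l$params$wconv[j, 1] * ds
    dM2p[, cols] <- dM2p[, cols] + l$params$wconv[j, 2] * ds
  }
  l$grads$wconv <- dwconv
  l$grads$bconv <- sum(ds)
  ctr <- cc$half + seq_len(T_)
  dA2 <- dA2p[, ctr, drop = FALSE]
  dM2 <- dM2p[, ctr, drop = FALSE]
  # channel-pool adjoints into dF1
  dF1m <- mat3(dF1) + matrix(as.numeric(dA2), N * T_, C) / C
  r <- seq_len(N * T_)
  dF1m[cbind(r, cc$idx2)] <- dF1m[cbind(r, cc$idx2)] + as.numeric(dM2)
  dF1 <- unmat3(dF1m, d)
  # F1 = X * Mc
  dX <- dF1 * cc$mc3
  E <- dF1 * cc$X
  dMc <- matrix(colSums(aperm(E, c(2, 1, 3)), dims = 1), N, C)
  dS <- dMc * cc$Mc * (1 - cc$Mc)
  # shared MLP, two pooled branches
  dW1 <- crossprod(cc$Ha, dS) + crossprod(cc$Hm, dS)
  dHa <- (dS %*% t(l$params$W1)) * (cc$za > 0)
  dHm <- (dS %*% t(l$params$W1)) * (cc$zm > 0)
  dW0 <- crossprod(cc$A, dHa) + crossprod(cc$Mx, dHm)
  l$grads$W0 <- dW0
  l$grads$W1 <- dW1
  dA <- dHa %*% t(l$params$W0)
  dMx <- dHm %*% t(l$params$W0)
  # temporal pooling adjoints
  for (t in seq_len(T_)) {
    add <- dA / T_
    m <- cc$idx == t
    add[m] <- add[m] + dMx[m]
    dX[, t, ] <- slice_t(dX, t) + add
  }
  dX
}

## ---- LSTM -----------------------------------------------------------------

layer_lstm <- function(cin, H) {
  l <- new_layer("lstm", cin = cin, H = as.integer(H))
  l$params$Wx <- uinit(cin, c(cin, 4L * H))
  l$params$Wh <- uinit(H, c(H, 4L * H))
  b <- numeric(4L * H)
  b[H + seq_len(H)] <- 1   # forget-gate bias init
  l$params$b <- b
  l
}

lstm_forward <- function(l, X) {
  d <- dim(X); N <- d[1]; T_ <- d[2]; H <- l$H
  h <- matrix(0, N, H); cst <- matrix(0, N, H)
  Y <- array(0, c(N, T_, H))
  steps <- vector("list", T_)
  ix <- seq_len(H); fx <- H + ix; gx <- 2L * H + ix; ox <- 3L * H + ix
  for (t in seq_len(T_)) {
    Xt <- slice_t(X, t)
    z <- Xt %*% l$params$Wx + h %*% l$params$Wh +
      matrix(l$params$b, N, 4L * H, byrow = TRUE)
    gi <- sigmoid(z[, ix, drop = FALSE])
    gf <- sigmoid(z[, fx, drop = FALSE])
    gg <- tanh(z[, gx, drop = FALSE])
    go <- sigmoid(z[, ox, drop = FALSE])
    c_prev <- cst
    cst <- gf * c_prev + gi * gg
    tc <- tanh(cst)
    h_prev <- h
    h <- go * tc
    Y[, t, ] <- h
    steps[[t]] <- list(Xt = Xt, h_prev = h_prev, c_prev = c_prev,
                       gi = gi, gf = gf, gg = gg, go = go, tc = tc)
  }
  l$cache <- list(steps = steps, d = d)
  Y
}

lstm_backward <- function(l, dY) {
  cc <- l$cache
  d <- cc$d; N <- d[1]; T_ <- d[2]; H <- l$H
  ix <- seq_len(H); fx <- H + ix; gx <- 2L * H + ix; ox <- 3L * H + ix
  dWx <- array(0, dim(l$params$Wx)); dWh <- array(0, dim(l$params$Wh))
  db <- numeric(4L * H)
  dh_next <- matrix(0, N, H); dc_next <- matrix(0, N, H)
  dX <- array(0, d)
  for (t in rev(seq_len(T_))) {
    st <- cc$steps[[t]]
    dh <- slice_t(dY, t) + dh_next
    dgo <- dh * st$tc
    dc <- dh * st$go * (1 - st$tc^2) + dc_next
    dgi <- dc * st$gg
    dgf <- dc * st$c_prev
    dgg <- dc * st$gi
    dc_next <- dc * st$gf
    dz <- matrix(0, N, 4L * H)
    dz[, ix] <- dgi * st$gi * (1 - st$gi)
    dz[, fx] <- dgf * st$gf * (1 - st$gf)
    dz[, gx] <- dgg * (1 - st$gg^2)
    dz[, ox] <- dgo * st$go * (1 - st$go)
    dWx <- dWx + crossprod(st$Xt, dz)
    dWh <- dWh + crossprod(st$h_prev, dz)
    db <- db + colSums(dz)
    dh_next <- dz %*% t(l$params$Wh)
    dX[, t, ] <- dz %*% t(l$params$Wx)
  }
  l$grads$Wx <- dWx; l$grads$Wh <- dWh; l$grads$b <- db
  dX
}

## ---- linear head on the last time step ------------------------------------

layer_head <- function(cin, n_out) {
  l <- new_layer("head", cin = cin, n_out = as.integer(n_out))
  l$params$W <- uinit(cin, c(cin, n_out))
  l$params$b <- numeric(n_out)
  l
}

head_forward <- function(l, X) {
  d <- dim(X)
  Xl <- slice_t(X, d[2])
  l$cache <- list(Xl = Xl, d = d)
  sweep(Xl %*% l$params$W, 2, l$params$b, "+")
}

head_backward <- function(l, dY) {
  cc <- l$cache
  l$grads$W <- crossprod(cc$Xl, dY)
  l$grads$b <- colSums(dY)
  dX <- array(0, cc$d)
  dX[, cc$d[2], ] <- dY %*% t(l$params$W)
  dX
}

## ---- dispatch --------------------------------------------------------------

layer_forward <- function(l, X, train = FALSE) {
  switch(l$kind,
    conv1d    = conv1d_forward(l, X),
    batchnorm = batchnorm_forward(l, X, train),
    relu      = relu_forward(l, X),
    dropout   = dropout_forward(l, X, train),
    residual  = residual_forward(l, X, train),
    cbam      = cbam_forward(l, X, train),
    lstm      = lstm_forward(l, X),
    head      = head_forward(l, X),
    stop("unknown layer kind: ", l$kind))
}

layer_backward <- function(l, dY) {
  switch(l$kind,
    conv1d    = conv1d_backward(l, dY),
    batchnorm = batchnorm_backward(l, dY),
    relu      = relu_backward(l, dY),
    dropout   = dropout_backward(l, dY),
    residual  = residual_backward(l, dY),
    cbam      = cbam_backward(l, dY),
    lstm      = lstm_backward(l, dY),
    head      = head_backward(l, dY),
    stop("unknown layer kind: ", l$kind))
}

# flatten a layer tree into the list of parameter-bearing leaf layers
collect_layers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$kind == "residual") {
      out <- c(out, collect_layers(l$main))
      if (!is.null(l$shortcut)) out <- c(out, collect_layers(list(l$shortcut)))
    } else if (length(l$params) > 0) {
      out <- c(out, list(l))
    }
  }
  out
}

# total trainable parameter count
count_params_layers <- function(layers) {
  sum(vapply(collect_layers(layers), function(l) {
    sum(vapply(l$params, function(p) length(unlist(p)), numeric(1)))
  }, numeric(1)))
}
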