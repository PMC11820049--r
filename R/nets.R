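#' Estimator architectures
#'
#' Builds the cascaded TCN - CBAM - TCN regressor (`cb_tcn`) and its four
#' comparison estimators: `ed_tcn` (encoder-decoder TCN, i.e. the same
#' cascade with the attention module removed), `tcn` (single TCN stage),
#' `lstm` (recurrent gated stack) and `wiener` (ridge-regularized FIR
#' least squares, see [wiener_fit()]). All networks consume a window of
#' envelope samples (`N x W x n_channels`) and emit one angle vector per
#' window from a linear head on the last time step's features. Causal
#' convolutions include the current sample with left zero padding of
#' `(K - 1) * d` (the standard convention; the one-sample-shifted textbook
#' indexing variant exists only as a test oracle).
#'
#' @name nets
NULL

#' Model specification
#'
#' Convolutional baselines share kernel size, channel width, block count
#' and dropout with `cb_tcn`; the LSTM mirrors the channel width as its
#' hidden size.
#'
#' @param architecture one of `"cb_tcn"`, `"ed_tcn"`, `"tcn"`, `"lstm"`,
#'   `"wiener"`.
#' @param channels feature channels per residual block (default 32; sized
#'   so the default 5-fold protocol trains in minutes on one CPU).
#' @param kernel convolution kernel size (default 3).
#' @param dilations dilation rate per residual block within one TCN stage
#'   (default `c(1, 2)`; length = blocks per stage). Receptive field of a
#'   stage is `1 + 2 * (K - 1) * sum(dilations)`.
#' @param dropout dropout rate inside residual blocks (default 0.1, sized
#'   with the default 32-channel width).
#' @param cbam_k attention-unit count (MLP hidden width); default
#'   `max(channels / 8, 1)`, the common reduction-ratio convention.
#' @param spatial_kernel temporal-attention convolution width (default 3).
#' @param lstm_hidden,lstm_layers LSTM stack shape (defaults mirror
#'   `channels` and 1).
#' @param lag_order,ridge Wiener baseline: FIR lag order (default: the
#'   window length at fit time) and ridge coefficient.
#' @param cbam_bypass force both attention maps to 1 (exact identity);
#'   `cb_tcn` with bypass equals `ed_tcn` given shared weights.
#' @export
model_spec <- function(architecture = c("cb_tcn", "ed_tcn", "tcn", "lstm",
                                        "wiener"),
                       channels = 32L, kernel = 3L, dilations = c(1L, 2L),
                       dropout = 0.1, cbam_k = NULL, spatial_kernel = 3L,
                       lstm_hidden = NULL, lstm_layers = 1L,
                       lag_order = NULL, ridge = 1e-6,
                       cbam_bypass = FALSE) {
  architecture <- match.arg(architecture)
  if (is.null(cbam_k)) cbam_k <- max(channels %/% 8L, 1L)
  if (is.null(lstm_hidden)) lstm_hidden <- channels
  structure(list(architecture = architecture, channels = as.integer(channels),
                 kernel = as.integer(kernel), dilations = as.integer(dilations),
                 dropout = dropout, cbam_k = as.integer(cbam_k),
                 spatial_kernel = as.integer(spatial_kernel),
                 lstm_hidden = as.integer(lstm_hidden),
                 lstm_layers = as.integer(lstm_layers),
                 lag_order = lag_order, ridge = ridge,
                 cbam_bypass = isTRUE(cbam_bypass)),
            class = "model_spec")
}

tcn_stage <- function(cin, spec) {
  layers <- list()
  for (d in spec$dilations) {
    layers <- c(layers, list(
      layer_residual(cin, spec$channels, spec$kernel, d, spec$dropout)))
    cin <- spec$channels
  }
  layers
}

#' Instantiate a network from a specification
#'
#' @param spec a [model_spec()] (not `wiener`, which is fit in closed
#'   form).
#' @param n_channels_in input channels (EMG envelopes).
#' @param n_joints output dimension.
#' @param seed initialization seed.
#' @return object of class `net_model`.
#' @export
build_model <- function(spec, n_channels_in, n_joints, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), spec$architecture != "wiener")
  layers <- with_seed(seed, {
    switch(spec$architecture,
      tcn = c(tcn_stage(n_channels_in, spec),
              list(layer_head(spec$channels, n_joints))),
      ed_tcn = c(tcn_stage(n_channels_in, spec),
                 tcn_stage(spec$channels, spec),
                 list(layer_head(spec$channels, n_joints))),
      cb_tcn = c(tcn_stage(n_channels_in, spec),
                 list(layer_cbam(spec$channels, spec$cbam_k,
                                 spec$spatial_kernel, spec$cbam_bypass)),
                 tcn_stage(spec$channels, spec),
                 list(layer_head(spec$channels, n_joints))),
      lstm = c({
        ls <- list(); cin <- n_channels_in
        for (i in seq_len(spec$lstm_layers)) {
          ls <- c(ls, list(layer_lstm(cin, spec$lstm_hidden)))
          cin <- spec$lstm_hidden
        }
        ls
      }, list(layer_head(spec$lstm_hidden, n_joints))))
  })
  structure(list(layers = layers, spec = spec,
                 n_channels_in = n_channels_in, n_joints = n_joints,
                 seed = seed),
            class = "net_model")
}

#' Forward pass
#'
#' @param model a `net_model`.
#' @param X input array `N x W x n_channels` (a batch of windows).
#' @param train training mode (batch statistics, dropout active).
#' @return `N x n_joints` matrix of predictions.
#' @export
model_forward <- function(model, X, train = FALSE) {
  h <- X
  for (l in model$layers) h <- layer_forward(l, h, train)
  h
}

model_backward <- function(model, dY) {
  g <- dY
  for (l in rev(model$layers)) g <- layer_backward(l, g)
  g
}

#' Predict joint angles for a window set
#'
#' Runs the network in evaluation mode (fixed normalization statistics, no
#' dropout). If `norm` is given, inputs are standardized with it and
#' predictions are mapped back to degrees.
#'
#' @param model a trained `net_model`.
#' @param ws a `window_set`.
#' @param norm optional `ws_normalizer` fitted on the training folds.
#' @param batch predict in chunks of this many windows.
#' @export
model_predict <- function(model, ws, norm = NULL, batch = 512L) {
  if (!is.null(norm)) ws <- apply_normalizer(ws, norm)
  n <- dim(ws$inputs)[1]
  out <- matrix(NA_real_, n, model$n_joints,
                dimnames = list(NULL, colnames(ws$targets)))
  for (at in seq(1L, n, by = batch)) {
    idx <- at:min(at + batch - 1L, n)
    out[idx, ] <- model_forward(model, ws$inputs[idx, , , drop = FALSE],
                                train = FALSE)
  }
  if (!is.null(norm)) {
    out <- sweep(sweep(out, 2, norm$y_sd, "*"), 2, norm$y_mean, "+")
  }
  out
}

#' Trainable parameter count
#' @param model a `net_model`.
#' @export
count_params <- function(model) count_params_layers(model$layers)

#' Standalone causal dilated convolution (single channel pair)
#'
#' Reference operation for the convolution used throughout the TCN stages:
#' `y_t = sum_{k=1..K} f_k x_{t - (k-1) d}` with left zero padding, i.e.
#' the current sample carries coefficient `f_1`.
#'
#' @param x numeric series.
#' @param f kernel coefficients `f_1 .. f_K`.
#' @param d dilation rate.
#' @export
causal_dilated_conv <- function(x, f, d = 1L) {
  T_ <- length(x)
  y <- numeric(T_)
  for (k in seq_along(f)) {
    lag <- (k - 1L) * d
    if (lag < T_) y[(lag + 1):T_] <- y[(lag + 1):T_] + f[k] * x[1:(T_ - lag)]
  }
  y
}

## ---- Wiener (FIR least squares) baseline ----------------------------------

#' Fit a Wiener (FIR) filter by ridge-regularized least squares
#'
#' Builds lagged regressors `[x_t, x_{t-1}, .., x_{t-L+1}]` across all
#' input channels plus an intercept and solves the normal equations
#' `(X'X + ridge I) c = X'y` (the intercept is not penalized). With
#' `ridge = 0` a singular system is surfaced as an error suggesting
#' regularization.
#'
#' @param envelopes `T x n_channels` input matrix.
#' @param angles `T x n_joints` target matrix.
#' @param lag_order number of lags L.
#' @param ridge ridge coefficient (default 0).
#' @return object of class `wiener_model`: coefficient matrix
#'   `(1 + L * n_channels) x n_joints`.
#' @export
wiener_fit <- function(envelopes, angles, lag_order = 10L, ridge = 0) {
  envelopes <- as.matrix(envelopes); angles <- as.matrix(angles)
  T_ <- nrow(envelopes)
  if (T_ < lag_order + 1) stop("need at least lag_order + 1 samples")
  X <- lag_design(envelopes, lag_order)
  y <- angles[lag_order:T_, , drop = FALSE]
  coef <- ridge_solve(cbind(1, X), y, ridge)
  structure(list(coef = coef, lag_order = as.integer(lag_order),
                 ridge = ridge, n_channels = ncol(envelopes),
                 joints = colnames(angles)),
            class = "wiener_model")
}

# rows t = L..T of [x_t, x_{t-1}, ..., x_{t-L+1}] for each channel
lag_design <- function(envelopes, L) {
  T_ <- nrow(envelopes)
  do.call(cbind, lapply(seq_len(ncol(envelopes)), function(ch) {
    sapply(0:(L - 1), function(j) envelopes[(L - j):(T_ - j), ch])
  }))
}

ridge_solve <- function(X, y, ridge) {
  p <- ncol(X)
  pen <- diag(ridge, p); pen[1, 1] <- 0   # don't penalize intercept
  xtx <- crossprod(X) + pen
  out <- tryCatch(solve(xtx, crossprod(X, y)), error = function(e) {
    if (ridge == 0) {
      stop("normal equations are singular; refit with ridge > 0",
           call. = FALSE)
    }
    stop(e)
  })
  out
}

#' @rdname wiener_fit
#' @param model a `wiener_model`.
#' @param new_envelopes `T x n_channels` series to predict from.
#' @return predictions aligned with `lag_order:T` of the input; the first
#'   `lag_order - 1` samples have no complete lag window and are returned
#'   as leading `NA` rows so the output has T rows.
#' @export
wiener_predict <- function(model, new_envelopes) {
  new_envelopes <- as.matrix(new_envelopes)
  X <- cbind(1, lag_design(new_envelopes, model$lag_order))
  pred <- X %*% model$coef
  out <- matrix(NA_real_, nrow(new_envelopes), ncol(pred),
                dimnames = list(NULL, model$joints))
  out[model$lag_order:nrow(new_envelopes), ] <- pred
  out
}

# Wiener fit/predict on window sets: a window of length W *is* the lag
# window, so the flattened window rows equal the lagged design matrix.
wiener_fit_windows <- function(ws, ridge = 0) {
  n <- dim(ws$inputs)[1]
  X <- cbind(1, matrix(ws$inputs[, rev(seq_len(dim(ws$inputs)[2])), ,
                                 drop = FALSE], nrow = n))
  coef <- ridge_solve(X, ws$targets, ridge)
  structure(list(coef = coef, lag_order = dim(ws$inputs)[2],
                 ridge = ridge, n_channels = dim(ws$inputs)[3],
                 joints = colnames(ws$targets)),
            class = "wiener_model")
}

wiener_predict_windows <- function(model, ws) {
  n <- dim(ws$inputs)[1]
  X <- cbind(1, matrix(ws$inputs[, rev(seq_len(dim(ws$inputs)[2])), ,
                                 drop = FALSE], nrow = n))
  out <- X %*% model$coef
  colnames(out) <- model$joints
  out
}
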