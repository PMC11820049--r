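#' Training recipe and cross-validation protocol
#'
#' Mini-batch Adam with MSE loss, L2 weight decay and a step-decay
#' learning-rate schedule (halved every 10 epochs from 0.001), batch size
#' 50, 50 epochs; evaluation by 5-fold cross-validation. Folds are formed
#' from whole trials by default (`by_block`): windows built with step 1
#' overlap in W - 1 samples, so randomly splitting windows (`by_window`)
#' leaks near-duplicates between training and validation -- the option
#' exists precisely so that this optimism can be demonstrated.
#'
#' @name trainer
NULL

#' Training specification
#'
#' @param lr0 initial learning rate (default 0.001).
#' @param lr_step epochs between learning-rate decays (default 10).
#' @param lr_gamma multiplicative decay factor (default 0.5).
#' @param epochs training epochs (default 50).
#' @param batch mini-batch size (default 50).
#' @param weight_decay L2 coefficient added to every parameter gradient
#'   (default 1e-4; unstated in the original recipe, configurable).
#' @param seed seed for shuffling, initialization offsets and dropout.
#' @param folds cross-validation folds (default 5).
#' @param split_policy `"by_block"` (whole trials per fold, leakage-free,
#'   default) or `"by_window"` (random window assignment).
#' @param clip_grad optional gradient-norm clip; `Inf` disables (default).
#' @export
train_spec <- function(lr0 = 0.001, lr_step = 10L, lr_gamma = 0.5,
                       epochs = 50L, batch = 50L, weight_decay = 1e-4,
                       seed = 1L, folds = 5L,
                       split_policy = c("by_block", "by_window"),
                       clip_grad = Inf) {
  stopifnot(epochs >= 1, folds >= 2, batch >= 1, lr0 > 0)
  structure(list(lr0 = lr0, lr_step = as.integer(lr_step),
                 lr_gamma = lr_gamma, epochs = as.integer(epochs),
                 batch = as.integer(batch), weight_decay = weight_decay,
                 seed = as.integer(seed), folds = as.integer(folds),
                 split_policy = match.arg(split_policy),
                 clip_grad = clip_grad),
            class = "train_spec")
}

#' Learning rate at a given (0-based) epoch
#'
#' `lr(e) = lr0 * lr_gamma ^ floor(e / lr_step)`.
#'
#' @param epoch integer epoch index, 0-based.
#' @param spec a [train_spec()].
#' @export
lr_at <- function(epoch, spec) {
  stopifnot(all(epoch >= 0))
  spec$lr0 * spec$lr_gamma^(epoch %/% spec$lr_step)
}

## ---- Adam ------------------------------------------------------------------

# parameters may be plain arrays or lists of arrays (conv taps); walk both
adam_init_state <- function(layers) {
  for (l in collect_layers(layers)) {
    l$adam <- lapply(l$params, function(p) {
      zero <- function(x) array(0, dim(x) %||% length(x))
      if (is.list(p)) list(m = lapply(p, zero), v = lapply(p, zero))
      else list(m = zero(p), v = zero(p))
    })
  }
  invisible(layers)
}

adam_step <- function(layers, lr, t, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      clip_grad = Inf) {
  leaves <- collect_layers(layers)
  if (is.finite(clip_grad)) {
    sq <- 0
    for (l in leaves) for (g in l$grads) {
      sq <- sq + sum(unlist(g)^2)
    }
    gn <- sqrt(sq)
    scale <- if (gn > clip_grad) clip_grad / gn else 1
  } else scale <- 1
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (l in leaves) {
    for (nm in names(l$params)) {
      p <- l$params[[nm]]; g <- l$grads[[nm]]; st <- l$adam[[nm]]
      one <- function(p1, g1, m1, v1) {
        g1 <- g1 * scale + weight_decay * p1
        m1 <- beta1 * m1 + (1 - beta1) * g1
        v1 <- beta2 * v1 + (1 - beta2) * g1^2
        p1 <- p1 - lr * (m1 / bc1) / (sqrt(v1 / bc2) + eps)
        list(p = p1, m = m1, v = v1)
      }
      if (is.list(p)) {
        for (k in seq_along(p)) {
          r <- one(p[[k]], g[[k]], st$m[[k]], st$v[[k]])
          p[[k]] <- r$p; st$m[[k]] <- r$m; st$v[[k]] <- r$v
        }
      } else {
        r <- one(p, g, st$m, st$v)
        p <- r$p; st$m <- r$m; st$v <- r$v
      }
      l$params[[nm]] <- p; l$adam[[nm]] <- st
    }
  }
  invisible(layers)
}

## ---- training --------------------------------------------------------------

#' Train a network on a window set
#'
#' Minimizes mean squared error over mini-batches under the step-decay
#' Adam recipe. If `norm` is supplied, inputs and targets are standardized
#' with it before fitting (fit it on training data only); predictions made
#' through [model_predict()] with the same normalizer come back in
#' degrees. All randomness (shuffling, dropout) derives from the spec
#' seed.
#'
#' @param model a `net_model` from [build_model()].
#' @param ws training `window_set`.
#' @param tspec a [train_spec()].
#' @param norm optional `ws_normalizer`.
#' @param verbose print per-epoch loss / lr.
#' @return the trained model with the per-epoch mean training loss attached
#'   as `$loss_trajectory` and lr as `$lr_trajectory`.
#' @export
train_model <- function(model, ws, tspec, norm = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "net_model"), inherits(tspec, "train_spec"))
  if (dim(ws$inputs)[1] == 0) stop("empty training set")
  if (!is.null(norm)) ws <- apply_normalizer(ws, norm, targets = TRUE)
  X <- ws$inputs; Y <- ws$targets
  n <- dim(X)[1]
  adam_init_state(model$layers)
  losses <- numeric(tspec$epochs)
  lrs <- numeric(tspec$epochs)
  step <- 0L
  with_seed(tspec$seed, {
    for (e in seq_len(tspec$epochs) - 1L) {
      lr <- lr_at(e, tspec)
      perm <- sample.int(n)
      bl <- 0; nb <- 0L
      for (at in seq(1L, n, by = tspec$batch)) {
        idx <- perm[at:min(at + tspec$batch - 1L, n)]
        xb <- X[idx, , , drop = FALSE]
        yb <- Y[idx, , drop = FALSE]
        pred <- model_forward(model, xb, train = TRUE)
        err <- pred - yb
        loss <- mean(err^2)
        if (!is.finite(loss)) {
          stop("training diverged (non-finite loss) at epoch ", e)
        }
        model_backward(model, 2 * err / length(err))
        step <- step + 1L
        adam_step(model$layers, lr, step, tspec$weight_decay,
                  clip_grad = tspec$clip_grad)
        bl <- bl + loss; nb <- nb + 1L
      }
      losses[e + 1L] <- bl / nb
      lrs[e + 1L] <- lr
      if (verbose) {
        message(sprintf("epoch %3d  lr %.2e  loss %.6f", e, lr, bl / nb))
      }
    }
  })
  model$loss_trajectory <- losses
  model$lr_trajectory <- lrs
  model
}

## ---- cross-validation ------------------------------------------------------

fold_assignment <- function(ws, tspec) {
  n <- dim(ws$inputs)[1]
  if (tspec$split_policy == "by_block") {
    trials <- sort(unique(ws$trial_ids))
    if (length(trials) < tspec$folds) {
      stop("only ", length(trials), " trials for ", tspec$folds,
           "-fold by_block splitting; use split_policy = \"by_window\" ",
           "or add trials")
    }
    trial_fold <- rep(seq_len(tspec$folds), length.out = length(trials))
    trial_fold[match(ws$trial_ids, trials)]
  } else {
    with_seed(tspec$seed + 7L,
              sample(rep(seq_len(tspec$folds), length.out = n)))
  }
}

#' k-fold cross-validation of one estimator
#'
#' Partitions windows into folds (whole trials per fold under
#' `by_block`), fits normalization on the training folds only, trains (or,
#' for the Wiener baseline, solves) the estimator, and returns per-fold
#' held-out predictions in degrees.
#'
#' @param mspec a [model_spec()].
#' @param ws full `window_set`.
#' @param tspec a [train_spec()].
#' @param verbose print per-epoch progress.
#' @return list of fold results: `fold`, `predictions`, `targets`,
#'   `test_idx`, `loss_trajectory` (NULL for wiener), `model`.
#' @export
cross_validate <- function(mspec, ws, tspec, verbose = FALSE) {
  stopifnot(inherits(mspec, "model_spec"))
  fold_of <- fold_assignment(ws, tspec)
  lapply(seq_len(tspec$folds), function(f) {
    tr <- subset_windows(ws, fold_of != f)
    te <- subset_windows(ws, fold_of == f)
    if (mspec$architecture == "wiener") {
      wm <- wiener_fit_windows(tr, ridge = mspec$ridge)
      pred <- wiener_predict_windows(wm, te)
      list(fold = f, predictions = pred, targets = te$targets,
           test_idx = which(fold_of == f), loss_trajectory = NULL,
           model = wm)
    } else {
      norm <- fit_normalizer(tr)
      model <- build_model(mspec, dim(ws$inputs)[3], ncol(ws$targets),
                           seed = tspec$seed + 100L * f)
      fold_tspec <- tspec
      fold_tspec$seed <- tspec$seed + 100L * f + 1L
      model <- train_model(model, tr, fold_tspec, norm = norm,
                           verbose = verbose)
      pred <- model_predict(model, te, norm = norm)
      list(fold = f, predictions = pred, targets = te$targets,
           test_idx = which(fold_of == f),
           loss_trajectory = model$loss_trajectory, model = model)
    }
  })
}

#' Cross-validate several estimators on the same folds
#'
#' @param specs named list of [model_spec()]s (names label the models).
#' @param ws full `window_set`.
#' @param tspec a [train_spec()] (shared; identical fold assignment).
#' @param verbose print progress.
#' @return tidy data.frame: model, joint, fold, n, r2, rmse, nrmse.
#' @export
run_comparison <- function(specs, ws, tspec, verbose = FALSE) {
  stopifnot(length(names(specs)) == length(specs))
  out <- list()
  for (nm in names(specs)) {
    if (verbose) message("cross-validating ", nm)
    folds <- cross_validate(specs[[nm]], ws, tspec, verbose = FALSE)
    out[[nm]] <- fold_metrics(folds, model = nm)
  }
  do.call(rbind, out)
}

# per-fold, per-joint metric rows from cross_validate() output
fold_metrics <- function(folds, model = "model") {
  rows <- list()
  for (fr in folds) {
    for (j in colnames(fr$targets)) {
      m <- metrics(fr$targets[, j], fr$predictions[, j])
      rows[[length(rows) + 1L]] <- data.frame(
        model = model, joint = j, fold = fr$fold, n = m$n,
        r2 = m$r2, rmse = m$rmse, nrmse = m$nrmse)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}
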