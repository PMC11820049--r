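#' Sliding-window dataset construction
#'
#' Expands per-trial envelope/angle series into overlapping fixed-length
#' windows, each an independent supervised sample: window `i` covers
#' samples `x_i ... x_{i+W-1}`, so with step `S = 1` a trial of length `T`
#' yields `T - W + 1` windows. The angle paired with a window follows the
#' target policy (default: the window's last sample, the causal choice).
#'
#' @name windows
NULL

#' Window specification
#'
#' @param W window length in samples (default 10).
#' @param S step between window starts in samples (default 1).
#' @param target_policy which time point's angle a window predicts:
#'   `"last_sample"` (causal, default) or `"center_sample"`.
#' @export
window_spec <- function(W = 10L, S = 1L,
                        target_policy = c("last_sample", "center_sample")) {
  stopifnot(W >= 1, S >= 1)
  structure(list(W = as.integer(W), S = as.integer(S),
                 target_policy = match.arg(target_policy)),
            class = "window_spec")
}

#' Number of windows for a trial of length T
#'
#' `floor((T - W) / S) + 1` when `T >= W`, else 0.
#' @param T series length; @param spec a [window_spec()].
#' @export
n_windows <- function(T, spec) {
  if (T < spec$W) return(0L)
  as.integer((T - spec$W) %/% spec$S + 1L)
}

#' Build the window set for one processed trial
#'
#' @param trial a `processed_trial` (or any list with `envelopes` and
#'   `angles` matrices of equal row count).
#' @param spec a [window_spec()].
#' @param trial_id integer provenance index stored per window.
#' @return object of class `window_set`: `inputs`
#'   (`n_windows x W x n_channels`), `targets` (`n_windows x n_joints`),
#'   `trial_ids`, `spec`.
#' @export
make_windows <- function(trial, spec = window_spec(), trial_id = 1L) {
  X <- trial$envelopes; Y <- trial$angles
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y))
  T_len <- nrow(X); W <- spec$W; S <- spec$S
  nw <- n_windows(T_len, spec)
  if (nw == 0L) {
    warning("trial length ", T_len, " < window length ", W,
            ": empty window set")
    return(empty_window_set(ncol(X), colnames(Y), spec))
  }
  starts <- seq(1L, by = S, length.out = nw)
  inputs <- array(NA_real_, c(nw, W, ncol(X)),
                  dimnames = list(NULL, NULL, colnames(X)))
  for (i in seq_len(nw)) {
    inputs[i, , ] <- X[starts[i]:(starts[i] + W - 1L), ]
  }
  tgt_idx <- switch(spec$target_policy,
                    last_sample = starts + W - 1L,
                    center_sample = starts + (W - 1L) %/% 2L)
  targets <- Y[tgt_idx, , drop = FALSE]
  structure(list(inputs = inputs, targets = targets,
                 trial_ids = rep(as.integer(trial_id), nw), spec = spec),
            class = "window_set")
}

empty_window_set <- function(n_channels, joint_names, spec) {
  structure(list(
    inputs = array(numeric(0), c(0, spec$W, n_channels)),
    targets = matrix(numeric(0), 0, length(joint_names),
                     dimnames = list(NULL, joint_names)),
    trial_ids = integer(0), spec = spec),
    class = "window_set")
}

#' Row-stack window sets from several trials
#'
#' Trial identifiers are preserved so folds can later be formed without
#' leaking overlapping windows across a trial boundary.
#'
#' @param sets list of `window_set` objects with identical channel/joint
#'   layout.
#' @export
concat_trials <- function(sets) {
  if (length(sets) == 0) stop("need at least a window spec; got empty list")
  stopifnot(all(vapply(sets, inherits, logical(1), "window_set")))
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (!identical(dim(s$inputs)[-1], dim(ref$inputs)[-1]) ||
        !identical(colnames(s$targets), colnames(ref$targets))) {
      stop("window sets have incompatible channel/joint layout")
    }
  }
  inputs <- do.call(abind_rows, lapply(sets, `[[`, "inputs"))
  structure(list(
    inputs = inputs,
    targets = do.call(rbind, lapply(sets, `[[`, "targets")),
    trial_ids = unlist(lapply(sets, `[[`, "trial_ids")),
    spec = ref$spec),
    class = "window_set")
}

# rbind for 3-D arrays along dim 1
abind_rows <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(NA_real_, c(n, d[2], d[3]), dimnames = dimnames(arrs[[1]]))
  at <- 0L
  for (a in arrs) {
    na <- dim(a)[1]
    if (na > 0) out[at + seq_len(na), , ] <- a
    at <- at + na
  }
  out
}

#' Subset a window set by row index
#' @param ws a `window_set`; @param idx integer/logical row index.
#' @export
subset_windows <- function(ws, idx) {
  structure(list(inputs = ws$inputs[idx, , , drop = FALSE],
                 targets = ws$targets[idx, , drop = FALSE],
                 trial_ids = ws$trial_ids[idx], spec = ws$spec),
            class = "window_set")
}

#' Per-channel normalization statistics (training data only)
#'
#' Computes per-channel mean/sd of the window inputs and per-joint mean/sd
#' of the targets. Fit these on training folds and apply to held-out folds
#' to avoid leakage.
#'
#' @param ws a `window_set`.
#' @export
fit_normalizer <- function(ws) {
  nc <- dim(ws$inputs)[3]
  xm <- numeric(nc); xs <- numeric(nc)
  for (ch in seq_len(nc)) {
    v <- ws$inputs[, , ch]
    xm[ch] <- mean(v); xs[ch] <- stats::sd(as.numeric(v))
  }
  xs[xs == 0] <- 1
  ym <- colMeans(ws$targets)
  ys <- apply(ws$targets, 2, stats::sd)
  ys[ys == 0] <- 1
  structure(list(x_mean = xm, x_sd = xs, y_mean = ym, y_sd = ys),
            class = "ws_normalizer")
}

#' @rdname fit_normalizer
#' @param norm a `ws_normalizer`.
#' @param targets also standardize the targets (used during fitting;
#'   predictions are mapped back to degrees).
#' @export
apply_normalizer <- function(ws, norm, targets = FALSE) {
  out <- ws
  for (ch in seq_len(dim(ws$inputs)[3])) {
    out$inputs[, , ch] <- (ws$inputs[, , ch] - norm$x_mean[ch]) / norm$x_sd[ch]
  }
  if (targets) {
    out$targets <- sweep(sweep(ws$targets, 2, norm$y_mean), 2, norm$y_sd, "/")
  }
  out
}

#' Serialize a window set to an array container + JSON sidecar
#'
#' The flattened input array is written as CSV (one row per window,
#' `W * n_channels` columns, channel-major) with targets and trial ids
#' appended; shapes and the window spec go to `<path>.json`.
#'
#' @param ws a `window_set`; @param path CSV path.
#' @export
write_windows <- function(ws, path) {
  n <- dim(ws$inputs)[1]
  flat <- matrix(ws$inputs, nrow = n)   # (t, ch) column-major flatten
  df <- data.frame(flat, ws$targets, trial_id = ws$trial_ids,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(shape = dim(ws$inputs), joints = colnames(ws$targets),
         channels = dimnames(ws$inputs)[[3]],
         spec = unclass(ws$spec)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  d <- meta$shape
  inputs <- array(as.matrix(df[, seq_len(d[2] * d[3]), drop = FALSE]), d,
                  dimnames = list(NULL, NULL, meta$channels))
  targets <- as.matrix(df[, d[2] * d[3] + seq_along(meta$joints), drop = FALSE])
  colnames(targets) <- meta$joints
  spec <- window_spec(meta$spec$W, meta$spec$S, meta$spec$target_policy)
  structure(list(inputs = inputs, targets = targets,
                 trial_ids = as.integer(df$trial_id), spec = spec),
            class = "window_set")
}
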