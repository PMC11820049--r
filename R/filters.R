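#' Filter specifications and digital IIR filtering
#'
#' Minimal digital-filter toolkit used by the preprocessing chain:
#' Butterworth low-pass / high-pass / band-pass design via bilinear
#' transform of the analog prototype, a Q-parameterised second-order notch,
#' single-pass (`lfilter`) and zero-phase forward-backward (`filtfilt`)
#' application. Filtering recursions are executed by [stats::filter()] at C
#' speed.
#'
#' @name filters
NULL

#' Create a filter specification
#'
#' @param kind one of `"butter_bandpass"`, `"butter_lowpass"`,
#'   `"butter_highpass"`, `"notch"`.
#' @param order filter order (Butterworth designs; a band-pass of order `n`
#'   has `2n` poles). Ignored for `"notch"`, which is always second order.
#' @param cutoff_hz one cutoff (low/high-pass, notch centre) or two
#'   (band-pass edges), in Hz. Must lie strictly inside (0, fs/2).
#' @param fs sampling rate in Hz.
#' @param q_factor notch quality factor (centre frequency / -3 dB width);
#'   required when `kind = "notch"`.
#' @param zero_phase apply forward-backward (`filtfilt`), doubling the
#'   effective magnitude order and cancelling group delay.
#' @return an object of class `filter_spec` with the designed `b`, `a`
#'   coefficient vectors attached.
#' @export
filter_spec <- function(kind = c("butter_bandpass", "butter_lowpass",
                                 "butter_highpass", "notch"),
                        order = 4L, cutoff_hz, fs,
                        q_factor = NULL, zero_phase = TRUE) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(cutoff_hz), is.numeric(fs), fs > 0)
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= fs / 2)) {
    stop("cutoff frequencies must lie strictly inside (0, fs/2)")
  }
  if (kind == "butter_bandpass" && length(cutoff_hz) != 2L) {
    stop("band-pass needs two cutoff frequencies")
  }
  if (kind %in% c("butter_lowpass", "butter_highpass", "notch") &&
      length(cutoff_hz) != 1L) {
    stop(kind, " needs exactly one cutoff frequency")
  }
  if (kind == "notch") {
    if (is.null(q_factor) || q_factor <= 0) stop("notch requires q_factor > 0")
    ba <- design_notch(cutoff_hz, q_factor, fs)
  } else {
    if (order < 1L) stop("order must be >= 1")
    type <- sub("butter_", "", kind)
    ba <- design_butter(order, cutoff_hz, fs, type)
  }
  structure(list(kind = kind, order = if (kind == "notch") 2L else as.integer(order),
                 cutoff_hz = cutoff_hz, fs = fs, q_factor = q_factor,
                 zero_phase = isTRUE(zero_phase), b = ba$b, a = ba$a),
            class = "filter_spec")
}

# polynomial with given roots, coefficients in decreasing degree
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0i) - c(0i, p * rt)
  p
}

# Butterworth design by bilinear transform of the analog prototype.
# type: "lowpass", "highpass", "bandpass". Returns list(b, a), a[1] == 1.
design_butter <- function(order, cutoff_hz, fs, type) {
  n <- as.integer(order)
  # analog prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  z <- complex(0)
  gain <- 1

  warp <- function(f) 2 * fs * tan(pi * f / fs)  # pre-warped analog freq
  if (type == "lowpass") {
    wc <- warp(cutoff_hz)
    p <- p * wc
    gain <- wc^n
  } else if (type == "highpass") {
    wc <- warp(cutoff_hz)
    # s -> wc / s
    gain <- Re(prod(-p))    # prototype: prod(-p) = 1 for Butterworth
    p <- wc / p
    z <- rep(0 + 0i, n)
    gain <- 1 / gain
  } else if (type == "bandpass") {
    w1 <- warp(min(cutoff_hz)); w2 <- warp(max(cutoff_hz))
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    # s -> (s^2 + w0^2) / (bw * s): order doubles
    pbp <- c()
    for (pk in p) {
      s <- pk * bw / 2
      d <- sqrt(s^2 - w0^2)
      pbp <- c(pbp, s + d, s - d)
    }
    z <- rep(0 + 0i, n)
    gain <- bw^n
    p <- pbp
  }

  # bilinear transform: s = 2*fs*(z-1)/(z+1)
  fs2 <- 2 * fs
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  # zeros at infinity map to z = -1
  n_inf <- length(p) - length(z)
  zd <- c(zd, rep(-1 + 0i, n_inf))
  kd <- gain * Re(prod(fs2 - z)) / Re(prod(fs2 - p))

  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b / a[1], a = a / a[1])
}

# Second-order IIR notch (unit gain at DC and Nyquist, zero at f0).
design_notch <- function(f0, q, fs) {
  w0 <- 2 * pi * f0 / fs
  beta <- tan(w0 / (2 * q))
  g <- 1 / (1 + beta)
  b <- g * c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * g * cos(w0), 2 * g - 1)
  list(b = b, a = a)
}

#' Single-pass IIR/FIR filtering (zero initial conditions)
#'
#' Direct-form difference equation
#' `a[1] y[n] = sum(b * x[n - 0:(nb-1)]) - sum(a[-1] * y[n - 1:(na-1)])`.
#'
#' @param b,a coefficient vectors (`a[1]` must be non-zero).
#' @param x numeric series.
#' @param init_steady start from the step-response steady state for `x[1]`
#'   instead of zero initial conditions (suppresses the startup transient;
#'   used by [filtfilt()]).
#' @return filtered series, same length as `x`.
#' @export
lfilter <- function(b, a, x, init_steady = FALSE) {
  stopifnot(length(a) >= 1, a[1] != 0)
  b <- b / a[1]; a <- a / a[1]
  n <- length(x)
  nb <- length(b)
  x0 <- if (init_steady) x[1] else 0
  # MA part with leading padding so output keeps length n
  xp <- c(rep(x0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:(nb + n - 1)]
  if (length(a) > 1) {
    y0 <- if (init_steady) sum(b) / sum(a) * x0 else 0
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive",
                                  init = rep(y0, length(a) - 1)))
  }
  v
}

#' Zero-phase forward-backward filtering
#'
#' Applies `lfilter` forward and backward with odd-reflection padding of
#' length `3 * (max(length(a), length(b)) - 1)` at both ends (the
#' conventional transient-suppression scheme), cancelling phase distortion
#' and squaring the magnitude response.
#'
#' @inheritParams lfilter
#' @export
filtfilt <- function(b, a, x) {
  n <- length(x)
  ntaps <- max(length(a), length(b))
  pad <- min(3L * (ntaps - 1L), n - 1L)
  if (pad > 0) {
    pre <- 2 * x[1] - x[seq(pad + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xe <- c(pre, x, post)
  } else {
    xe <- x
  }
  y <- lfilter(b, a, xe, init_steady = TRUE)
  y <- rev(lfilter(b, a, rev(y), init_steady = TRUE))
  y[(pad + 1):(pad + n)]
}

#' Apply a filter specification to a uniformly sampled series
#'
#' @param x numeric series (finite values).
#' @param spec a [filter_spec()].
#' @return filtered series, same length as `x`.
#' @export
apply_filter <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("input series must be finite numeric")
  }
  min_len <- 3L * max(length(spec$a), length(spec$b))
  if (spec$zero_phase && length(x) <= min_len) {
    stop("series too short for zero-phase filtering (need > ", min_len,
         " samples)")
  }
  if (spec$zero_phase) filtfilt(spec$b, spec$a, x) else lfilter(spec$b, spec$a, x)
}

#' Magnitude response of a filter specification
#'
#' Evaluates `|H(e^{i 2 pi f / fs})|` (squared when `zero_phase`), used in
#' tests against analytic Butterworth/notch responses.
#'
#' @param spec a [filter_spec()].
#' @param f_hz frequencies at which to evaluate, Hz.
#' @export
filter_gain <- function(spec, f_hz) {
  w <- 2 * pi * f_hz / spec$fs
  z1 <- exp(-1i * w)
  hb <- vapply(z1, function(zz) sum(spec$b * zz^(seq_along(spec$b) - 1)),
               complex(1))
  ha <- vapply(z1, function(zz) sum(spec$a * zz^(seq_along(spec$a) - 1)),
               complex(1))
  g <- Mod(hb / ha)
  if (spec$zero_phase) g^2 else g
}
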