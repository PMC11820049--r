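#' Preprocessing: filtering, envelopes, joint angles, resampling
#'
#' The offline preprocessing chain that turns a raw synchronized session
#' into per-trial analysis series on a common 20 Hz time base:
#' per EMG channel, a fourth-order Butterworth band-pass (20-450 Hz), a
#' 50 Hz notch (Q = 35), full-wave rectification and a 10 Hz low-pass
#' envelope; per marker coordinate, a fourth-order zero-phase Butterworth
#' low-pass at 15 Hz, then the cosine-formula vertex angle per frame; both
#' streams are finally resampled to 20 Hz. EMG filters are applied
#' zero-phase by default (offline tool; a causal mode is available via
#' `zero_phase = FALSE` in the specs).
#'
#' @name preprocess
NULL

#' Extract the linear envelope of one EMG channel
#'
#' Full-wave rectification followed by a low-pass filter (10 Hz default),
#' clipped at zero. The input is expected to be band-passed and
#' notch-filtered already.
#'
#' @param emg numeric series (mV).
#' @param fs sampling rate, Hz.
#' @param lp_hz envelope low-pass cutoff, Hz.
#' @param order Butterworth order of the low-pass.
#' @param zero_phase forward-backward application (default TRUE).
#' @return non-negative envelope series, same length as input.
#' @export
extract_envelope <- function(emg, fs, lp_hz = 10, order = 4L,
                             zero_phase = TRUE) {
  spec <- filter_spec("butter_lowpass", order, lp_hz, fs,
                      zero_phase = zero_phase)
  pmax(apply_filter(abs(emg), spec), 0)
}

#' Vertex angle of a marker triple (cosine formula)
#'
#' Angle at vertex `b` between limb vectors `a - b` and `c - b`:
#' `acos((a-b).(c-b) / (|a-b| |c-b|))`, in degrees, range `[0, 180]`; the
#' cosine is clamped to `[-1, 1]` before `acos`. Accepts single 3-D points
#' or `n x 3` matrices of synchronized trajectories.
#'
#' @param a,b,c 3-D points (length-3 vectors) or `n x 3` matrices.
#' @return angle(s) in degrees.
#' @export
joint_angle <- function(a, b, c) {
  to_mat <- function(p) if (is.matrix(p)) p else matrix(p, 1, 3)
  a <- to_mat(a); b <- to_mat(b); c <- to_mat(c)
  u <- a - b; v <- c - b
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  if (any(nu == 0) || any(nv == 0)) {
    stop("degenerate geometry: vertex coincides with a limb marker")
  }
  cosang <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
  ang <- acos(cosang) * 180 / pi
  if (length(ang) == 1) ang[[1]] else ang
}

#' Anti-aliased rate conversion
#'
#' Downsampling applies a zero-phase fourth-order Butterworth anti-alias
#' low-pass at `0.45 * fs_out` before cubic-spline evaluation on the new
#' time grid; upsampling (with a warning) interpolates directly. Output
#' length is `round(length(x) * fs_out / fs_in)`. Constant series are
#' preserved.
#'
#' @param x numeric series at `fs_in`.
#' @param fs_in,fs_out sampling rates, Hz.
#' @return series at `fs_out`.
#' @export
resample <- function(x, fs_in, fs_out) {
  stopifnot(fs_in > 0, fs_out > 0)
  if (length(x) == 0) stop("cannot resample an empty series")
  n_out <- round(length(x) * fs_out / fs_in)
  if (fs_out > fs_in) {
    warning("upsampling from ", fs_in, " Hz to ", fs_out, " Hz")
  } else if (fs_out < fs_in) {
    aa <- filter_spec("butter_lowpass", 4, 0.45 * fs_out, fs_in,
                      zero_phase = TRUE)
    x <- apply_filter(x, aa)
  }
  t_in <- (seq_along(x) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  stats::spline(t_in, x, xout = t_out, method = "natural")$y
}

#' Run the full preprocessing chain on a raw session
#'
#' EMG path per channel: band-pass (`bp_hz`) -> notch (`notch_hz`, Q
#' `notch_q`) -> rectify + `env_hz` low-pass -> resample to `fs_out`.
#' Kinematic path: 15 Hz zero-phase low-pass on every marker coordinate ->
#' cosine-formula angle per frame -> resample to `fs_out`. Streams are
#' truncated to their common length; a mismatch of more than one sample at
#' `fs_out` is an alignment error.
#'
#' @param raw a `raw_session` (from [simulate_session()] or
#'   [read_session()]).
#' @param fs_out common analysis rate, Hz (default 20).
#' @param bp_hz band-pass edges, Hz.
#' @param notch_hz,notch_q notch centre frequency and quality factor.
#' @param env_hz envelope low-pass cutoff, Hz.
#' @param kin_hz kinematic low-pass cutoff, Hz.
#' @param zero_phase_emg apply the EMG filters forward-backward (default
#'   TRUE; set FALSE for a causal chain).
#' @return object of class `processed_trial`: `time`, `envelopes`
#'   (`n x n_channels`, mV, non-negative), `angles` (`n x n_joints`,
#'   degrees), `pattern`, `fs` and a `provenance` list describing the
#'   filter chain.
#' @export
preprocess_session <- function(raw, fs_out = 20, bp_hz = c(20, 450),
                               notch_hz = 50, notch_q = 35, env_hz = 10,
                               kin_hz = 15, zero_phase_emg = TRUE) {
  stopifnot(inherits(raw, "raw_session"))
  bp <- filter_spec("butter_bandpass", 4, bp_hz, raw$fs_emg,
                    zero_phase = zero_phase_emg)
  nt <- filter_spec("notch", cutoff_hz = notch_hz, fs = raw$fs_emg,
                    q_factor = notch_q, zero_phase = zero_phase_emg)
  env <- apply(raw$emg, 2, function(ch) {
    filtered <- apply_filter(apply_filter(ch, bp), nt)
    e <- extract_envelope(filtered, raw$fs_emg, lp_hz = env_hz,
                          zero_phase = zero_phase_emg)
    pmax(resample(e, raw$fs_emg, fs_out), 0)
  })

  kin <- filter_spec("butter_lowpass", 4, kin_hz, raw$fs_mocap,
                     zero_phase = TRUE)
  mk <- raw$markers
  joints <- intersect(c("hip", "knee", "ankle"),
                      unique(sub("_[abc]_[xyz]$", "", setdiff(names(mk), "time"))))
  angles <- sapply(joints, function(j) {
    cols <- function(m) as.matrix(mk[, paste0(j, "_", m, "_", c("x", "y", "z"))])
    sm <- lapply(list(a = cols("a"), b = cols("b"), c = cols("c")),
                 function(p) apply(p, 2, function(x) apply_filter(x, kin)))
    th <- joint_angle(sm$a, sm$b, sm$c)
    resample(th, raw$fs_mocap, fs_out)
  })

  n_env <- nrow(env); n_ang <- nrow(angles)
  if (abs(n_env - n_ang) > 1) {
    stop("stream durations misaligned: ", n_env, " envelope vs ", n_ang,
         " angle samples at ", fs_out, " Hz")
  }
  n <- min(n_env, n_ang)
  structure(list(
    time = (seq_len(n) - 1) / fs_out,
    envelopes = env[seq_len(n), , drop = FALSE],
    angles = angles[seq_len(n), , drop = FALSE],
    pattern = raw$pattern, fs = fs_out,
    provenance = list(bp_hz = bp_hz, notch_hz = notch_hz, notch_q = notch_q,
                      env_hz = env_hz, kin_hz = kin_hz,
                      zero_phase_emg = zero_phase_emg)),
    class = "processed_trial")
}

#' Write / read a processed trial as one delimited table
#'
#' @param trial a `processed_trial`.
#' @param path CSV path; a `<path>.json` sidecar stores pattern, rate and
#'   provenance.
#' @return `path`, invisibly.
#' @export
write_processed <- function(trial, path) {
  stopifnot(inherits(trial, "processed_trial"))
  df <- data.frame(time = trial$time, trial$envelopes,
                   check.names = FALSE)
  for (j in colnames(trial$angles)) df[[paste0("angle_", j)]] <- trial$angles[, j]
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(pattern = trial$pattern, fs = trial$fs,
         channels = colnames(trial$envelopes),
         joints = colnames(trial$angles), provenance = trial$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_processed
#' @export
read_processed <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  ang_cols <- paste0("angle_", meta$joints)
  structure(list(
    time = df$time,
    envelopes = as.matrix(df[, meta$channels, drop = FALSE]),
    angles = {
      m <- as.matrix(df[, ang_cols, drop = FALSE])
      colnames(m) <- meta$joints
      m
    },
    pattern = meta$pattern, fs = meta$fs, provenance = meta$provenance),
    class = "processed_trial")
}
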