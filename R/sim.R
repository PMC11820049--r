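#' Synthetic sEMG + motion-capture session simulator
#'
#' Generates synchronized multi-rate recordings -- seven channels of raw
#' surface EMG at `fs_emg` plus planar marker trajectories at `fs_mocap` --
#' with fully known ground truth, emulating four lower-limb movement
#' patterns (gait, obstacle crossing, squatting, seated knee
#' flexion-extension). The forward model is deliberately simple and
#' transparent: joint angles drive muscle activations through a fixed
#' rectified-linear-plus-saturation map of weighted angles, angular
#' velocities and co-contraction (speed-magnitude) terms, advanced by an
#' electromechanical delay, and activations amplitude-modulate band-limited
#' (20-450 Hz) Gaussian carriers, with 50 Hz line interference and
#' broadband baseline noise added at a configurable SNR. It is a stand-in
#' for data collection, not a musculoskeletal model.
#'
#' @name sim
NULL

SIM_MUSCLES <- c("RF", "TA", "SOL", "GAS", "VM", "VL", "BF")

# muscle x (hip, knee, ankle, dhip, dknee, dankle, |dhip|, |dknee|,
# |dankle|) drive weights. The last three columns are co-contraction
# terms: stabilizing activation that grows with the speed of joint motion
# regardless of its direction (eccentric and concentric work both cost
# effort). Physiologically flavoured but arbitrary; stored with outputs so
# tests can invert the activation map where a muscle is active.
sim_muscle_weights <- function() {
  w <- rbind(
    RF  = c(-0.8,  0.9,  0.0, 0.0,  0.3,  0.0, 0.0, 0.5, 0.0),
    TA  = c( 0.0,  0.0, -1.0, 0.0,  0.0, -0.4, 0.0, 0.0, 0.6),
    SOL = c( 0.0,  0.0,  1.0, 0.0,  0.0,  0.4, 0.0, 0.0, 0.6),
    GAS = c( 0.0,  0.4,  0.8, 0.0,  0.0,  0.3, 0.0, 0.3, 0.5),
    VM  = c( 0.0,  1.0,  0.0, 0.0,  0.4,  0.0, 0.0, 0.6, 0.0),
    VL  = c( 0.0,  1.0,  0.0, 0.0, -0.4,  0.0, 0.0, 0.6, 0.0),
    BF  = c( 0.5, -0.9,  0.0, 0.0, -0.3,  0.0, 0.3, 0.5, 0.0)
  )
  colnames(w) <- c("hip", "knee", "ankle", "dhip", "dknee", "dankle",
                   "cc_hip", "cc_knee", "cc_ankle")
  w
}

#' Simulation configuration
#'
#' @param pattern movement pattern: `"gait"`, `"obstacle"`, `"squat"` or
#'   `"knee_flexion"`.
#' @param duration_s trial duration in seconds. Defaults mirror the
#'   experimental protocol being emulated: 5.5 s gait, 5 s obstacle
#'   crossing, 25 s squatting (10 repetitions), 20 s knee
#'   flexion-extension (10 repetitions).
#' @param fs_emg sEMG sampling rate, Hz (default 2000; must exceed 900 so
#'   the 20-450 Hz EMG band is representable).
#' @param fs_mocap motion-capture sampling rate, Hz (default 100).
#' @param n_emg_channels number of EMG channels (default 7, one per muscle).
#' @param joints joints to simulate, subset of hip/knee/ankle.
#' @param emd_s electromechanical delay in seconds: muscle activation leads
#'   the mechanical angle change by this much (default 0.05).
#' @param line_hz power-line interference frequency, Hz.
#' @param line_amp_rel line amplitude relative to the RMS of the modulated
#'   EMG component (default 1).
#' @param snr_db ratio (dB) of modulated-signal power to broadband baseline
#'   noise power (default 20).
#' @param amp_mv full-scale EMG carrier amplitude in mV.
#' @param seed integer seed fixing all randomness.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(pattern = c("gait", "obstacle", "squat", "knee_flexion"),
                       duration_s = NULL, fs_emg = 2000, fs_mocap = 100,
                       n_emg_channels = 7L,
                       joints = c("hip", "knee", "ankle"),
                       emd_s = 0.05, line_hz = 50, line_amp_rel = 1,
                       snr_db = 20, amp_mv = 1, seed = 1L) {
  pattern <- match.arg(pattern)
  if (is.null(duration_s)) {
    duration_s <- switch(pattern, gait = 5.5, obstacle = 5,
                         squat = 25, knee_flexion = 20)
  }
  stopifnot(duration_s > 0, fs_emg > 2 * 450, fs_mocap > 0, emd_s >= 0,
            n_emg_channels >= 1)
  joints <- match.arg(joints, c("hip", "knee", "ankle"), several.ok = TRUE)
  structure(list(pattern = pattern, duration_s = duration_s,
                 fs_emg = fs_emg, fs_mocap = fs_mocap,
                 n_emg_channels = as.integer(n_emg_channels),
                 joints = joints, emd_s = emd_s, line_hz = line_hz,
                 line_amp_rel = line_amp_rel, snr_db = snr_db,
                 amp_mv = amp_mv, seed = as.integer(seed)),
            class = "sim_config")
}

# pattern definitions: cycle period (s) and per-joint waveform of the cycle
# phase. Angles are included vertex angles in degrees, kept inside (0, 180)
# so the marker construction is always valid. All harmonics stay below 5 Hz.
pattern_waveforms <- function(pattern, duration_s) {
  period <- switch(pattern,
    gait = 1.1, obstacle = 1.4,
    squat = duration_s / 10, knee_flexion = duration_s / 10)
  wf <- switch(pattern,
    gait = list(
      hip   = function(p) 120 + 12 * sin(p) + 3 * sin(2 * p + 0.6),
      knee  = function(p) 145 + 18 * sin(p + 1.2) + 8 * sin(2 * p + 2.0),
      ankle = function(p)  90 + 10 * sin(p + 2.1) + 4 * sin(2 * p + 0.3)),
    obstacle = list(
      hip   = function(p) 115 + 15 * sin(p + 0.8),
      knee  = function(p) 135 - 28 * cos(p) + 6 * sin(2 * p),
      ankle = function(p)  90 + 12 * sin(p + 1.5)),
    squat = list(
      hip   = function(p) 125 - 20 * cos(p),
      knee  = function(p) 135 - 34 * cos(p),
      ankle = function(p)  90 -  8 * cos(p)),
    knee_flexion = list(
      hip   = NULL,  # near-constant, handled below
      knee  = function(p) 130 - 33 * cos(p),
      ankle = function(p)  90 - 10 * cos(p)))
  list(period = period, wf = wf)
}

#' Simulate joint-angle trajectories
#'
#' Smooth band-limited (< 5 Hz) periodic trajectories with pattern-specific
#' period and amplitudes; per-trial amplitude (3 %) and global phase jitter
#' are drawn from the configured seed. The knee-flexion pattern keeps the
#' hip essentially constant. Angle ranges are simulator configuration, not
#' measured values.
#'
#' @param cfg a [sim_config()].
#' @return matrix `n x length(joints)` of included vertex angles in degrees
#'   at `fs_mocap`, with a `time` attribute and the cycle period as
#'   attribute `period_s`.
#' @export
simulate_angles <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, simulate_angles_impl(cfg))
}

simulate_angles_impl <- function(cfg) {
  pw <- pattern_waveforms(cfg$pattern, cfg$duration_s)
  n <- round(cfg$duration_s * cfg$fs_mocap)
  t <- (seq_len(n) - 1) / cfg$fs_mocap
  phase0 <- stats::rnorm(1, 0, 0.05)
  # natural-pace variability: cycles differ smoothly in amplitude and
  # drift slightly in phase, as self-paced human movement does. Fast
  # many-cycle patterns (gait, obstacle) get strong modulation; the slow
  # counted-repetition patterns (squat, flexion) get gentle modulation at
  # a small fraction of the cycle rate, so every repetition keeps exactly
  # one peak.
  fast <- cfg$pattern %in% c("gait", "obstacle")
  depth <- if (fast) 0.30 else 0.10
  var_hz <- if (fast) 0.4 else 0.25 / pw$period
  amp_mod <- 1 + depth * smooth_noise(n, cfg$fs_mocap, var_hz)
  phase_drift <- 0.20 * smooth_noise(n, cfg$fs_mocap, var_hz)
  p <- 2 * pi * t / pw$period + phase0 + phase_drift
  out <- matrix(NA_real_, n, length(cfg$joints),
                dimnames = list(NULL, cfg$joints))
  for (j in cfg$joints) {
    amp_jit <- 1 + stats::rnorm(1, 0, 0.03)
    f <- pw$wf[[j]]
    if (is.null(f)) {             # near-constant hip in seated flexion
      out[, j] <- 120 + 0.5 * sin(2 * pi * t / cfg$duration_s)
    } else {
      base <- f(p)
      mid <- mean(range(f(seq(0, 2 * pi, length.out = 512))))
      out[, j] <- mid + (base - mid) * amp_jit * amp_mod
    }
  }
  # smooth range guard: keeps all angles strictly inside (5, 175) degrees
  # without clipping artefacts, whatever the jitter draws
  out <- 90 + 85 * tanh((out - 90) / 85)
  if (any(out <= 0 | out >= 180)) stop("simulated angle left (0, 180) degrees")
  attr(out, "time") <- t
  attr(out, "period_s") <- pw$period
  out
}

# unit-sd band-limited (< cutoff_hz) Gaussian process; falls back to a
# constant zero series when the trial is too short to filter
smooth_noise <- function(n, fs, cutoff_hz = 0.4) {
  spec <- filter_spec("butter_lowpass", 2, cutoff_hz, fs, zero_phase = TRUE)
  min_len <- 3L * max(length(spec$a), length(spec$b))
  if (n <= min_len) return(numeric(n))
  x <- apply_filter(stats::rnorm(n), spec)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  (x - mean(x)) / s
}

#' Map joint angles to muscle activations
#'
#' Each muscle's activation is a rectified-linear-plus-saturation function
#' `tanh(gain * max(u, 0))` of a fixed muscle-specific weighted sum `u` of
#' normalized joint angles and angular velocities, evaluated `emd_s`
#' seconds ahead of the kinematics (EMG leads motion). Rectification makes
#' antagonist muscles fire in alternate phases of the movement cycle, as
#' real flexor/extensor pairs do; saturation bounds activation in [0, 1).
#' The mapping parameters are attached to the result so tests can invert
#' the map wherever the muscle is active: `u = atanh(a) / gain`.
#'
#' @param angles matrix from [simulate_angles()] (degrees at `fs_mocap`).
#' @param cfg the [sim_config()].
#' @return matrix `n_emg x n_emg_channels` of activations in (0, 1) at
#'   `fs_emg`, with attributes `weights`, `gain`, `drive` (the un-delayed
#'   drive signal at `fs_emg`, for oracle tests) and `time`.
#' @export
angles_to_activations <- function(angles, cfg) {
  stopifnot(inherits(cfg, "sim_config"), is.matrix(angles))
  w_full <- sim_muscle_weights()
  muscles <- SIM_MUSCLES[seq_len(cfg$n_emg_channels)]
  t_mo <- attr(angles, "time") %||%
    ((seq_len(nrow(angles)) - 1) / cfg$fs_mocap)
  n_emg <- round(cfg$duration_s * cfg$fs_emg)
  t_emg <- (seq_len(n_emg) - 1) / cfg$fs_emg
  dur <- max(t_mo)
  gain <- 5

  # spline interpolants of normalized angle and velocity per joint;
  # joints are centred at their neutral included angle so drives are
  # roughly zero-mean (keeps activations well inside (0,1) with real
  # dynamic range)
  centre <- c(hip = 120, knee = 140, ankle = 90)
  feat <- function(tt) {
    z <- matrix(0, length(tt), 9,
                dimnames = list(NULL, colnames(w_full)))
    for (j in colnames(angles)) {
      sf <- stats::splinefun(t_mo, (angles[, j] - centre[[j]]) / 30)
      z[, j] <- sf(tt)
      v <- sf(tt, deriv = 1) / 5
      z[, paste0("d", j)] <- v
      z[, paste0("cc_", j)] <- abs(v)
    }
    z
  }
  z_adv <- feat(pmin(t_emg + cfg$emd_s, dur))   # advanced: EMG leads
  z_now <- feat(t_emg)
  w <- w_full[muscles, , drop = FALSE]
  act <- tanh(gain * pmax(z_adv %*% t(w), 0))
  colnames(act) <- muscles
  attr(act, "weights") <- w
  attr(act, "gain") <- gain
  attr(act, "drive") <- z_now %*% t(w)
  attr(act, "time") <- t_emg
  act
}

#' Synthesize raw sEMG from activations
#'
#' Channel `c` is `amp_mv * act_c(t) * n_c(t)` where `n_c` is unit-RMS
#' Gaussian noise band-limited to 20-450 Hz, plus a `line_hz` sinusoid with
#' amplitude `line_amp_rel` times the modulated-component RMS, plus white
#' baseline noise whose power sits `snr_db` dB below the modulated
#' component. Deterministic given the config seed.
#'
#' @param activations matrix at `fs_emg`, values in `[0, 1]`.
#' @param cfg the [sim_config()].
#' @return matrix of raw sEMG in mV, same shape as `activations`.
#' @export
activations_to_semg <- function(activations, cfg) {
  stopifnot(inherits(cfg, "sim_config"),
            all(activations >= 0), all(activations <= 1))
  with_seed(cfg$seed + 1000L, activations_to_semg_impl(activations, cfg))
}

activations_to_semg_impl <- function(activations, cfg) {
  n <- nrow(activations); nc <- ncol(activations)
  t <- (seq_len(n) - 1) / cfg$fs_emg
  bp <- filter_spec("butter_bandpass", 4, c(20, 450), cfg$fs_emg,
                    zero_phase = FALSE)
  out <- matrix(0, n, nc, dimnames = dimnames(activations))
  for (ch in seq_len(nc)) {
    carrier <- lfilter(bp$b, bp$a, stats::rnorm(n))
    carrier <- carrier / rms(carrier)
    sig <- cfg$amp_mv * activations[, ch] * carrier
    s_rms <- rms(sig)
    line <- cfg$line_amp_rel * s_rms *
      sin(2 * pi * cfg$line_hz * t + stats::runif(1, 0, 2 * pi))
    noise_sd <- s_rms * 10^(-cfg$snr_db / 20)
    noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    out[, ch] <- sig + line + noise
  }
  out
}

#' Place marker triples reproducing given joint angles
#'
#' For each joint the vertex marker sits at a fixed origin and the two limb
#' markers lie in a joint-specific plane at fixed segment lengths, at
#' directions `+theta/2` and `-theta/2` about the x axis -- so the included
#' vertex angle equals the input angle exactly by construction. This is the
#' three-marker minimum the cosine formula needs, not a full-body marker
#' set.
#'
#' @param angles matrix of included angles in degrees, strictly inside
#'   (0, 180).
#' @param cfg the [sim_config()].
#' @return data.frame: `time` plus `<joint>_{a,b,c}_{x,y,z}` columns (mm).
#' @export
angles_to_markers <- function(angles, cfg) {
  stopifnot(is.matrix(angles))
  if (any(angles <= 0 | angles >= 180)) {
    stop("angles must lie strictly inside (0, 180) degrees ",
         "(collinear or reflex vertex is degenerate)")
  }
  t <- attr(angles, "time") %||% ((seq_len(nrow(angles)) - 1) / cfg$fs_mocap)
  seg <- c(hip = 400, knee = 400, ankle = 150)   # mm
  out <- data.frame(time = t)
  for (j in colnames(angles)) {
    jidx <- match(j, c("hip", "knee", "ankle"))
    org <- c(0, -450 * (jidx - 1), 20 * jidx)
    half <- angles[, j] * pi / 360               # theta/2 in radians
    L <- seg[[j]]
    out[[paste0(j, "_a_x")]] <- org[1] + L * cos(half)
    out[[paste0(j, "_a_y")]] <- org[2] + L * sin(half)
    out[[paste0(j, "_a_z")]] <- org[3]
    out[[paste0(j, "_b_x")]] <- org[1]
    out[[paste0(j, "_b_y")]] <- org[2]
    out[[paste0(j, "_b_z")]] <- org[3]
    out[[paste0(j, "_c_x")]] <- org[1] + L * cos(half)
    out[[paste0(j, "_c_y")]] <- org[2] - L * sin(half)
    out[[paste0(j, "_c_z")]] <- org[3]
  }
  out
}

#' Simulate one synchronized recording session
#'
#' Bundles [simulate_angles()], [angles_to_activations()],
#' [activations_to_semg()] and [angles_to_markers()] into a raw session plus
#' its ground truth. Repeated calls with incremented seeds give independent
#' trials sharing the pattern parameters.
#'
#' @param cfg a [sim_config()].
#' @return list of class `raw_session` with elements `emg` (mV matrix at
#'   `fs_emg`), `markers` (data.frame at `fs_mocap`), `pattern`, `fs_emg`,
#'   `fs_mocap`, `seed` and `ground_truth` (class `ground_truth`:
#'   `activations`, `angles`, the activation-map parameters).
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  angles <- simulate_angles(cfg)
  act <- angles_to_activations(angles, cfg)
  emg <- activations_to_semg(act, cfg)
  markers <- angles_to_markers(angles, cfg)
  gt <- structure(list(activations = act, angles = angles,
                       weights = attr(act, "weights"),
                       gain = attr(act, "gain")),
                  class = "ground_truth")
  structure(list(emg = emg, t_emg = attr(act, "time"),
                 markers = markers, pattern = cfg$pattern,
                 fs_emg = cfg$fs_emg, fs_mocap = cfg$fs_mocap,
                 joints = cfg$joints, seed = cfg$seed, config = cfg,
                 ground_truth = gt),
            class = "raw_session")
}

#' Simulate a block of trials
#'
#' @param cfg base [sim_config()]; trial `i` uses `seed + i - 1`.
#' @param n_trials number of trials (default 5).
#' @return list of `raw_session` objects.
#' @export
simulate_trials <- function(cfg, n_trials = 5L) {
  lapply(seq_len(n_trials), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i - 1L
    simulate_session(cfg_i)
  })
}

#' Write / read a raw session as delimited text
#'
#' `emg.csv` holds time plus one column per channel, `markers.csv` the
#' marker coordinates, `manifest.json` the pattern, rates and seed;
#' ground-truth angles (and optionally the large activation matrix) are
#' saved alongside for test use only.
#'
#' @param session a `raw_session`.
#' @param dir output directory (created if needed).
#' @param write_activations also dump the `fs_emg`-rate activation matrix.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, write_activations = FALSE) {
  stopifnot(inherits(session, "raw_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  emg <- data.frame(time = session$t_emg, session$emg)
  utils::write.csv(emg, file.path(dir, "emg.csv"), row.names = FALSE)
  utils::write.csv(session$markers, file.path(dir, "markers.csv"),
                   row.names = FALSE)
  gt <- session$ground_truth
  ang <- data.frame(time = attr(gt$angles, "time"), unclass(gt$angles))
  utils::write.csv(ang, file.path(dir, "gt_angles.csv"), row.names = FALSE)
  if (write_activations) {
    utils::write.csv(data.frame(time = session$t_emg, gt$activations),
                     file.path(dir, "gt_activations.csv"), row.names = FALSE)
  }
  manifest <- list(pattern = session$pattern, fs_emg = session$fs_emg,
                   fs_mocap = session$fs_mocap, joints = session$joints,
                   seed = session$seed,
                   n_emg_channels = ncol(session$emg))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  emg <- utils::read.csv(file.path(dir, "emg.csv"))
  markers <- utils::read.csv(file.path(dir, "markers.csv"))
  gt <- NULL
  gtp <- file.path(dir, "gt_angles.csv")
  if (file.exists(gtp)) {
    ga <- utils::read.csv(gtp)
    angles <- as.matrix(ga[, -1, drop = FALSE])
    attr(angles, "time") <- ga$time
    gt <- structure(list(angles = angles), class = "ground_truth")
  }
  structure(list(emg = as.matrix(emg[, -1, drop = FALSE]),
                 t_emg = emg$time, markers = markers,
                 pattern = man$pattern, fs_emg = man$fs_emg,
                 fs_mocap = man$fs_mocap, joints = man$joints,
                 seed = man$seed, ground_truth = gt),
            class = "raw_session")
}
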