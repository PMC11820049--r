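# synthetic session simulator

test_that("simulated angle series have the right shape and determinism", {
  cfg <- sim_config("gait", duration_s = 5.5, seed = 4L)
  a1 <- simulate_angles(cfg)
  expect_equal(dim(a1), c(550L, 3L))
  expect_identical(a1, simulate_angles(cfg))      # bit-identical
  a2 <- simulate_angles(sim_config("gait", duration_s = 5.5, seed = 5L))
  expect_false(identical(a1, a2))
  expect_true(all(a1 > 0 & a1 < 180))
  expect_error(sim_config("backflip"), "arg")
})

test_that("10 squat repetitions give exactly 10 knee peaks above mid-range", {
  # brute-force peak scan oracle
  count_peaks <- function(x) {
    mid <- mean(range(x))
    sum(vapply(2:(length(x) - 1), function(i) {
      x[i] > x[i - 1] && x[i] > x[i + 1] && x[i] > mid
    }, logical(1)))
  }
  for (seed in c(1L, 9L, 23L)) {
    a <- simulate_angles(sim_config("squat", duration_s = 25, seed = seed))
    expect_equal(count_peaks(a[, "knee"]), 10L)
  }
})

test_that("knee-flexion pattern keeps the hip near-constant", {
  a <- simulate_angles(sim_config("knee_flexion", seed = 2L))
  expect_lt(diff(range(a[, "hip"])), 2)
  expect_gt(diff(range(a[, "knee"])), 30)
})

test_that("activations are bounded and lead the kinematics by emd_s", {
  cfg <- sim_config("gait", seed = 3L, emd_s = 0.05)
  ang <- simulate_angles(cfg)
  act <- angles_to_activations(ang, cfg)
  expect_equal(dim(act), c(11000L, 7L))
  expect_true(all(act >= 0 & act <= 1))
  # brute-force cross-correlation: activation vs the same map of the
  # un-delayed drive; argmax lag must equal emd_s within one EMG sample
  drive <- attr(act, "drive"); gain <- attr(act, "gain")
  for (ch in c(1L, 5L)) {
    a_now <- tanh(gain * pmax(drive[, ch], 0))
    lags <- -200:200
    cc <- vapply(lags, function(L) {
      i <- (max(1, 1 - L)):(min(11000, 11000 - L))
      cor(act[i, ch], a_now[i + L])
    }, numeric(1))
    best <- lags[which.max(cc)]
    expect_lte(abs(best - 0.05 * cfg$fs_emg), 1)
  }
  # constant angles give constant activations
  angc <- matrix(c(120, 140, 90), nrow = 200, ncol = 3, byrow = TRUE,
                 dimnames = list(NULL, c("hip", "knee", "ankle")))
  attr(angc, "time") <- (0:199) / 100
  cfg2 <- sim_config("gait", duration_s = 2, seed = 1L)
  actc <- angles_to_activations(angc, cfg2)
  expect_lt(max(apply(actc, 2, function(x) diff(range(x)))), 1e-8)
})

test_that("raw sEMG synthesis has the advertised structure", {
  cfg <- sim_config("gait", duration_s = 2, seed = 6L)
  ang <- simulate_angles(cfg)
  act <- angles_to_activations(ang, cfg)

  # zero activation, no baseline, no line -> exactly zero signal
  cfg0 <- cfg; cfg0$line_amp_rel <- 0; cfg0$snr_db <- Inf
  z <- activations_to_semg(act * 0, cfg0)
  expect_true(all(z == 0))

  # periodogram of the output shows a line at line_hz
  emg <- activations_to_semg(act, cfg)
  sp <- stats::spec.pgram(emg[, 1], plot = FALSE, taper = 0)
  f_hz <- sp$freq * cfg$fs_emg
  band <- f_hz > 40 & f_hz < 60
  expect_lt(abs(f_hz[band][which.max(sp$spec[band])] - 50), 1)

  # doubling activation doubles the RMS of the noise-free modulated part
  s1 <- activations_to_semg(act / 2, cfg0)
  s2 <- activations_to_semg(act, cfg0)
  expect_equal(sqrt(mean(s2^2)) / sqrt(mean(s1^2)), 2, tolerance = 1e-10)

  # seeded determinism
  expect_identical(emg, activations_to_semg(act, cfg))
})

test_that("marker construction reproduces angles exactly and rejects degenerates", {
  cfg <- sim_config("gait", duration_s = 1, seed = 7L)
  ang <- simulate_angles(cfg)
  mk <- angles_to_markers(ang, cfg)
  for (j in c("hip", "knee", "ankle")) {
    cols <- function(m) as.matrix(mk[, paste0(j, "_", m, "_", c("x", "y", "z"))])
    th <- joint_angle(cols("a"), cols("b"), cols("c"))
    expect_lt(max(abs(th - ang[, j])), 1e-9)
  }
  bad <- matrix(180, 10, 1, dimnames = list(NULL, "knee"))
  expect_error(angles_to_markers(bad, cfg), "strictly inside")
  bad0 <- matrix(0, 10, 1, dimnames = list(NULL, "knee"))
  expect_error(angles_to_markers(bad0, cfg), "strictly inside")
})

test_that("simulate_trials yields distinct sessions with shared structure", {
  cfg <- sim_config("gait", duration_s = 1.5, seed = 30L)
  trials <- simulate_trials(cfg, 3)
  expect_length(trials, 3)
  expect_false(identical(trials[[1]]$emg, trials[[2]]$emg))
  expect_true(all(vapply(trials, function(s) s$pattern == "gait", logical(1))))
  # ground-truth marker/angle consistency holds for every trial
  for (s in trials) {
    cols <- function(m) {
      as.matrix(s$markers[, paste0("knee_", m, "_", c("x", "y", "z"))])
    }
    th <- joint_angle(cols("a"), cols("b"), cols("c"))
    expect_lt(max(abs(th - s$ground_truth$angles[, "knee"])), 1e-9)
  }
})

test_that("session round-trips through the delimited on-disk format", {
  dir <- withr::local_tempdir()
  ses <- fixture_session(1L)
  write_session(ses, dir)
  expect_true(all(file.exists(file.path(dir,
    c("emg.csv", "markers.csv", "gt_angles.csv", "manifest.json")))))
  back <- read_session(dir)
  expect_equal(back$pattern, "gait")
  expect_equal(back$fs_emg, 2000)
  expect_equal(unname(back$emg), unname(ses$emg), tolerance = 1e-6)
  expect_equal(back$markers$knee_b_x, ses$markers$knee_b_x, tolerance = 1e-6)
})
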