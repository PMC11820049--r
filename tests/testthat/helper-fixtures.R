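# shared fixtures, built once per test run

.fixture_env <- new.env()

# small processed gait session (5.5 s, default snr) used by several files
fixture_session <- function(seed = 1L) {
  key <- paste0("ses_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config("gait", seed = seed)
    .fixture_env[[key]] <- simulate_session(cfg)
  }
  .fixture_env[[key]]
}

fixture_processed <- function(seed = 1L) {
  key <- paste0("pt_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- preprocess_session(fixture_session(seed))
  }
  .fixture_env[[key]]
}

# tiny window set with a known linear envelope->angle mapping (noise-free,
# smooth envelope-like inputs, degree-scaled targets), for training sanity
# checks
fixture_linear_windows <- function(n_trials = 3, T_len = 120, seed = 5L) {
  key <- paste0("lin_", n_trials, "_", T_len, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    set.seed(seed)
    B <- matrix(rnorm(7 * 2), 7, 2)
    sets <- lapply(seq_len(n_trials), function(i) {
      env <- sapply(1:7, function(ch) {
        x <- abs(as.numeric(stats::filter(rnorm(T_len + 40), rep(1 / 12, 12),
                                          sides = 1)))
        x[!is.na(x)][1:T_len]
      })
      colnames(env) <- paste0("ch", 1:7)
      ang <- env %*% B * 10 + 100
      colnames(ang) <- c("hip", "knee")
      make_windows(list(envelopes = env, angles = ang), window_spec(),
                   trial_id = i)
    })
    .fixture_env[[key]] <- list(ws = concat_trials(sets), B = B)
  }
  .fixture_env[[key]]
}
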