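# training recipe and cross-validation protocol

test_that("the learning-rate schedule is the exact step-decay closed form", {
  spec <- train_spec()
  expect_equal(lr_at(0:9, spec), rep(0.001, 10))
  expect_equal(lr_at(10, spec), 0.0005)
  expect_equal(lr_at(20, spec), 0.00025)
  expect_equal(lr_at(30, spec), 1.25e-4)
  expect_equal(lr_at(49, spec), 0.001 * 0.5^4)
  expect_equal(lr_at(0:49, spec), 0.001 * 0.5^(0:49 %/% 10))
  expect_error(lr_at(-1, spec))
})

test_that("training drives a noiseless linear mapping to near-zero error", {
  # the model class contains the linear map (first conv reads the current
  # sample, head is linear), so with a generous optimization budget the
  # training MSE must approach zero; lr_step is stretched so the step
  # decay does not freeze the optimizer early
  fx <- fixture_linear_windows()
  ws <- fx$ws
  norm <- fit_normalizer(ws)
  tspec <- train_spec(seed = 2L, epochs = 500L, lr_step = 120L,
                      weight_decay = 0)
  m <- build_model(model_spec("tcn", channels = 16, dropout = 0), 7, 2,
                   seed = 11)
  m <- train_model(m, ws, tspec, norm = norm)
  pred <- model_predict(m, ws, norm = norm)
  expect_lt(mean((pred - ws$targets)^2), 1e-2)
  expect_true(all(is.finite(m$loss_trajectory)))
  expect_equal(m$lr_trajectory, lr_at(0:499, tspec))
})

test_that("training is reproducible from the seed", {
  fx <- fixture_linear_windows()
  tspec <- train_spec(seed = 2L, epochs = 5L)
  norm <- fit_normalizer(fx$ws)
  run <- function(seed_model) {
    m <- build_model(model_spec("tcn", channels = 8), 7, 2, seed = seed_model)
    train_model(m, fx$ws, tspec, norm = norm)$loss_trajectory
  }
  expect_identical(run(11), run(11))
  expect_false(identical(run(11), run(12)))
})

test_that("by_block folds hold out whole trials and partition all windows", {
  fx <- fixture_linear_windows(n_trials = 5)
  ws <- fx$ws
  tspec <- train_spec(seed = 3L, epochs = 2L, folds = 5L)
  fold_of <- semg2angle:::fold_assignment(ws, tspec)
  expect_length(fold_of, dim(ws$inputs)[1])
  for (f in 1:5) {
    expect_length(unique(ws$trial_ids[fold_of == f]), 1L)
  }
  expect_equal(sort(unique(fold_of)), 1:5)
  expect_equal(sum(table(fold_of)), dim(ws$inputs)[1])

  too_few <- subset_windows(ws, ws$trial_ids <= 3)
  expect_error(semg2angle:::fold_assignment(too_few, tspec), "by_window")
})

test_that("cross_validate returns held-out predictions per fold", {
  fx <- fixture_linear_windows(n_trials = 5)
  ws <- fx$ws
  tspec <- train_spec(seed = 4L, epochs = 8L, folds = 5L)
  res <- cross_validate(model_spec("tcn", channels = 8, dropout = 0), ws,
                        tspec)
  expect_length(res, 5)
  idx <- sort(unlist(lapply(res, `[[`, "test_idx")))
  expect_equal(idx, seq_len(dim(ws$inputs)[1]))
  met <- semg2angle:::fold_metrics(res, "tcn")
  expect_equal(nrow(met), 10L)          # 5 folds x 2 joints
  expect_true(all(is.finite(met$rmse)))

  # wiener route shares the fold interface; data are exactly linear
  resw <- cross_validate(model_spec("wiener"), ws, tspec)
  metw <- semg2angle:::fold_metrics(resw, "wiener")
  expect_true(all(metw$r2 > 0.99))
})

test_that("random window splitting is optimistic versus block splitting", {
  # windows overlap in W - 1 samples, so randomly assigning windows to
  # folds leaks near-duplicates into the held-out sets; blocked splitting
  # does not. Demonstrated on one long drifting trial cut into contiguous
  # blocks, with an overfit-capable model.
  cfg <- sim_config("gait", duration_s = 15, seed = 60L, snr_db = 20)
  pt <- preprocess_session(simulate_session(cfg))
  ws <- make_windows(pt, window_spec(), trial_id = 1L)
  ws$trial_ids <- as.integer(cut(seq_len(dim(ws$inputs)[1]), 5))
  r2_of <- function(policy) {
    tspec <- train_spec(seed = 6L, epochs = 50L, folds = 5L,
                        split_policy = policy)
    res <- cross_validate(model_spec("tcn", channels = 16, dropout = 0),
                          ws, tspec)
    met <- semg2angle:::fold_metrics(res, "tcn")
    mean(met$r2[met$joint == "knee"])
  }
  expect_gt(r2_of("by_window"), r2_of("by_block"))
})

test_that("run_comparison produces one tidy row per model, joint and fold", {
  fx <- fixture_linear_windows(n_trials = 5)
  tspec <- train_spec(seed = 8L, epochs = 3L, folds = 5L)
  specs <- list(tcn = model_spec("tcn", channels = 4),
                wiener = model_spec("wiener"))
  df <- run_comparison(specs, fx$ws, tspec)
  expect_equal(nrow(df), 2L * 2L * 5L)
  expect_setequal(unique(df$model), c("tcn", "wiener"))
  expect_true(all(c("r2", "rmse", "nrmse") %in% names(df)))
})
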