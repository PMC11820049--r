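# architectures: attention oracle, causality, baselines, Wiener

test_that("CBAM agrees with the brute-force attention oracle", {
  set.seed(31)
  for (rep in 1:20) {
    C <- sample(1:4, 1); T_ <- sample(2:8, 1); k <- sample(1:2, 1)
    l <- semg2angle:::layer_cbam(C, k = k)
    Xs <- matrix(rnorm(T_ * C), T_, C)
    Xb <- array(0, c(1, T_, C)); Xb[1, , ] <- Xs   # X[1, t, c] = Xs[t, c]
    out <- semg2angle:::layer_forward(l, Xb)
    ref <- oracle_cbam(Xs, l$params$W0, l$params$W1, l$params$wconv,
                       l$params$bconv)
    expect_lt(max(abs(out[1, , ] - ref$out)), 1e-10)
  }
})

test_that("zero-weight attention returns exactly 0.5 maps", {
  C <- 3; T_ <- 5
  l <- semg2angle:::layer_cbam(C, k = 2)
  l$params$W0[] <- 0; l$params$W1[] <- 0
  l$params$wconv[] <- 0; l$params$bconv <- 0
  Xb <- array(rnorm(T_ * C), c(1, T_, C))
  out <- semg2angle:::layer_forward(l, Xb)
  # Mc = sigma(0) = 0.5 and Ms = sigma(0) = 0.5 -> output = X / 4
  expect_equal(out, Xb * 0.25, tolerance = 1e-12)
})

test_that("attention weights are bounded and never amplify", {
  set.seed(32)
  for (rep in 1:10) {
    C <- sample(2:6, 1); T_ <- sample(3:9, 1)
    l <- semg2angle:::layer_cbam(C, k = 2)
    Xb <- array(rnorm(2 * T_ * C) * 3, c(2, T_, C))
    out <- semg2angle:::layer_forward(l, Xb)
    cc <- l$cache
    expect_true(all(cc$Mc > 0 & cc$Mc < 1))
    expect_true(all(cc$Ms > 0 & cc$Ms < 1))
    expect_true(all(abs(out) <= abs(Xb) + 1e-12))
  }
})

test_that("forward passes have the contracted output shape and determinism", {
  for (arch in c("cb_tcn", "ed_tcn", "tcn", "lstm")) {
    spec <- model_spec(arch, channels = 8)
    m <- build_model(spec, 7, 3, seed = 9)
    X <- with_seed_test(7, array(rnorm(4 * 10 * 7), c(4, 10, 7)))
    out <- model_forward(m, X)
    expect_equal(dim(out), c(4L, 3L))
    m2 <- build_model(spec, 7, 3, seed = 9)
    expect_equal(model_forward(m2, X), out, tolerance = 1e-14)
  }
})

test_that("window-level causality: samples beyond a window never matter", {
  # predictions for a window are invariant to any change in the series
  # after that window (windows are verbatim slices; the network sees
  # nothing else)
  set.seed(33)
  env <- matrix(abs(rnorm(40 * 7)), 40, 7,
                dimnames = list(NULL, paste0("ch", 1:7)))
  ang <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("hip", "knee")))
  for (arch in c("cb_tcn", "ed_tcn", "tcn")) {
    m <- build_model(model_spec(arch, channels = 8), 7, 2, seed = 5)
    ws <- make_windows(list(envelopes = env, angles = ang), window_spec())
    base <- model_predict(m, ws)
    env2 <- env; env2[25:40, ] <- env2[25:40, ] + 100
    ws2 <- make_windows(list(envelopes = env2, angles = ang), window_spec())
    pert <- model_predict(m, ws2)
    # windows ending before sample 25 are untouched
    expect_equal(pert[1:15, ], base[1:15, ], tolerance = 1e-12)
  }
})

test_that("ED-TCN equals CB-TCN with the attention module bypassed", {
  cb <- build_model(model_spec("cb_tcn", channels = 8, cbam_bypass = TRUE),
                    7, 3, seed = 17)
  ed <- build_model(model_spec("ed_tcn", channels = 8), 7, 3, seed = 17)
  # share every non-attention weight
  lcb <- semg2angle:::collect_layers(cb$layers)
  lcb <- Filter(function(l) l$kind != "cbam", lcb)
  led <- semg2angle:::collect_layers(ed$layers)
  stopifnot(length(lcb) == length(led))
  for (i in seq_along(led)) led[[i]]$params <- lcb[[i]]$params
  X <- with_seed_test(3, array(rnorm(5 * 10 * 7), c(5, 10, 7)))
  expect_equal(model_forward(ed, X), model_forward(cb, X), tolerance = 1e-12)
})

test_that("parameter counts satisfy the cascade bookkeeping identity", {
  spec_cb <- model_spec("cb_tcn", channels = 16)
  spec_ed <- model_spec("ed_tcn", channels = 16)
  n_cb <- count_params(build_model(spec_cb, 7, 3, seed = 1))
  n_ed <- count_params(build_model(spec_ed, 7, 3, seed = 1))
  C <- 16; k <- spec_cb$cbam_k
  cbam_params <- C * k + k * C + 3 * 2 + 1
  expect_equal(n_cb, n_ed + cbam_params)
})

test_that("Wiener recovers a known FIR exactly and shrinks under noise targets", {
  set.seed(41)
  # noiseless FIR-generated data, ridge = 0 -> exact recovery
  T_ <- 600; L <- 5
  x <- matrix(rnorm(T_ * 2), T_, 2)
  h <- list(c(0.5, -0.3, 0.2, 0.1, -0.05), c(1, 0.4, 0, -0.2, 0.3))
  y <- rep(2.5, T_)   # intercept 2.5
  for (ch in 1:2) {
    y <- y + as.numeric(stats::filter(x[, ch], h[[ch]], sides = 1,
                                      method = "convolution"))
  }
  keep <- !is.na(y)
  fit <- wiener_fit(x[keep, ], matrix(y[keep]), lag_order = L, ridge = 0)
  expect_equal(fit$coef[1], 2.5, tolerance = 1e-6)
  expect_equal(unname(fit$coef[2:6]), h[[1]], tolerance = 1e-6)
  expect_equal(unname(fit$coef[7:11]), h[[2]], tolerance = 1e-6)

  # the closed-form solution equals the brute-force pseudo-inverse
  Xd <- cbind(1, semg2angle:::lag_design(x[keep, ], L))
  ref <- oracle_pinv(Xd) %*% y[keep][L:sum(keep)]
  expect_equal(unname(fit$coef[, 1]), as.numeric(ref), tolerance = 1e-6)

  # independent white-noise target drives coefficients to ~0
  yn <- matrix(rnorm(1e4))
  xn <- matrix(rnorm(1e4 * 2), ncol = 2)
  fitn <- wiener_fit(xn, yn, lag_order = 5, ridge = 0)
  expect_lt(max(abs(fitn$coef[-1])), 0.05)

  # constant target -> intercept = mean, filter ~ 0
  fc <- wiener_fit(matrix(rnorm(200)), matrix(rep(7, 200)), 3, ridge = 1e-8)
  expect_equal(fc$coef[1], 7, tolerance = 1e-4)
  expect_lt(max(abs(fc$coef[-1])), 1e-4)

  # prediction reproduces the generating series
  pr <- wiener_predict(fit, x[keep, ])
  expect_equal(pr[L:sum(keep)], y[keep][L:sum(keep)], tolerance = 1e-6)
})

test_that("singular normal equations without ridge give a helpful error", {
  x <- matrix(rep(1, 50))          # constant channel: collinear with intercept
  y <- matrix(rnorm(50))
  expect_error(wiener_fit(x, y, lag_order = 3, ridge = 0), "ridge")
  expect_silent(wiener_fit(x, y, lag_order = 3, ridge = 1e-6))
})
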