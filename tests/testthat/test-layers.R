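# layer primitives: exact gradients and structural contracts

lc <- function(...) semg2angle:::layer_conv1d(...)

test_that("causal dilated convolution matches hand computation", {
  # K = 1 identity
  expect_equal(causal_dilated_conv(c(3, -1, 2), 1), c(3, -1, 2))
  # hand oracle: x = 1..4, f = (1, 1), current-sample convention
  expect_equal(causal_dilated_conv(1:4, c(1, 1)), c(1, 3, 5, 7))
  # dilation skips d samples
  expect_equal(causal_dilated_conv(1:5, c(1, 1), d = 2), c(1, 2, 4, 6, 8))
  # the literal printed indexing (strictly past) differs by one shift;
  # kept as a documented oracle of the notational variant
  expect_equal(oracle_causal_conv_strict_past(1:4, c(1, 1)), c(0, 1, 3, 5))

  # the batched layer agrees with the scalar reference on 1 channel
  l <- lc(1, 1, 3, 2)
  l$params$W <- lapply(1:3, function(k) matrix(k / 2, 1, 1))
  l$params$b <- 0
  x <- rnorm(12)
  y <- semg2angle:::layer_forward(l, array(x, c(1, 12, 1)))
  expect_equal(as.numeric(y), causal_dilated_conv(x, c(1, 2, 3) / 2, d = 2),
               tolerance = 1e-12)
})

test_that("convolution and residual blocks are strictly causal", {
  set.seed(14)
  stack <- list(semg2angle:::layer_residual(3, 8, 3, 1, dropout = 0),
                semg2angle:::layer_residual(8, 8, 3, 2, dropout = 0))
  X <- array(rnorm(2 * 12 * 3), c(2, 12, 3))
  base <- X
  for (l in stack) base <- semg2angle:::layer_forward(l, base, train = FALSE)
  for (probe in 1:10) {
    tp <- sample(2:12, 1)
    Xp <- X
    Xp[1, tp, sample(3, 1)] <- rnorm(1) * 10
    out <- Xp
    for (l in stack) out <- semg2angle:::layer_forward(l, out, train = FALSE)
    expect_equal(out[, seq_len(tp - 1), , drop = FALSE],
                 base[, seq_len(tp - 1), , drop = FALSE], tolerance = 1e-12)
  }
})

test_that("zero-weight residual block passes its input through the shortcut", {
  l <- semg2angle:::layer_residual(4, 4, 3, 1, dropout = 0)
  for (sub in l$main) {
    if (sub$kind == "conv1d") {
      sub$params$W <- lapply(sub$params$W, function(w) w * 0)
      sub$params$b <- sub$params$b * 0
    }
  }
  X <- array(abs(rnorm(2 * 6 * 4)), c(2, 6, 4))   # non-negative input
  out <- semg2angle:::layer_forward(l, X, train = FALSE)
  expect_equal(out, X, tolerance = 1e-12)
})

test_that("receptive field of a dilated stack matches the formula", {
  # 2 blocks, K = 3, dilations (1, 2), two convs per block:
  # RF = 1 + 2 * (K - 1) * (1 + 2) = 13 -> perturbation at t - 13 is unseen
  set.seed(15)
  stack <- list(semg2angle:::layer_residual(1, 4, 3, 1, dropout = 0),
                semg2angle:::layer_residual(4, 4, 3, 2, dropout = 0))
  T_ <- 40
  X <- array(rnorm(T_), c(1, T_, 1))
  base <- X
  for (l in stack) base <- semg2angle:::layer_forward(l, base, train = FALSE)
  probe <- function(tp) {
    Xp <- X; Xp[1, tp, 1] <- Xp[1, tp, 1] + 5
    out <- Xp
    for (l in stack) out <- semg2angle:::layer_forward(l, out, train = FALSE)
    abs(out[1, T_, ] - base[1, T_, ])
  }
  expect_gt(max(probe(T_ - 12)), 0)        # inside the receptive field
  expect_equal(max(probe(T_ - 13)), 0)     # just outside
})

test_that("analytic gradients match numeric differentiation", {
  set.seed(1)
  tol <- 5e-4
  expect_lt(gradcheck_layers(list(lc(2, 4, 3, 2),
                                  semg2angle:::layer_batchnorm(4),
                                  semg2angle:::layer_relu(),
                                  semg2angle:::layer_head(4, 2)),
                             C_in = 2, n_out = 2), tol)
  expect_lt(gradcheck_layers(list(semg2angle:::layer_residual(2, 4, 3, 1, 0.3),
                                  semg2angle:::layer_head(4, 2)),
                             C_in = 2, n_out = 2), tol)
  expect_lt(gradcheck_layers(list(lc(2, 4, 1, 1),
                                  semg2angle:::layer_cbam(4, k = 2),
                                  semg2angle:::layer_head(4, 2)),
                             C_in = 2, n_out = 2), tol)
  expect_lt(gradcheck_layers(list(semg2angle:::layer_lstm(2, 5),
                                  semg2angle:::layer_head(5, 2)),
                             C_in = 2, n_out = 2), tol)
  expect_lt(gradcheck_layers(
    build_model(model_spec("cb_tcn", channels = 6, cbam_k = 2), 2, 2,
                seed = 3)$layers, C_in = 2, n_out = 2), tol)
})

test_that("batchnorm eval mode uses running statistics", {
  l <- semg2angle:::layer_batchnorm(2)
  set.seed(2)
  X <- array(rnorm(4 * 5 * 2, mean = 3, sd = 2), c(4, 5, 2))
  for (i in 1:200) semg2angle:::layer_forward(l, X, train = TRUE)
  out <- semg2angle:::layer_forward(l, X, train = FALSE)
  m <- matrix(out, 20, 2)
  expect_lt(max(abs(colMeans(m))), 0.05)
  expect_lt(max(abs(apply(m, 2, sd) - 1)), 0.1)
})
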