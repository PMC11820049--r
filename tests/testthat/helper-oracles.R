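# independent oracles used across test files; these deliberately avoid the
# package's own code paths

# brute-force CBAM evaluation: channel attention (temporal avg/max pooling
# through a shared two-layer MLP, summed, sigmoid) followed by temporal
# attention (channel avg/max pooling, width-3 conv with symmetric zero
# padding, sigmoid), computed loop-by-loop on one sample
oracle_cbam <- function(X, W0, W1, wconv, bconv) {
  sig <- function(x) 1 / (1 + exp(-x))
  T_ <- nrow(X); C <- ncol(X)          # X is T x C (one sample)
  favg <- colMeans(X)
  fmax <- apply(X, 2, max)
  mlp <- function(v) as.numeric(pmax(v %*% W0, 0) %*% W1)
  Mc <- sig(mlp(favg) + mlp(fmax))
  F1 <- sweep(X, 2, Mc, "*")
  a2 <- rowMeans(F1)
  m2 <- apply(F1, 1, max)
  kk <- nrow(wconv); half <- (kk - 1) %/% 2
  a2p <- c(rep(0, half), a2, rep(0, half))
  m2p <- c(rep(0, half), m2, rep(0, half))
  s <- vapply(seq_len(T_), function(t) {
    acc <- bconv
    for (j in seq_len(kk)) {
      acc <- acc + wconv[j, 1] * a2p[t + j - 1] + wconv[j, 2] * m2p[t + j - 1]
    }
    acc
  }, numeric(1))
  Ms <- sig(s)
  list(Mc = Mc, Ms = Ms, out = F1 * Ms)
}

# literal textbook indexing of the causal convolution (kernel applied to
# strictly past samples, current sample excluded) -- kept as documentation
# of the printed form; the network uses the standard convention
oracle_causal_conv_strict_past <- function(x, f) {
  T_ <- length(x)
  y <- numeric(T_)
  for (t in seq_len(T_)) {
    for (k in seq_along(f)) {
      if (t - k >= 1) y[t] <- y[t] + f[k] * x[t - k]
    }
  }
  y
}

# direct difference-equation filter (naive loops)
oracle_lfilter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  y <- numeric(length(x))
  for (n in seq_along(x)) {
    for (k in seq_along(b)) {
      if (n - k + 1 >= 1) y[n] <- y[n] + b[k] * x[n - k + 1]
    }
    if (length(a) > 1) for (k in 2:length(a)) {
      if (n - k + 1 >= 1) y[n] <- y[n] - a[k] * y[n - k + 1]
    }
  }
  y
}

# two-pass reference metrics
oracle_metrics <- function(y, yhat) {
  n <- length(y)
  ybar <- sum(y) / n
  ss_res <- 0; ss_tot <- 0
  for (i in seq_len(n)) {
    ss_res <- ss_res + (yhat[i] - y[i])^2
    ss_tot <- ss_tot + (ybar - y[i])^2
  }
  rmse <- sqrt(ss_res / n)
  list(r2 = 1 - ss_res / ss_tot, rmse = rmse,
       nrmse = rmse / (max(y) - min(y)))
}

# one-way ANOVA from sum-of-squares identities
oracle_anova <- function(values, groups) {
  groups <- as.factor(groups)
  n <- length(values); k <- nlevels(groups)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(g) {
    length(g) * (mean(g) - grand)^2
  }))
  ss_within <- sum(unlist(tapply(values, groups, function(g) (g - mean(g))^2)))
  df1 <- k - 1; df2 <- n - k
  F_ <- (ss_between / df1) / (ss_within / df2)
  list(F = F_, p = stats::pf(F_, df1, df2, lower.tail = FALSE))
}

# numeric gradient check: max relative error over sampled coordinates of
# every parameter and the input, for a model built from `layers`
gradcheck_layers <- function(layers, C_in, n_out, N = 3, T_ = 6,
                             train = TRUE, seed = 42, n_probe = 3) {
  set.seed(seed)
  X <- array(rnorm(N * T_ * C_in), c(N, T_, C_in))
  Y <- matrix(rnorm(N * n_out), N, n_out)
  model <- structure(list(layers = layers, n_joints = n_out),
                     class = "net_model")
  loss_fn <- function() {
    set.seed(99)  # freeze dropout masks
    mean((model_forward(model, X, train = train) - Y)^2)
  }
  set.seed(99)
  pred <- model_forward(model, X, train = train)
  dY <- 2 * (pred - Y) / length(pred)
  dX <- semg2angle:::model_backward(model, dY)
  eps <- 1e-5
  worst <- 0
  for (l in semg2angle:::collect_layers(layers)) {
    for (nm in names(l$params)) {
      p <- l$params[[nm]]; gr <- l$grads[[nm]]
      pieces <- if (is.list(p)) seq_along(p) else NA
      for (k in pieces) {
        pp <- if (is.list(p)) p[[k]] else p
        gg <- if (is.list(p)) gr[[k]] else gr
        for (i in sample(length(pp), min(n_probe, length(pp)))) {
          orig <- pp[i]
          setp <- function(val) {
            if (is.list(p)) l$params[[nm]][[k]][i] <<- val
            else l$params[[nm]][i] <<- val
          }
          setp(orig + eps); lp <- loss_fn()
          setp(orig - eps); lm <- loss_fn()
          setp(orig)
          num <- (lp - lm) / (2 * eps)
          worst <- max(worst, abs(num - gg[i]) /
                                max(1e-6, abs(num) + abs(gg[i])))
        }
      }
    }
  }
  for (i in sample(length(X), 6)) {
    orig <- X[i]
    X[i] <- orig + eps; lp <- loss_fn()
    X[i] <- orig - eps; lm <- loss_fn()
    X[i] <- orig
    num <- (lp - lm) / (2 * eps)
    worst <- max(worst, abs(num - dX[i]) / max(1e-6, abs(num) + abs(dX[i])))
  }
  worst
}

# naive pseudo-inverse via SVD, avoiding the package's solver
oracle_pinv <- function(X, tol = 1e-10) {
  s <- svd(X)
  d <- ifelse(s$d > tol * max(s$d), 1 / s$d, 0)
  s$v %*% (d * t(s$u))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
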