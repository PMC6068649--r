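test_that("LM solves a linear least-squares recast in <= 3 iterations", {
  set.seed(1)
  A <- matrix(stats::rnorm(40), 10, 4)
  tgt <- stats::rnorm(10)
  rfn <- function(w) list(residuals = tgt - drop(A %*% w), jacobian = -A)
  res <- lm_optimize(rfn, rep(0, 4),
                     train_config("lm", error_goal = 1e-12, max_epochs = 10))
  w_star <- solve(crossprod(A), crossprod(A, tgt))  # normal-equations oracle
  expect_lte(res$epochs, 3)
  expect_lt(max(abs(res$w - w_star)), 1e-8)
})

test_that("LM accepted steps never increase the loss", {
  b <- make_blobs(31)
  fit <- train_mlp(mlp_init(4, 8, 3, seed = 1), b$x, b$targets,
                   train_config("lm", max_epochs = 40, error_goal = 1e-9))
  expect_true(all(diff(fit$mse_trace) <= 0))
})

test_that("at large damping the LM step direction approaches the negative gradient", {
  set.seed(5)
  A <- matrix(stats::rnorm(30), 10, 3)
  tgt <- stats::rnorm(10)
  rfn <- function(w) list(residuals = tgt - drop(A %*% w), jacobian = -A)
  w0 <- c(1, -1, 2)
  res <- lm_optimize(rfn, w0,
                     train_config("lm", error_goal = 1e-30, max_epochs = 1,
                                  lm = list(mu0 = 1e8)))
  step <- res$w - w0
  g <- drop(crossprod(-A, tgt - drop(A %*% w0)))  # gradient of SSE/2
  cosang <- sum(step * (-g)) / sqrt(sum(step^2) * sum(g^2))
  expect_gt(cosang, cos(pi / 180))
})

test_that("LM masters the XOR benchmark for most seeds", {
  d <- xor_data()
  wins <- 0
  for (s in 1:10) {
    fit <- train_mlp(mlp_init(2, 2, 1, seed = s), d$x, d$y,
                     train_config("lm"))
    wins <- wins + (fit$final_mse < 1e-3)
  }
  expect_gte(wins, 8)
})

test_that("SCG minimises an n-dimensional quadratic within n + 5 iterations", {
  set.seed(2)
  n <- 10
  Q <- qr.Q(qr(matrix(stats::rnorm(n * n), n)))
  M <- Q %*% diag(seq(1, 10, length.out = n)) %*% t(Q)
  b <- stats::rnorm(n)
  shift <- 0.5 * sum(solve(M, b) * b) + 1   # keep the minimum value positive
  fn <- function(w) list(value = 0.5 * sum(w * (M %*% w)) - sum(b * w) + shift,
                         grad = drop(M %*% w - b))
  res <- scg_optimize(fn, rep(0, n),
                      train_config("scg", error_goal = 1e-12,
                                   max_epochs = n + 5, min_gradient = 1e-12))
  expect_lt(max(abs(res$w - solve(M, b))), 1e-6)
})

test_that("trainers leave the model untouched when the goal is already met", {
  b <- make_blobs(7, n_per = 4)
  m <- mlp_init(4, 5, 3, seed = 7)
  for (alg in c("lm", "scg", "rprop", "gd")) {
    fit <- train_mlp(m, b$x, b$targets,
                     train_config(alg, error_goal = 10))
    expect_equal(fit$epochs, 0)
    expect_identical(fit$model$W1, m$W1)
    expect_identical(fit$stop_reason, "error_goal")
  }
})

test_that("rprop steps grow geometrically under a constant-sign gradient", {
  cfg <- train_config("rprop", max_epochs = 10, error_goal = 1e-12)
  fn <- function(w) list(value = 1, grad = 1)   # constant positive gradient
  res <- rprop_optimize(fn, 0, cfg)
  # first epoch keeps delta0 (no history), then eta_plus growth
  expect_equal(res$delta, 0.07 * 1.2^9, tolerance = 1e-12)
  expect_equal(res$w, -sum(0.07 * c(1, 1.2^(1:9))), tolerance = 1e-12)
})

test_that("rprop steps shrink toward delta_min under alternating gradients", {
  cfg <- train_config("rprop", max_epochs = 40, error_goal = 1e-12)
  flip <- new.env(); flip$k <- 0
  fn <- function(w) {
    flip$k <- flip$k + 1
    list(value = 1, grad = if (flip$k %% 2) 1 else -1)
  }
  res <- rprop_optimize(fn, 0, cfg)
  # a sign flip halves the step (with retraction) every other epoch
  expect_equal(res$delta, max(0.07 * 0.5^19, 1e-6), tolerance = 1e-9)
})

test_that("rprop caps steps at delta_max and floors them at delta_min", {
  cfg <- train_config("rprop", max_epochs = 60, error_goal = 1e-12,
                      rprop = list(delta0 = 10, delta_max = 50))
  fn <- function(w) list(value = 1, grad = 1)
  expect_equal(rprop_optimize(fn, 0, cfg)$delta, 50)
})

test_that("gd reproduces a hand-computed delta-rule step and its degenerate cases", {
  m <- mlp_init(2, 2, 1, seed = 4)
  x <- matrix(c(0.3, 0.7), 1, 2)
  y <- matrix(1, 1, 1)
  # hand arithmetic: one delta-rule update with lr eta, no momentum history
  fw <- mlp_forward(m, x)
  e <- 1 - fw$output[1, 1]
  dk <- fw$output[1, 1] * (1 - fw$output[1, 1]) * e
  dj <- drop(dk * m$W2[1, ]) * fw$hidden[1, ] * (1 - fw$hidden[1, ])
  eta <- 0.1
  fit <- train_mlp(m, x, y, train_config("gd", lr = eta, max_epochs = 1,
                                         error_goal = 1e-12))
  expect_equal(fit$model$W2[1, ], m$W2[1, ] + eta * dk * fw$hidden[1, ],
               tolerance = 1e-12)
  expect_equal(fit$model$b2, m$b2 + eta * dk, tolerance = 1e-12)
  expect_equal(fit$model$W1, m$W1 + eta * outer(dj, x[1, ]),
               tolerance = 1e-12)

  # eta = 0: nothing moves
  fit0 <- train_mlp(m, x, y, train_config("gd", lr = 0, max_epochs = 3,
                                          error_goal = 1e-12))
  expect_identical(fit0$model$W1, m$W1)

  # momentum 0 reduces to the pure delta rule over two steps
  fit2 <- train_mlp(m, x, y, train_config("gd", lr = eta, momentum = 0,
                                          max_epochs = 2, error_goal = 1e-12))
  step1 <- train_mlp(m, x, y, train_config("gd", lr = eta, momentum = 0,
                                           max_epochs = 1, error_goal = 1e-12))
  step2 <- train_mlp(step1$model, x, y,
                     train_config("gd", lr = eta, momentum = 0,
                                  max_epochs = 1, error_goal = 1e-12))
  expect_equal(fit2$model$W1, step2$model$W1, tolerance = 1e-12)
})

test_that("all trainers are bit-reproducible given identical seeds", {
  b <- make_blobs(19, n_per = 5)
  for (alg in c("lm", "scg", "rprop", "gd")) {
    f1 <- train_mlp(mlp_init(4, 6, 3, seed = 2), b$x, b$targets,
                    train_config(alg, max_epochs = 30))
    f2 <- train_mlp(mlp_init(4, 6, 3, seed = 2), b$x, b$targets,
                    train_config(alg, max_epochs = 30))
    expect_identical(f1$model, f2$model)
    expect_identical(f1$mse_trace, f2$mse_trace)
  }
})

test_that("scg beats plain gradient descent at an equal epoch budget on most seeds", {
  wins <- 0
  for (s in 1:10) {
    b <- make_blobs(100 + s)
    m <- mlp_init(4, 10, 3, seed = s)
    f_scg <- train_mlp(m, b$x, b$targets,
                       train_config("scg", max_epochs = 50,
                                    error_goal = 1e-12))
    f_gd <- train_mlp(m, b$x, b$targets,
                      train_config("gd", max_epochs = 50,
                                   error_goal = 1e-12))
    wins <- wins + (f_scg$final_mse <= f_gd$final_mse)
  }
  expect_gte(wins, 6)
})

test_that("rprop reaches the error goal in fewer epochs than gradient descent on most seeds", {
  wins <- 0
  for (s in 1:10) {
    b <- make_blobs(100 + s)
    m <- mlp_init(4, 10, 3, seed = s)
    f_rp <- train_mlp(m, b$x, b$targets, train_config("rprop"))
    f_gd <- train_mlp(m, b$x, b$targets, train_config("gd"))
    gd_ep <- if (f_gd$stop_reason == "error_goal") f_gd$epochs else Inf
    wins <- wins + (f_rp$epochs < gd_ep)
  }
  expect_gte(wins, 6)
})
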