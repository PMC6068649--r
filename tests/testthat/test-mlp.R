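test_that("initialisation is seeded, bounded and layer-scaled", {
  a <- mlp_init(seed = 5)
  b <- mlp_init(seed = 5)
  expect_identical(a, b)
  expect_false(identical(mlp_init(seed = 6)$W1, a$W1))
  expect_true(all(abs(a$W1) <= sqrt(6 / (4 + 35))))
  expect_true(all(abs(a$W2) <= sqrt(6 / (35 + 3))))
  expect_equal(length(ppgstenosis:::mlp_weights(a)), 35 * 4 + 35 + 3 * 35 + 3)
})

test_that("zero weights and biases produce sigmoid(0) = 0.5 everywhere", {
  m <- mlp_init(4, 7, 3, seed = 1)
  m$W1[] <- 0; m$b1[] <- 0; m$W2[] <- 0; m$b2[] <- 0
  out <- mlp_forward(m, matrix(stats::rnorm(8), 2, 4))$output
  expect_equal(as.vector(out), rep(0.5, 6))
  expect_equal(as.vector(mlp_forward(m, c(0, 0, 0, 0))$output), rep(0.5, 3))
})

test_that("vectorised forward pass matches an explicit loop oracle", {
  set.seed(14)
  m <- mlp_init(3, 6, 2, seed = 14)
  x <- matrix(stats::rnorm(12), 4, 3)
  got <- mlp_forward(m, x)$output
  sig <- function(v) 1 / (1 + exp(-v))
  for (p in 1:4) {
    h <- numeric(6)
    for (j in 1:6) h[j] <- sig(sum(m$W1[j, ] * x[p, ]) + m$b1[j])
    for (k in 1:2) {
      y <- sig(sum(m$W2[k, ] * h) + m$b2[k])
      expect_lt(abs(got[p, k] - y), 1e-12)
    }
  }
  expect_true(all(got > 0 & got < 1))
  expect_error(mlp_forward(m, matrix(1, 2, 4)), "expects")
})

test_that("mse loss matches closed forms", {
  expect_equal(mlp_mse(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(mlp_mse(c(0.9, 0, 0), c(1, 0, 0)), 0.01 / 3)
  expect_error(mlp_mse(1:3, 1:4), "same shape")
})

test_that("backprop gradient matches central finite differences", {
  set.seed(3)
  m <- mlp_init(4, 5, 3, seed = 3)
  x <- matrix(stats::runif(20), 5, 4)
  y <- class_one_hot(sample(1:3, 5, replace = TRUE))
  gr <- mlp_gradients(m, x, y)
  w <- ppgstenosis:::mlp_weights(m)
  h <- 1e-6
  fd <- vapply(seq_along(w), function(j) {
    wp <- w; wp[j] <- wp[j] + h
    wm <- w; wm[j] <- wm[j] - h
    (mlp_gradients(ppgstenosis:::mlp_set_weights(m, wp), x, y)$mse -
     mlp_gradients(ppgstenosis:::mlp_set_weights(m, wm), x, y)$mse) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(gr$grad_mse - fd) / pmax(abs(fd), 1e-8)), 1e-5)
})

test_that("the error Jacobian reassembles the backprop gradient", {
  set.seed(4)
  m <- mlp_init(4, 6, 3, seed = 4)
  x <- matrix(stats::runif(16), 4, 4)
  y <- class_one_hot(c(1, 2, 3, 1))
  gr <- mlp_gradients(m, x, y, jacobian = TRUE)
  expect_equal(dim(gr$jacobian),
               c(4 * 3, length(ppgstenosis:::mlp_weights(m))))
  g_from_j <- 2 * drop(crossprod(gr$jacobian, gr$residuals)) / (4 * 3)
  expect_lt(max(abs(g_from_j - gr$grad_mse)), 1e-10)
})

test_that("a perfect fit has an exactly zero gradient", {
  m <- mlp_init(2, 3, 2, seed = 9)
  x <- matrix(stats::rnorm(6), 3, 2)
  y <- mlp_forward(m, x)$output     # targets equal to the outputs
  gr <- mlp_gradients(m, x, y)
  expect_equal(max(abs(gr$grad_mse)), 0)
  expect_equal(gr$mse, 0)
})

test_that("gradients are bit-reproducible and a single output weight follows the delta rule", {
  m <- mlp_init(4, 5, 3, seed = 2)
  x <- matrix(stats::runif(8), 2, 4)
  y <- class_one_hot(c(1, 3))
  g1 <- mlp_gradients(m, x, y, jacobian = TRUE)
  g2 <- mlp_gradients(m, x, y, jacobian = TRUE)
  expect_identical(g1, g2)

  # one sample: dE/dW2[k, j] = -2/(n o) * hidden_j * delta_k
  fw <- mlp_forward(m, x[1, , drop = FALSE])
  e <- class_one_hot(1) - fw$output
  delta_k <- fw$output * (1 - fw$output) * e
  g_one <- mlp_gradients(m, x[1, , drop = FALSE], class_one_hot(1))
  gW2 <- matrix(g_one$grad_mse[(4 * 5 + 5 + 1):(4 * 5 + 5 + 15)], nrow = 3)
  expect_equal(gW2, -2 / 3 * t(delta_k) %*% fw$hidden, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("model JSON serialisation round-trips", {
  m <- mlp_init(4, 5, 3, seed = 8)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  mlp_save_json(m, path)
  back <- mlp_load_json(path)
  x <- matrix(stats::runif(8), 2, 4)
  expect_equal(mlp_forward(back, x)$output, mlp_forward(m, x)$output,
               tolerance = 1e-12)
})
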