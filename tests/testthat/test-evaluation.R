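test_that("confusion matrix counts match a brute-force double loop", {
  act <- c(1, 1, 1, 2, 2, 3)
  expect_equal(diag(confusion_matrix3(act, act)), c(3, 2, 1),
               ignore_attr = TRUE)
  all1 <- confusion_matrix3(act, rep(1, 6))
  expect_equal(as.vector(all1[, 1]), c(3, 2, 1))
  expect_equal(sum(all1[, 2:3]), 0)

  set.seed(12)
  a <- sample(1:3, 60, replace = TRUE)
  p <- sample(1:3, 60, replace = TRUE)
  cm <- confusion_matrix3(a, p)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(cm[i, j], sum(a == i & p == j))
  }
  expect_error(confusion_matrix3(c(1, 4), c(1, 1)), "labels")
  expect_error(confusion_matrix3(1:3, 1:2), "equal length")
})

test_that("micro-aggregation matches hand expansions and its algebraic identities", {
  cm <- diag(c(4, 4, 2))
  ag <- aggregate_counts(cm)
  expect_equal(ag[c("TP", "FP", "FN", "TN")],
               list(TP = 10, FP = 0, FN = 0, TN = 20))

  cm[1, 2] <- 1   # a single class-1 -> class-2 error
  ag1 <- aggregate_counts(cm)
  expect_equal(ag1[c("TP", "FP", "FN", "TN")],
               list(TP = 10, FP = 1, FN = 1, TN = 21))

  set.seed(30)
  for (i in 1:20) {
    cm <- matrix(sample(0:9, 9, replace = TRUE), 3, 3)
    ag <- aggregate_counts(cm)
    expect_equal(ag$FP, ag$FN)
    expect_equal(ag$TN, ag$N + ag$TP)
    expect_equal(ag$TP + ag$FN, ag$N)
  }
})

test_that("metrics reach 100% for a perfect classifier and honour the rate identities", {
  perfect <- classification_metrics(aggregate_counts(diag(c(5, 4, 2))))
  expect_equal(unname(perfect), rep(100, 5))

  m <- classification_metrics(list(TP = 10, FP = 1, FN = 1, TN = 21))
  expect_equal(unname(m["REC"]), unname(m["PPV"]))
  R <- m[["REC"]] / 100
  expect_equal(m[["ACC"]], (1 + 2 * R) / 3 * 100, tolerance = 1e-12)
  expect_equal(m[["SPE"]], (1 + R) / 2 * 100, tolerance = 1e-12)
  expect_equal(m[["GM"]], sqrt(m[["REC"]] * m[["SPE"]]), tolerance = 1e-12)

  expect_warning(bad <- classification_metrics(
    list(TP = 0, FP = 2, FN = 0, TN = 5)), "REC undefined")
  expect_true(is.na(bad[["REC"]]))
  expect_true(is.na(bad[["GM"]]))
})

test_that("cross-validation with an always-correct dummy yields 100% with zero spread", {
  b <- make_blobs(40, n_per = 5)
  cv <- cross_validate(
    b$x, b$labels, k = 3, repeats = 4, seed = 2,
    train_fun = function(x, y, seed) "oracle",
    predict_fun = function(fit, x) {
      # nearest canonical centre: blobs are separable by construction
      ctr <- matrix(c(0.2, 0.2, 0.2, 0.2,
                      0.5, 0.8, 0.5, 0.8,
                      0.8, 0.3, 0.8, 0.3), 3, 4, byrow = TRUE)
      apply(x, 1, function(r) which.min(colSums((t(ctr) - r)^2)))
    })
  expect_equal(cv$metrics$mean[cv$metrics$metric == "ACC"], 100)
  expect_equal(cv$metrics$sd[cv$metrics$metric == "ACC"], 0)
})

test_that("an always-class-1 dummy on a balanced set scores REC 33.33%", {
  b <- make_blobs(41, n_per = 4)   # 4 per class, balanced
  cv <- cross_validate(
    b$x, b$labels, k = 4, repeats = 3, seed = 3,
    train_fun = function(x, y, seed) NULL,
    predict_fun = function(fit, x) rep(1L, nrow(x)))
  expect_equal(cv$metrics$mean[cv$metrics$metric == "REC"], 100 / 3,
               tolerance = 1e-9)
  expect_equal(cv$metrics$mean[cv$metrics$metric == "ACC"],
               (1 + 2 / 3) / 3 * 100, tolerance = 1e-9)
})

test_that("cross-validation rejects impossible fold counts and is seed-reproducible", {
  b <- make_blobs(42, n_per = 2)
  expect_error(cross_validate(b$x, b$labels, k = 7, seed = 1), "exceeds")
  cv1 <- cross_validate(b$x, b$labels, train_config("rprop"), hidden_dim = 5,
                        k = 2, repeats = 2, seed = 9)
  cv2 <- cross_validate(b$x, b$labels, train_config("rprop"), hidden_dim = 5,
                        k = 2, repeats = 2, seed = 9)
  expect_identical(cv1$per_repeat, cv2$per_repeat)
  expect_identical(cv1$confusions, cv2$confusions)
  # every sample predicted exactly once per repeat
  expect_true(all(vapply(cv1$confusions, sum, numeric(1)) == nrow(b$x)))
})
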