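# Shared fixtures, all generated in code.

# A single symmetric triangle pulse as a recording.
triangle_recording <- function(n_up = 100, amp = 1, rate = 1000) {
  y <- c(seq(0, amp, length.out = n_up + 1),
         seq(amp, 0, length.out = n_up + 1)[-1])
  ppg_recording(y, rate = rate)
}

# Independent brute-force robust local regression oracle: per-point weighted
# polynomial fit by explicit lm.wfit calls. Mirrors the documented smoother
# contract (tricube over a fixed +/-h sample window truncated at edges,
# bisquare reweighting at 6 * median absolute residual).
oracle_robust_loess <- function(y, h, degree, robust_iterations) {
  n <- length(y)
  r <- rep(1, n)
  fit <- numeric(n)
  for (iter in seq_len(robust_iterations + 1)) {
    for (j in seq_len(n)) {
      lo <- max(1, j - h); hi <- min(n, j + h)
      idx <- lo:hi
      delta <- idx - j
      wt <- (1 - (abs(delta) / (h + 1))^3)^3 * r[idx]
      X <- outer(delta, 0:degree, `^`)
      beta <- stats::lm.wfit(X, y[idx], wt)$coefficients
      fit[j] <- beta[1]
    }
    if (iter > robust_iterations) break
    e <- y - fit
    s <- 6 * stats::median(abs(e))
    if (s <= 0 || !is.finite(s)) break
    r <- pmax(1 - (e / s)^2, 0)^2
  }
  fit
}

# Well-separated 3-class Gaussian blobs in 4-D for trainer head-to-heads.
make_blobs <- function(seed, n_per = 10, sd = 0.08) {
  set.seed(seed)
  ctr <- matrix(c(0.2, 0.2, 0.2, 0.2,
                  0.5, 0.8, 0.5, 0.8,
                  0.8, 0.3, 0.8, 0.3), 3, 4, byrow = TRUE)
  x <- NULL; lab <- integer(0)
  for (cl in 1:3) {
    x <- rbind(x, matrix(stats::rnorm(n_per * 4, mean = ctr[cl, ], sd = sd),
                         n_per, 4, byrow = TRUE))
    lab <- c(lab, rep(cl, n_per))
  }
  list(x = x, labels = lab, targets = class_one_hot(lab))
}

# Small, fast cohort spec for pipeline-level tests.
small_cohort_spec <- function(...) {
  cohort_spec(n_per_class = c(2, 2, 2),
              segments_per_subject = 1,
              beats_per_recording = 13, ...)
}

xor_data <- function() {
  list(x = matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2),
       y = matrix(c(0, 1, 1, 0), ncol = 1))
}
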