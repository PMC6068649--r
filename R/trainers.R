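#' Training configuration
#'
#' Collects the stopping contract shared by all trainers (error goal on the
#' MSE, epoch budget, minimum gradient norm) and the per-algorithm
#' constants. The defaults mirror the reference experimental setup: learning
#' rate 0.1 and momentum 0.95 (honoured only by the plain gradient-descent
#' reference - the three main algorithms use neither), error goal 1e-3, at
#' most 1000 epochs.
#'
#' @param algorithm `"lm"` (Levenberg-Marquardt), `"scg"` (scaled conjugate
#'   gradient), `"rprop"` (resilient backpropagation) or `"gd"` (delta-rule
#'   gradient descent with momentum).
#' @param lr Learning rate (GD only).
#' @param error_goal Stop once the training MSE is at or below this.
#' @param max_epochs Epoch budget.
#' @param momentum Momentum factor (GD only).
#' @param seed Optional seed (recorded; used by callers that initialise).
#' @param min_gradient Stop when the gradient norm falls below this.
#' @param lm,scg,rprop Named lists overriding algorithm constants:
#'   `lm`: `mu0` 1e-3, `mu_inc` 10, `mu_dec` 10, `mu_max` 1e10;
#'   `scg`: `sigma` 5e-5, `lambda0` 5e-7;
#'   `rprop`: `delta0` 0.07, `eta_plus` 1.2, `eta_minus` 0.5,
#'   `delta_max` 50, `delta_min` 1e-6.
#' @return An object of class `train_config`.
#' @export
train_config <- function(algorithm = c("lm", "scg", "rprop", "gd"),
                         lr = 0.1, error_goal = 1e-3, max_epochs = 1000,
                         momentum = 0.95, seed = NULL,
                         min_gradient = 1e-10,
                         lm = list(), scg = list(), rprop = list()) {
  algorithm <- match.arg(algorithm)
  if (!(error_goal > 0)) stop("error_goal must be > 0")
  if (!(max_epochs >= 1)) stop("max_epochs must be >= 1")
  lm_d <- utils::modifyList(
    list(mu0 = 1e-3, mu_inc = 10, mu_dec = 10, mu_max = 1e10), lm)
  scg_d <- utils::modifyList(list(sigma = 5e-5, lambda0 = 5e-7), scg)
  rp_d <- utils::modifyList(
    list(delta0 = 0.07, eta_plus = 1.2, eta_minus = 0.5,
         delta_max = 50, delta_min = 1e-6), rprop)
  structure(list(algorithm = algorithm, lr = lr, error_goal = error_goal,
                 max_epochs = max_epochs, momentum = momentum, seed = seed,
                 min_gradient = min_gradient,
                 lm = lm_d, scg = scg_d, rprop = rp_d),
            class = "train_config")
}

## ---- generic optimiser cores -------------------------------------------
## These operate on plain weight vectors so their convergence behaviour can
## be checked against closed-form problems (linear least squares, quadratics)
## independently of the network.

#' Damped Gauss-Newton (Levenberg-Marquardt) core
#'
#' Minimises `mean(e(w)^2)` for a residual function by the damped normal
#' equations `(J'J + mu I) step = J'e`, solved by Cholesky factorisation
#' (never an explicit inverse). The damping `mu` is divided by `mu_dec`
#' after an accepted step and multiplied by `mu_inc` after a rejected one;
#' accepted steps strictly decrease the loss by construction.
#'
#' @param residual_fn Function `w -> list(residuals, jacobian)` with
#'   `jacobian = d residuals / d w`.
#' @param w0 Initial weight vector.
#' @param config A [train_config()].
#' @return List: `w`, `epochs` (accepted iterations), `mse_trace`
#'   (initial value followed by the value after each accepted step),
#'   `stop_reason` in `error_goal`, `max_epochs`, `mu_overflow`,
#'   `min_gradient`, and the final `mu`.
#' @export
lm_optimize <- function(residual_fn, w0, config = train_config("lm")) {
  w <- w0
  mu <- config$lm$mu0
  ev <- residual_fn(w)
  mse <- mean(ev$residuals^2)
  trace <- mse
  epochs <- 0
  reason <- "max_epochs"
  while (TRUE) {
    if (mse <= config$error_goal) { reason <- "error_goal"; break }
    if (epochs >= config$max_epochs) { reason <- "max_epochs"; break }
    J <- ev$jacobian
    g <- drop(crossprod(J, ev$residuals))
    if (max(abs(g)) < config$min_gradient) { reason <- "min_gradient"; break }
    H <- crossprod(J)
    accepted <- FALSE
    while (!accepted) {
      step <- tryCatch({
        R <- chol(H + diag(mu, ncol(H)))
        backsolve(R, forwardsolve(t(R), g))
      }, error = function(e) NULL)
      if (!is.null(step)) {
        w_new <- w - step
        ev_new <- residual_fn(w_new)
        mse_new <- mean(ev_new$residuals^2)
        if (is.finite(mse_new) && mse_new < mse) {
          w <- w_new; ev <- ev_new; mse <- mse_new
          mu <- mu / config$lm$mu_dec
          accepted <- TRUE
          epochs <- epochs + 1
          trace <- c(trace, mse)
        } else {
          mu <- mu * config$lm$mu_inc
        }
      } else {
        mu <- mu * config$lm$mu_inc
      }
      if (mu > config$lm$mu_max) break
    }
    if (!accepted) { reason <- "mu_overflow"; break }
  }
  list(w = w, epochs = epochs, mse_trace = trace, stop_reason = reason,
       mu = mu)
}

#' Scaled conjugate gradient core (Moller)
#'
#' Hessian-free conjugate-direction minimiser: the curvature along each
#' search direction is estimated from a finite gradient perturbation of size
#' `sigma`, and a Levenberg-style scaling `lambda` enforces positive
#' curvature; the step size has a closed second-order form, so no line
#' search is performed.
#'
#' @param fn Function `w -> list(value, grad)`.
#' @param w0 Initial weight vector.
#' @param config A [train_config()].
#' @return List: `w`, `epochs` (iterations), `mse_trace`, `stop_reason` in
#'   `error_goal`, `max_epochs`, `min_gradient`, `lambda_overflow`.
#' @export
scg_optimize <- function(fn, w0, config = train_config("scg")) {
  sigma0 <- config$scg$sigma
  lambda <- config$scg$lambda0
  lambdabar <- 0
  n <- length(w0)
  w <- w0
  cur <- fn(w)
  fw <- cur$value
  grad_w <- cur$grad
  r <- -grad_w
  p <- r
  success <- TRUE
  delta_raw <- 0
  trace <- fw
  epochs <- 0
  reason <- "max_epochs"
  while (TRUE) {
    if (fw <= config$error_goal) { reason <- "error_goal"; break }
    if (sqrt(sum(r^2)) < config$min_gradient) { reason <- "min_gradient"; break }
    if (epochs >= config$max_epochs) { reason <- "max_epochs"; break }
    pp <- sum(p^2)
    if (success) {
      sigma_k <- sigma0 / sqrt(pp)
      s <- (fn(w + sigma_k * p)$grad - grad_w) / sigma_k
      delta_raw <- sum(p * s)
    }
    delta <- delta_raw + (lambda - lambdabar) * pp
    if (delta <= 0) {                    # make the Hessian estimate PD
      lambdabar <- 2 * (lambda - delta / pp)
      delta <- -delta + lambda * pp
      lambda <- lambdabar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    f_new <- fn(w + alpha * p)$value
    Delta <- 2 * delta * (fw - f_new) / mu^2   # comparison ratio
    if (is.finite(Delta) && Delta >= 0) {
      w <- w + alpha * p
      cur <- fn(w)
      fw <- cur$value
      grad_w <- cur$grad
      r_new <- -grad_w
      lambdabar <- 0
      success <- TRUE
      if ((epochs + 1) %% n == 0) {
        p <- r_new                        # periodic restart
      } else {
        beta <- (sum(r_new^2) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
    } else {
      lambdabar <- lambda
      success <- FALSE
    }
    if (!is.finite(Delta) || Delta < 0.25) {
      lambda <- lambda + delta * (1 - max(Delta, 0, na.rm = TRUE)) / pp
    }
    if (!is.finite(lambda) || lambda > 1e100) {
      reason <- "lambda_overflow"; break
    }
    epochs <- epochs + 1
    trace <- c(trace, fw)
  }
  list(w = w, epochs = epochs, mse_trace = trace, stop_reason = reason)
}

#' Resilient backpropagation core (Rprop with weight backtracking)
#'
#' Per-weight adaptive step sizes: when the partial derivative keeps its
#' sign the step grows by `eta_plus`; when it flips the previous update is
#' retracted, the step shrinks by `eta_minus`, and that weight skips one
#' adaptation. Updates are `-sign(gradient) * step`, independent of the
#' gradient magnitude.
#'
#' @inheritParams scg_optimize
#' @return List: `w`, `epochs`, `mse_trace`, `stop_reason`, and the final
#'   per-weight `delta` steps.
#' @export
rprop_optimize <- function(fn, w0, config = train_config("rprop")) {
  cfg <- config$rprop
  w <- w0
  delta <- rep(cfg$delta0, length(w))
  g_prev <- numeric(length(w))
  dw_prev <- numeric(length(w))
  cur <- fn(w)
  trace <- cur$value
  epochs <- 0
  reason <- "max_epochs"
  while (TRUE) {
    if (cur$value <= config$error_goal) { reason <- "error_goal"; break }
    g <- cur$grad
    if (max(abs(g)) < config$min_gradient) { reason <- "min_gradient"; break }
    if (epochs >= config$max_epochs) { reason <- "max_epochs"; break }
    s <- g_prev * g
    dw <- numeric(length(w))
    up <- s > 0
    delta[up] <- pmin(delta[up] * cfg$eta_plus, cfg$delta_max)
    dw[up] <- -sign(g[up]) * delta[up]
    dn <- s < 0
    delta[dn] <- pmax(delta[dn] * cfg$eta_minus, cfg$delta_min)
    dw[dn] <- -dw_prev[dn]               # retract the previous update
    g[dn] <- 0                            # skip one adaptation
    zo <- s == 0 & !dn
    dw[zo] <- -sign(g[zo]) * delta[zo]
    w <- w + dw
    g_prev <- g
    dw_prev <- dw
    cur <- fn(w)
    epochs <- epochs + 1
    trace <- c(trace, cur$value)
  }
  list(w = w, epochs = epochs, mse_trace = trace, stop_reason = reason,
       delta = delta)
}

#' Delta-rule gradient descent with momentum (reference trainer)
#'
#' Full-batch steepest descent `w <- w + momentum * v - lr * grad`, the
#' classical backpropagation delta rule the three main algorithms are
#' compared against.
#'
#' @inheritParams scg_optimize
#' @return List: `w`, `epochs`, `mse_trace`, `stop_reason` (adds
#'   `"divergence"` when the loss exceeds 1e6).
#' @export
gd_optimize <- function(fn, w0, config = train_config("gd")) {
  w <- w0
  v <- numeric(length(w))
  cur <- fn(w)
  trace <- cur$value
  epochs <- 0
  reason <- "max_epochs"
  while (TRUE) {
    if (cur$value <= config$error_goal) { reason <- "error_goal"; break }
    if (cur$value > 1e6) { reason <- "divergence"; break }
    g <- if (!is.null(cur$grad_delta)) cur$grad_delta else cur$grad
    if (max(abs(g)) < config$min_gradient) { reason <- "min_gradient"; break }
    if (epochs >= config$max_epochs) { reason <- "max_epochs"; break }
    v <- config$momentum * v - config$lr * g
    w <- w + v
    cur <- fn(w)
    epochs <- epochs + 1
    trace <- c(trace, cur$value)
  }
  list(w = w, epochs = epochs, mse_trace = trace, stop_reason = reason)
}

## ---- MLP front end ------------------------------------------------------

#' Train an MLP with a chosen algorithm
#'
#' Full-batch training of an [mlp_init()] network under the shared stopping
#' contract of [train_config()]: stop at `error_goal` MSE, at the epoch
#' budget, on a vanishing gradient, or on damping overflow (LM). The
#' gradient-descent reference uses the delta rule (learning rate x hidden
#' activation x output delta) with momentum; LM uses the residual Jacobian;
#' SCG and Rprop use the backpropagated MSE gradient.
#'
#' @param model An [mlp_init()] model (the starting weights).
#' @param x Input matrix (`n x input_dim`).
#' @param targets Target matrix (`n x output_dim`), e.g. one-hot rows.
#' @param config A [train_config()].
#' @return An object of class `mlp_train_result`: list with `model`
#'   (trained), `algorithm`, `epochs`, `mse_trace`, `final_mse`,
#'   `stop_reason`, `train_time_s`.
#' @examples
#' xor_x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2)
#' xor_y <- matrix(c(0, 1, 1, 0), ncol = 1)
#' fit <- train_mlp(mlp_init(2, 2, 1, seed = 3), xor_x, xor_y,
#'                  train_config("lm", max_epochs = 200))
#' fit$final_mse
#' @export
train_mlp <- function(model, x, targets, config = train_config()) {
  stopifnot(inherits(model, "mlp_model"), inherits(config, "train_config"))
  x <- as_input_matrix(x, model$input_dim)
  targets <- as.matrix(targets)
  if (nrow(x) == 0) stop("training data must be non-empty")
  w0 <- mlp_weights(model)
  n_res <- nrow(x) * model$output_dim

  residual_fn <- function(w) {
    m <- mlp_set_weights(model, w)
    gr <- mlp_gradients(m, x, targets, jacobian = TRUE)
    list(residuals = gr$residuals, jacobian = gr$jacobian)
  }
  value_grad <- function(w) {
    m <- mlp_set_weights(model, w)
    gr <- mlp_gradients(m, x, targets)
    list(value = gr$mse, grad = gr$grad_mse,
         grad_delta = gr$grad_mse * n_res / 2)  # delta-rule scale (half-SSE)
  }

  t0 <- proc.time()[["elapsed"]]
  res <- switch(config$algorithm,
    lm = lm_optimize(residual_fn, w0, config),
    scg = scg_optimize(value_grad, w0, config),
    rprop = rprop_optimize(value_grad, w0, config),
    gd = gd_optimize(value_grad, w0, config))
  elapsed <- proc.time()[["elapsed"]] - t0

  structure(list(model = mlp_set_weights(model, res$w),
                 algorithm = config$algorithm,
                 epochs = res$epochs,
                 mse_trace = res$mse_trace,
                 final_mse = res$mse_trace[length(res$mse_trace)],
                 stop_reason = res$stop_reason,
                 train_time_s = elapsed),
            class = "mlp_train_result")
}

#' @export
print.mlp_train_result <- function(x, ...) {
  cat(sprintf("<mlp_train_result> %s | %d epochs | MSE %.3g | stop: %s | %.3fs\n",
              x$algorithm, x$epochs, x$final_mse, x$stop_reason,
              x$train_time_s))
  invisible(x)
}
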