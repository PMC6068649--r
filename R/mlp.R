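#' Initialise a logistic-sigmoid multilayer perceptron
#'
#' Builds a fully connected one-hidden-layer network with logistic-sigmoid
#' activation at both the hidden and output layers. The default 4-35-3
#' architecture takes the four slope summary features (mean and variance of
#' the selected slope, before and after treatment) and emits three class
#' scores. All parameters (weights and biases) are drawn uniformly within
#' the layer-scaled bounds `+/- sqrt(6 / (fan_in + fan_out))`; biases can be
#' disabled entirely.
#'
#' @param input_dim,hidden_dim,output_dim Layer sizes (default 4, 35, 3).
#' @param seed Integer seed making the initialisation reproducible.
#' @param use_bias Include bias terms (default `TRUE`).
#' @return An object of class `mlp_model`: list with weight matrices `W1`
#'   (`hidden x input`), `W2` (`output x hidden`), bias vectors `b1`, `b2`,
#'   and the dimensions.
#' @examples
#' m <- mlp_init(seed = 1)
#' m
#' @export
mlp_init <- function(input_dim = 4, hidden_dim = 35, output_dim = 3,
                     seed = NULL, use_bias = TRUE) {
  stopifnot(input_dim >= 1, hidden_dim >= 1, output_dim >= 1)
  if (!is.null(seed)) set.seed(seed)
  lim1 <- sqrt(6 / (input_dim + hidden_dim))
  lim2 <- sqrt(6 / (hidden_dim + output_dim))
  structure(list(
    W1 = matrix(stats::runif(hidden_dim * input_dim, -lim1, lim1),
                nrow = hidden_dim),
    b1 = stats::runif(hidden_dim, -lim1, lim1),
    W2 = matrix(stats::runif(output_dim * hidden_dim, -lim2, lim2),
                nrow = output_dim),
    b2 = stats::runif(output_dim, -lim2, lim2),
    input_dim = input_dim, hidden_dim = hidden_dim, output_dim = output_dim,
    use_bias = use_bias),
    class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %d-%d-%d logistic-sigmoid MLP (%d weights%s)\n",
              x$input_dim, x$hidden_dim, x$output_dim, length(mlp_weights(x)),
              if (x$use_bias) ", biases on" else ", biases off"))
  invisible(x)
}

sigmoid <- function(v) 1 / (1 + exp(-v))

as_input_matrix <- function(x, input_dim) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != input_dim) {
    stop("input has ", ncol(x), " features; model expects ", input_dim)
  }
  x
}

#' Forward pass through an MLP
#'
#' Computes `y = sigmoid(W2 sigmoid(W1 x + b1) + b2)` for a batch of inputs.
#'
#' @param model An [mlp_init()] model.
#' @param x Input matrix (`n x input_dim`) or a single input vector.
#' @return List with `output` (`n x output_dim`), `hidden` (`n x hidden_dim`)
#'   activations and the pre-activations `v_hidden`, `v_output`.
#' @examples
#' m <- mlp_init(2, 3, 1, seed = 1)
#' mlp_forward(m, c(0.2, 0.8))$output
#' @export
mlp_forward <- function(model, x) {
  stopifnot(inherits(model, "mlp_model"))
  x <- as_input_matrix(x, model$input_dim)
  b1 <- if (model$use_bias) model$b1 else numeric(model$hidden_dim)
  b2 <- if (model$use_bias) model$b2 else numeric(model$output_dim)
  vh <- x %*% t(model$W1) + matrix(b1, nrow(x), model$hidden_dim, byrow = TRUE)
  h <- sigmoid(vh)
  vo <- h %*% t(model$W2) + matrix(b2, nrow(x), model$output_dim, byrow = TRUE)
  list(output = sigmoid(vo), hidden = h, v_hidden = vh, v_output = vo)
}

#' @export
predict.mlp_model <- function(object, newdata, type = c("score", "class"),
                              ...) {
  type <- match.arg(type)
  y <- mlp_forward(object, newdata)$output
  if (type == "score") y else max.col(y, ties.method = "first")
}

#' Mean squared error loss
#'
#' Mean of the squared errors `(target - output)^2` over all samples and all
#' output neurons.
#'
#' @param outputs,targets Equal-shaped matrices (or vectors).
#' @return A single non-negative number.
#' @examples
#' mlp_mse(c(0.9, 0.1, 0.1), c(1, 0, 0))
#' @export
mlp_mse <- function(outputs, targets) {
  outputs <- as.matrix(outputs); targets <- as.matrix(targets)
  if (!all(dim(outputs) == dim(targets))) {
    stop("outputs and targets must have the same shape")
  }
  mean((targets - outputs)^2)
}

# flatten model weights to a vector (order: W1, b1, W2, b2; column-major)
mlp_weights <- function(model) {
  if (model$use_bias) {
    c(as.vector(model$W1), model$b1, as.vector(model$W2), model$b2)
  } else {
    c(as.vector(model$W1), as.vector(model$W2))
  }
}

mlp_set_weights <- function(model, w) {
  r <- model$input_dim; h <- model$hidden_dim; o <- model$output_dim
  i <- 0
  model$W1 <- matrix(w[i + seq_len(h * r)], nrow = h); i <- i + h * r
  if (model$use_bias) { model$b1 <- w[i + seq_len(h)]; i <- i + h }
  model$W2 <- matrix(w[i + seq_len(o * h)], nrow = o); i <- i + o * h
  if (model$use_bias) { model$b2 <- w[i + seq_len(o)]; i <- i + o }
  stopifnot(i == length(w))
  model
}

#' Gradient, residuals and error Jacobian of an MLP batch
#'
#' For the batch sum of squared errors `F = sum(e^2)` with residuals
#' `e = target - output`, computes by backpropagation the gradient of the
#' mean squared error, and optionally the Jacobian `J = d e / d w` of the
#' residual vector with respect to all weights (the matrix used by the
#' damped Gauss-Newton trainer, for which `grad F = 2 J' e`).
#'
#' The output-layer delta is `delta_k = y_k (1 - y_k) e_k` (derivative of
#' the logistic sigmoid times the output error); hidden deltas follow by the
#' chain rule.
#'
#' @param model An [mlp_init()] model.
#' @param x Input matrix (`n x input_dim`).
#' @param targets Target matrix (`n x output_dim`).
#' @param jacobian If `TRUE`, also return the
#'   `(n * output_dim) x n_weights` Jacobian (residuals ordered
#'   sample-fastest: all outputs of sample 1, then sample 2, ...).
#' @return List with `residuals` (vector `e`), `mse`, `grad_mse` (gradient
#'   of the MSE w.r.t. the flattened weights), and if requested `jacobian`.
#' @export
mlp_gradients <- function(model, x, targets, jacobian = FALSE) {
  stopifnot(inherits(model, "mlp_model"))
  x <- as_input_matrix(x, model$input_dim)
  targets <- as.matrix(targets)
  if (nrow(targets) != nrow(x) || ncol(targets) != model$output_dim) {
    stop("targets must be ", nrow(x), " x ", model$output_dim)
  }
  if (nrow(x) == 0) stop("batch must be non-empty")
  fw <- mlp_forward(model, x)
  y <- fw$output; hdn <- fw$hidden
  E <- targets - y                       # n x o
  go <- y * (1 - y)                      # sigmoid' at output
  gh <- hdn * (1 - hdn)                  # sigmoid' at hidden
  delta_o <- go * E                      # n x o (the classical output delta)
  delta_h <- (delta_o %*% model$W2) * gh # n x h

  n_out <- ncol(y)
  scale <- 2 / (nrow(x) * n_out)         # d(MSE)/d(SSE) handled here
  gW2 <- -scale * t(delta_o) %*% hdn
  gb2 <- -scale * colSums(delta_o)
  gW1 <- -scale * t(delta_h) %*% x
  gb1 <- -scale * colSums(delta_h)
  grad <- if (model$use_bias) {
    c(as.vector(gW1), gb1, as.vector(gW2), gb2)
  } else {
    c(as.vector(gW1), as.vector(gW2))
  }

  out <- list(residuals = as.vector(t(E)), mse = mean(E^2), grad_mse = grad,
              outputs = y)
  if (jacobian) {
    out$jacobian <- mlp_jacobian(model, x, fw)
  }
  out
}

# J[(p-1)*o + k, ] = d e_pk / d w, with e = t - y  (rows: sample-major)
mlp_jacobian <- function(model, x, fw) {
  n <- nrow(x); r <- model$input_dim
  h <- model$hidden_dim; o <- model$output_dim
  y <- fw$output; hdn <- fw$hidden
  go <- y * (1 - y); gh <- hdn * (1 - hdn)
  nw <- length(mlp_weights(model))
  J <- matrix(0, n * o, nw)
  off_W1 <- 0
  off_b1 <- h * r
  off_W2 <- off_b1 + if (model$use_bias) h else 0
  off_b2 <- off_W2 + o * h
  for (k in seq_len(o)) {
    rows <- (seq_len(n) - 1) * o + k
    gk <- go[, k]                               # n
    # output layer: d y_pk / d W2[k, j] = gk * hdn[p, j]
    colsW2 <- off_W2 + (seq_len(h) - 1) * o + k # column-major W2 (o x h)
    J[rows, colsW2] <- -gk * hdn
    if (model$use_bias) J[rows, off_b2 + k] <- -gk
    # hidden layer: d y_pk / d W1[j, i] = gk * W2[k, j] * gh[p, j] * x[p, i]
    back <- gk * sweep(gh, 2, model$W2[k, ], `*`) # n x h
    for (i in seq_len(r)) {
      colsW1 <- off_W1 + (i - 1) * h + seq_len(h)
      J[rows, colsW1] <- -(back * x[, i])
    }
    if (model$use_bias) J[rows, off_b1 + seq_len(h)] <- -back
  }
  J
}

#' Serialise / restore an MLP model as JSON
#'
#' @param model An [mlp_init()] model.
#' @param path File path.
#' @return `mlp_save_json()` returns `path` invisibly; `mlp_load_json()`
#'   returns the restored `mlp_model`.
#' @export
mlp_save_json <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  jsonlite::write_json(
    list(input_dim = model$input_dim, hidden_dim = model$hidden_dim,
         output_dim = model$output_dim, use_bias = model$use_bias,
         W1 = as.vector(t(model$W1)),  # row-major
         b1 = model$b1, W2 = as.vector(t(model$W2)), b2 = model$b2),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname mlp_save_json
#' @export
mlp_load_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- mlp_init(j$input_dim, j$hidden_dim, j$output_dim,
                use_bias = j$use_bias)
  m$W1 <- matrix(j$W1, nrow = j$hidden_dim, byrow = TRUE)
  m$b1 <- j$b1
  m$W2 <- matrix(j$W2, nrow = j$output_dim, byrow = TRUE)
  m$b2 <- j$b2
  m
}
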