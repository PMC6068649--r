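#' Robust local-regression smoothing of a PPG recording
#'
#' Conditions a raw PPG waveform with the classical robust local-regression
#' (LOESS-type) smoother: at every sample a weighted polynomial of degree
#' `degree` is fitted over a centred window spanning `span` of the record,
#' with tricube distance weights, and the fitted value at the centre replaces
#' the sample. Outliers are suppressed by `robust_iterations` rounds of
#' bisquare reweighting of scaled residuals. Windows are truncated at the
#' record boundaries (no padding).
#'
#' A plain centred moving average over the same window is available via
#' `method = "moving_average"` for comparison; the robust local regression is
#' the default and the one whose parameters (1% span, second-degree
#' polynomial) match the intended conditioning of 1 kHz PPG signals.
#'
#' Implementation note: on the regular sample grid the weighted least-squares
#' normal equations at every centre share the same offset abscissa, so all
#' running sums are computed as convolutions and the per-point degree-2
#' system is solved in closed form (Cramer), giving O(n * window) cost.
#'
#' @param recording A [ppg_recording()].
#' @param span Window length as a fraction of the record length (default
#'   0.01, i.e. 1%). The window must contain at least `degree + 2` samples.
#' @param degree Local polynomial degree, 1 or 2 (default 2).
#' @param robust_iterations Number of bisquare reweighting passes (default 5;
#'   0 gives plain weighted least squares).
#' @param method `"local_regression"` (default) or `"moving_average"`.
#' @return A [ppg_recording()] of the same length and metadata.
#' @examples
#' rec <- generate_recording(beat_template(), 3,
#'                           noise = noise_spec(noise_sd = 0.05, seed = 1))
#' sm <- smooth_ppg(rec$recording)
#' @export
smooth_ppg <- function(recording, span = 0.01, degree = 2,
                       robust_iterations = 5,
                       method = c("local_regression", "moving_average")) {
  stopifnot(inherits(recording, "ppg_recording"))
  method <- match.arg(method)
  if (!(span > 0 && span <= 1)) stop("span must be in (0, 1]")
  if (!degree %in% c(1, 2)) stop("degree must be 1 or 2")
  if (robust_iterations < 0) stop("robust_iterations must be >= 0")
  y <- recording$samples
  n <- length(y)
  q <- ceiling(span * n)
  if (q < degree + 2) {
    stop(sprintf(
      "span %.4g gives a %d-sample window; degree %d needs at least %d samples (span >= %.4g)",
      span, q, degree, degree + 2, (degree + 2) / n))
  }
  h <- max(1L, floor(q / 2))

  fit <- if (method == "moving_average") {
    local_poly_fit(y, h, degree = 0, robust_iterations = 0, uniform = TRUE)
  } else {
    local_poly_fit(y, h, degree = degree,
                   robust_iterations = robust_iterations)
  }
  new_recording_like(recording, fit)
}

# Convolution helper: for kernel g indexed by offsets -h..h returns
# z[j] = sum_delta g[delta] * x[j + delta] with zero truncation at edges.
conv_offsets <- function(x, g, h) {
  n <- length(x)
  xp <- c(numeric(h), x, numeric(h))
  z <- stats::filter(xp, rev(g), method = "convolution", sides = 2)
  as.numeric(z[(h + 1):(h + n)])
}

# Core fixed-window local polynomial smoother on a regular grid.
local_poly_fit <- function(y, h, degree, robust_iterations, uniform = FALSE) {
  n <- length(y)
  delta <- seq.int(-h, h)
  tw <- if (uniform) rep(1, 2 * h + 1) else (1 - (abs(delta) / (h + 1))^3)^3
  r <- rep(1, n)  # robustness weights per data point

  for (iter in seq_len(robust_iterations + 1)) {
    if (degree == 0) {
      S0 <- conv_offsets(r, tw, h)
      T0 <- conv_offsets(r * y, tw, h)
      fit <- T0 / S0
    } else {
      S <- lapply(0:(2 * degree), function(k) conv_offsets(r, tw * delta^k, h))
      Tm <- lapply(0:degree, function(k) conv_offsets(r * y, tw * delta^k, h))
      if (degree == 1) {
        det <- S[[1]] * S[[3]] - S[[2]]^2
        fit <- (Tm[[1]] * S[[3]] - S[[2]] * Tm[[2]]) / det
      } else {
        S0 <- S[[1]]; S1 <- S[[2]]; S2 <- S[[3]]; S3 <- S[[4]]; S4 <- S[[5]]
        T0 <- Tm[[1]]; T1 <- Tm[[2]]; T2 <- Tm[[3]]
        det <- S0 * (S2 * S4 - S3^2) - S1 * (S1 * S4 - S2 * S3) +
          S2 * (S1 * S3 - S2^2)
        det0 <- T0 * (S2 * S4 - S3^2) - T1 * (S1 * S4 - S2 * S3) +
          T2 * (S1 * S3 - S2^2)
        fit <- det0 / det
      }
    }
    if (iter > robust_iterations) break
    e <- y - fit
    s <- 6 * stats::median(abs(e))
    if (s <= 0 || !is.finite(s)) break
    r <- pmax(1 - (e / s)^2, 0)^2
  }
  fit
}

#' Remove offset and linear drift from a recording
#'
#' Subtracts the ordinary least-squares line (intercept + slope over time)
#' from the waveform, removing the constant offset and any linear baseline
#' drift. The result has zero mean and zero best-fit slope. A constant input
#' detrends to all zeros.
#'
#' @param recording A [ppg_recording()].
#' @return A [ppg_recording()] with the fitted line removed.
#' @examples
#' rec <- ppg_recording(1:100 * 0.01 + 3)
#' range(detrend_ppg(rec)$samples)  # ~0
#' @export
detrend_ppg <- function(recording) {
  stopifnot(inherits(recording, "ppg_recording"))
  t <- recording_times(recording)
  fit <- stats::lm.fit(cbind(1, t), recording$samples)
  new_recording_like(recording, unname(fit$residuals))
}
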