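#' Before-vs-after treatment t-test on a slope feature
#'
#' Tests whether a pulse-slope feature differs between the before- and
#' after-hemodialysis conditions. Two variants are provided:
#'
#' * `"paired"` (default): two-sided paired Student t-test on the per-subject
#'   differences `after - before` (df = n - 1). This is the variant that
#'   reproduces the reference cohort's tabulated p-values.
#' * `"welch"`: the unpaired statistic
#'   `t = (mean1 - mean2) / sqrt(S1^2/n1 + S2^2/n2)` with
#'   Welch-Satterthwaite degrees of freedom.
#'
#' The null hypothesis is rejected when `p < alpha` (strict inequality).
#'
#' @param before,after Numeric vectors of per-subject feature values; the
#'   paired variant requires equal lengths >= 2.
#' @param variant `"paired"` or `"welch"`.
#' @param alpha Significance level (default 0.05).
#' @param feature_name Optional label carried into the result.
#' @return An object of class `ppg_ttest`: list with `feature`, `variant`,
#'   `t_statistic`, `degrees_of_freedom`, `p_value`, `alpha`, `decision`
#'   (`"rejected"`/`"not_rejected"`).
#' @examples
#' slope_t_test(c(1, 2, 3, 4), c(2, 2.5, 3.6, 4.9))
#' @export
slope_t_test <- function(before, after, variant = c("paired", "welch"),
                         alpha = 0.05, feature_name = NA_character_) {
  variant <- match.arg(variant)
  if (variant == "paired") {
    if (length(before) != length(after)) {
      stop("paired variant requires equal-length before/after vectors")
    }
    if (length(before) < 2) stop("need at least 2 pairs")
    d <- after - before
    if (stats::sd(d) == 0) {
      stop("zero variance of the paired differences: t statistic undefined")
    }
    tt <- stats::t.test(after, before, paired = TRUE,
                        alternative = "two.sided")
  } else {
    if (length(before) < 2 || length(after) < 2) {
      stop("welch variant needs at least 2 values per group")
    }
    if (stats::sd(before) == 0 && stats::sd(after) == 0) {
      stop("zero variance in both groups: t statistic undefined")
    }
    tt <- stats::t.test(after, before, paired = FALSE, var.equal = FALSE,
                        alternative = "two.sided")
  }
  p <- unname(tt$p.value)
  structure(list(feature = feature_name, variant = variant,
                 t_statistic = unname(tt$statistic),
                 degrees_of_freedom = unname(tt$parameter),
                 p_value = p, alpha = alpha,
                 decision = if (p < alpha) "rejected" else "not_rejected"),
            class = "ppg_ttest")
}

#' @export
print.ppg_ttest <- function(x, ...) {
  cat(sprintf("<ppg_ttest> %s | %s | t = %.4f, df = %.2f, p = %.4f -> %s (alpha = %g)\n",
              if (is.na(x$feature)) "feature" else x$feature, x$variant,
              x$t_statistic, x$degrees_of_freedom, x$p_value, x$decision,
              x$alpha))
  invisible(x)
}

#' Select slope features by statistical significance
#'
#' Keeps the features whose before/after test rejected the null hypothesis.
#' If no feature is significant, all features are retained with a warning
#' (the classifier still needs an input).
#'
#' @param tests A list of [slope_t_test()] results, named by feature (or
#'   carrying `feature` fields).
#' @param alpha Significance level used for the decision (default 0.05,
#'   strict inequality).
#' @return Character vector of selected feature names.
#' @examples
#' tests <- list(
#'   rs = slope_t_test(c(1, 2, 3), c(2, 3.5, 4.2), feature_name = "rs"),
#'   fs = slope_t_test(c(1, 2, 3), c(1.5, 1.8, 3.4), feature_name = "fs"))
#' select_features(tests)
#' @export
select_features <- function(tests, alpha = 0.05) {
  if (!length(tests)) stop("at least one feature test is required")
  nms <- names(tests)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- vapply(tests, function(t) as.character(t$feature), character(1))
  }
  p <- vapply(tests, function(t) t$p_value, numeric(1))
  sel <- nms[p < alpha]
  if (!length(sel)) {
    warning("no feature significant at alpha = ", alpha,
            "; falling back to all features")
    sel <- nms
  }
  sel
}
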