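#' Per-subject slope summaries for a synthetic cohort
#'
#' Runs the signal path over every treated-hand recording of a cohort:
#' robust local-regression smoothing, detrending, landmark detection,
#' 12-beat selection and slope computation, then the mean/variance summary
#' per subject and phase.
#'
#' @param cohort A [generate_cohort()] result (with waveforms, unless
#'   `use_truth = TRUE`).
#' @param channel Hand to analyse (default `"left"`, the treated hand).
#' @param k Beats per recording to use (default 12).
#' @param smooth Apply [smooth_ppg()] before landmark detection.
#' @param span,degree,robust_iterations Smoother settings (see
#'   [smooth_ppg()]; the pipeline default of 2 robust passes is enough for
#'   the generator's Gaussian noise).
#' @param rescale_beats Min-max rescale beat slopes within each recording
#'   before summarising (off by default: per-recording rescaling erases the
#'   absolute slope level that carries the stenosis signal; see the methods
#'   vignette).
#' @param use_truth Summarise the generator's analytic per-beat slopes
#'   instead of re-measuring them from the waveform (fast path for
#'   statistical calibration studies; works on waveform-free cohorts).
#' @return Data frame: `subject_id`, `phase`, `rs_mean`, `rs_var`,
#'   `fs_mean`, `fs_var`, `n_beats`.
#' @export
cohort_slope_summaries <- function(cohort, channel = "left", k = 12,
                                   smooth = TRUE, span = 0.01, degree = 2,
                                   robust_iterations = 2,
                                   rescale_beats = FALSE,
                                   use_truth = FALSE) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  rows <- list()
  for (sid in cohort$patients$subject_id) {
    for (ph in c("before", "after")) {
      if (use_truth) {
        if (is.null(cohort$recordings)) {
          # waveform-free cohort: per-subject slope parameters only; emulate
          # beat-level sampling is unavailable, so variance is undefined here
          stop("use_truth on a waveform-free cohort is not supported; ",
               "summaries need per-beat values")
        }
        truth <- cohort$recordings[[paste(sid, channel, ph, sep = "_")]]$truth
        rs <- truth$rs_true[seq_len(k)]
        fs <- truth$fs_true[seq_len(k)]
      } else {
        rec <- cohort$recordings[[paste(sid, channel, ph, sep = "_")]]$recording
        if (smooth) {
          rec <- smooth_ppg(rec, span = span, degree = degree,
                            robust_iterations = robust_iterations)
        }
        rec <- detrend_ppg(rec)
        beats <- extract_beat_features(rec, k = k, rescale = rescale_beats)
        rs <- beats$rs
        fs <- beats$fs
      }
      rows[[paste(sid, ph)]] <- data.frame(
        subject_id = sid, phase = ph,
        rs_mean = mean(rs), rs_var = stats::var(rs),
        fs_mean = mean(fs), fs_var = stats::var(fs), n_beats = k,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classifier input matrix from slope summaries
#'
#' Builds the four-feature network input. The default layout uses the
#' selected slope feature's mean before, mean after, variance before and
#' variance after treatment; the alternative `"rs_fs"` layout uses the mean
#' and variance of both slopes in the after-treatment phase. Columns are
#' min-max rescaled to `[0, 1]` across the cohort.
#'
#' @param summaries Data frame from [cohort_slope_summaries()] (or any frame
#'   with the same columns).
#' @param feature `"rs"` or `"fs"` (ignored for layout `"rs_fs"`).
#' @param layout `"before_after"` (default) or `"rs_fs"`.
#' @param rescale Min-max rescale each column across subjects (default
#'   `TRUE`).
#' @return Numeric matrix, one row per subject (ordered as in `summaries`),
#'   with rownames set to the subject ids.
#' @export
feature_matrix <- function(summaries, feature = c("rs", "fs"),
                           layout = c("before_after", "rs_fs"),
                           rescale = TRUE) {
  feature <- match.arg(feature)
  layout <- match.arg(layout)
  before <- summaries[summaries$phase == "before", ]
  after <- summaries[summaries$phase == "after", ]
  stopifnot(identical(before$subject_id, after$subject_id))
  m <- if (layout == "before_after") {
    cbind(mean_before = before[[paste0(feature, "_mean")]],
          mean_after = after[[paste0(feature, "_mean")]],
          var_before = before[[paste0(feature, "_var")]],
          var_after = after[[paste0(feature, "_var")]])
  } else {
    cbind(rs_mean = after$rs_mean, rs_var = after$rs_var,
          fs_mean = after$fs_mean, fs_var = after$fs_var)
  }
  rownames(m) <- before$subject_id
  if (rescale) m <- apply(m, 2, rescale01)
  m
}

#' End-to-end stenosis-classification pipeline
#'
#' Orchestrates the full chain on a synthetic cohort: simulate, condition
#' the waveforms, extract and summarise pulse slopes, select the
#' discriminative slope feature by paired t-test, label classes from the
#' degree of stenosis, and evaluate one or more MLP training algorithms by
#' repeated stratified cross-validation. All stages derive their randomness
#' from `seed`; identical `(spec, seed)` give identical outputs.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed for the whole run.
#' @param algorithms Character vector of trainers to evaluate (subset of
#'   `"lm"`, `"scg"`, `"rprop"`, `"gd"`).
#' @param out_dir Optional directory; when given, the patient table,
#'   summaries, t-test report and metrics are written there as CSV/JSON.
#' @param k,repeats Cross-validation folds and repeats.
#' @param hidden_dim Hidden-layer size.
#' @param config_args Named list of extra [train_config()] arguments applied
#'   to every algorithm.
#' @param alpha Significance level of the feature-selection t-test.
#' @param ... Passed to [cohort_slope_summaries()] (smoother settings etc.).
#' @return List of class `ppg_pipeline_result`: `cohort`, `summaries`,
#'   `tests`, `selected`, `features`, `labels`, `reports` (one
#'   [cross_validate()] report per algorithm), `seed`.
#' @examples
#' \donttest{
#' res <- run_pipeline(cohort_spec(), seed = 7, algorithms = "lm",
#'                     repeats = 2)
#' res$reports$lm$metrics
#' }
#' @export
run_pipeline <- function(spec = cohort_spec(), seed = 1,
                         algorithms = c("lm", "scg", "rprop"),
                         out_dir = NULL, k = 5, repeats = 10,
                         hidden_dim = 35, config_args = list(),
                         alpha = 0.05, ...) {
  algorithms <- match.arg(algorithms, c("lm", "scg", "rprop", "gd"),
                          several.ok = TRUE)
  cohort <- generate_cohort(spec, seed = seed)
  summaries <- cohort_slope_summaries(cohort, ...)

  before <- summaries[summaries$phase == "before", ]
  after <- summaries[summaries$phase == "after", ]
  tests <- list(
    rs = slope_t_test(before$rs_mean, after$rs_mean, alpha = alpha,
                      feature_name = "rs"),
    fs = slope_t_test(before$fs_mean, after$fs_mean, alpha = alpha,
                      feature_name = "fs"))
  selected <- select_features(tests, alpha = alpha)
  main_feature <- if ("rs" %in% selected) "rs" else selected[1]

  labels <- dos_class(cohort$patients$dos)
  feats <- feature_matrix(summaries, feature = main_feature)

  reports <- list()
  for (alg in algorithms) {
    cfg <- do.call(train_config, c(list(algorithm = alg), config_args))
    reports[[alg]] <- cross_validate(feats, labels, cfg,
                                     hidden_dim = hidden_dim, k = k,
                                     repeats = repeats, seed = seed)
  }

  result <- structure(
    list(cohort = cohort, summaries = summaries, tests = tests,
         selected = selected, features = feats, labels = labels,
         reports = reports, seed = seed),
    class = "ppg_pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cbind(cohort$patients, class_assigned = labels),
                     file.path(out_dir, "patients.csv"), row.names = FALSE)
    utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, alpha = alpha, selected = selected,
           tests = lapply(tests, unclass)),
      file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(seed = seed,
           reports = lapply(reports, function(r) {
             list(algorithm = r$algorithm,
                  metrics = r$metrics,
                  epochs = as.list(r$epochs), mse = as.list(r$mse),
                  train_time_s = as.list(r$train_time_s),
                  test_time_s = as.list(r$test_time_s))
           })),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.ppg_pipeline_result <- function(x, ...) {
  cat(sprintf("<ppg_pipeline_result> seed %d | selected feature(s): %s\n",
              x$seed, paste(x$selected, collapse = ", ")))
  for (r in x$reports) print(r)
  invisible(x)
}
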