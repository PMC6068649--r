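#' Three-class confusion matrix
#'
#' `C[i, j]` counts samples whose actual class is `i` and predicted class is
#' `j`, for classes 1 (mild), 2 (moderate), 3 (severe).
#'
#' @param actual,predicted Equal-length integer vectors with values in
#'   `{1, 2, 3}`.
#' @return A 3x3 integer matrix with dimnames `actual` x `predicted`.
#' @examples
#' confusion_matrix3(c(1, 1, 2, 3), c(1, 2, 2, 3))
#' @export
confusion_matrix3 <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have equal length")
  }
  if (any(!actual %in% 1:3) || any(!predicted %in% 1:3)) {
    stop("labels must be in {1, 2, 3}")
  }
  cm <- matrix(0L, 3, 3,
               dimnames = list(actual = 1:3, predicted = 1:3))
  for (i in seq_along(actual)) {
    cm[actual[i], predicted[i]] <- cm[actual[i], predicted[i]] + 1L
  }
  cm
}

#' Micro-aggregated confusion counts
#'
#' Sums the per-class true/false positives/negatives of a 3-class confusion
#' matrix into single counts:
#' `TP = C11 + C22 + C33`; `FP` sums each class's off-diagonal column mass;
#' `FN` sums each class's off-diagonal row mass; `TN` sums, for each class,
#' everything outside its row and column. Algebraic identities of this
#' aggregation (asserted internally): `FP = FN = N - TP` and `TN = N + TP`,
#' where `N` is the total sample count.
#'
#' @param cm A 3x3 confusion matrix from [confusion_matrix3()].
#' @return List with `TP`, `FP`, `FN`, `TN`, `N`.
#' @export
aggregate_counts <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(all(dim(cm) == c(3, 3)), all(cm >= 0))
  TP <- cm[1, 1] + cm[2, 2] + cm[3, 3]
  FP <- (cm[2, 1] + cm[3, 1]) + (cm[1, 2] + cm[3, 2]) + (cm[1, 3] + cm[2, 3])
  FN <- (cm[1, 2] + cm[1, 3]) + (cm[2, 1] + cm[2, 3]) + (cm[3, 1] + cm[3, 2])
  TN <- (cm[2, 2] + cm[2, 3] + cm[3, 2] + cm[3, 3]) +
        (cm[1, 1] + cm[1, 3] + cm[3, 1] + cm[3, 3]) +
        (cm[1, 1] + cm[1, 2] + cm[2, 1] + cm[2, 2])
  N <- sum(cm)
  stopifnot(isTRUE(all.equal(FP, FN)), isTRUE(all.equal(TN, N + TP)),
            isTRUE(all.equal(TP + FN, N)))
  list(TP = TP, FP = FP, FN = FN, TN = TN, N = N)
}

#' Classification metrics from micro-aggregated counts
#'
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `REC = TP/(TP+FN)` (sensitivity),
#' `SPE = TN/(TN+FP)` (specificity), `PPV = TP/(TP+FP)` (precision) and
#' `GM = sqrt(REC * SPE)`, all in percent. Under the three-class
#' micro-aggregation `REC = PPV`, `ACC = (1 + 2 REC)/3` and
#' `SPE = (1 + REC)/2` (rates as fractions). A zero denominator yields `NA`
#' with a warning, never a silent 0.
#'
#' @param counts List with `TP`, `FP`, `FN`, `TN` (from
#'   [aggregate_counts()], or constructed directly).
#' @return Named numeric vector `ACC`, `REC`, `SPE`, `PPV`, `GM` in percent.
#' @examples
#' classification_metrics(list(TP = 10, FP = 1, FN = 1, TN = 21))
#' @export
classification_metrics <- function(counts) {
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NA_real_)
    }
    num / den
  }
  with(counts, {
    acc <- safe_div(TP + TN, TP + TN + FP + FN, "ACC")
    rec <- safe_div(TP, TP + FN, "REC")
    spe <- safe_div(TN, TN + FP, "SPE")
    ppv <- safe_div(TP, TP + FP, "PPV")
    gm <- sqrt(rec * spe)
    c(ACC = acc, REC = rec, SPE = spe, PPV = ppv, GM = gm) * 100
  })
}

#' Repeated stratified k-fold cross-validation of the MLP classifier
#'
#' Per repeat: shuffle within class, deal the samples into `k` folds
#' preserving class proportions as far as integer counts allow, train on
#' k-1 folds, predict each held-out fold by the arg-max of the three network
#' outputs (ties to the lower class index), pool the predictions of all
#' folds into one confusion matrix, and micro-aggregate. Metrics are
#' reported as mean and (n-1)-denominator SD over the repeats. Very small
#' classes may be absent from some folds; pooling makes that benign.
#'
#' @param x Feature matrix (`n x input_dim`), typically the four slope
#'   summary features rescaled to `[0, 1]`.
#' @param labels Integer class labels in `{1, 2, 3}`, length `n`.
#' @param config A [train_config()].
#' @param hidden_dim Hidden-layer size (default 35).
#' @param k Number of folds (default 5); must not exceed `n`.
#' @param repeats Number of repeated shuffles (default 10).
#' @param seed Integer seed; fold shuffles and weight initialisations derive
#'   from it deterministically.
#' @param train_fun,predict_fun Optional classifier override for harness
#'   testing: `train_fun(x, y_onehot, fold_seed)` returns a fitted object,
#'   `predict_fun(fit, x)` returns class labels. Defaults train an MLP via
#'   [train_mlp()].
#' @return An object of class `cv_report`: list with `metrics` (data frame:
#'   mean and sd per metric, percent), `per_repeat` (matrix of per-repeat
#'   metrics), `confusions` (list of pooled 3x3 matrices), `epochs`, `mse`,
#'   `train_time_s`, `test_time_s` (mean and sd each), plus the settings.
#' @export
cross_validate <- function(x, labels, config = train_config(),
                           hidden_dim = 35, k = 5, repeats = 10, seed = 1,
                           train_fun = NULL, predict_fun = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels must match rows of x")
  if (any(!labels %in% 1:3)) stop("labels must be in {1, 2, 3}")
  if (k > n) stop("k = ", k, " exceeds the number of samples (", n, ")")
  if (k < 2) stop("k must be >= 2")

  if (is.null(train_fun) != is.null(predict_fun)) {
    stop("supply both train_fun and predict_fun, or neither")
  }
  use_mlp <- is.null(train_fun)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, repeats)

  per_repeat <- matrix(NA_real_, repeats, 5,
                       dimnames = list(NULL, c("ACC", "REC", "SPE", "PPV", "GM")))
  confusions <- vector("list", repeats)
  epochs <- tr_time <- te_time <- mse <- numeric(repeats)

  for (rr in seq_len(repeats)) {
    set.seed(rep_seeds[rr])
    fold <- integer(n)
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(sample(k), length(idx))
    }
    pred <- integer(n)
    ep_f <- tr_f <- te_f <- ms_f <- numeric(0)
    for (f in sort(unique(fold))) {
      test_idx <- which(fold == f)
      train_idx <- setdiff(seq_len(n), test_idx)
      y_tr <- class_one_hot(labels[train_idx])
      fold_seed <- (rep_seeds[rr] + f) %% (.Machine$integer.max - 1L)
      if (use_mlp) {
        model <- mlp_init(ncol(x), hidden_dim, 3, seed = fold_seed)
        fit <- train_mlp(model, x[train_idx, , drop = FALSE], y_tr, config)
        t0 <- proc.time()[["elapsed"]]
        pred[test_idx] <- predict(fit$model, x[test_idx, , drop = FALSE],
                                  type = "class")
        te_f <- c(te_f, proc.time()[["elapsed"]] - t0)
        ep_f <- c(ep_f, fit$epochs)
        tr_f <- c(tr_f, fit$train_time_s)
        ms_f <- c(ms_f, fit$final_mse)
      } else {
        fit <- train_fun(x[train_idx, , drop = FALSE], y_tr, fold_seed)
        pred[test_idx] <- predict_fun(fit, x[test_idx, , drop = FALSE])
      }
    }
    cm <- confusion_matrix3(labels, pred)
    confusions[[rr]] <- cm
    per_repeat[rr, ] <- classification_metrics(aggregate_counts(cm))
    if (use_mlp) {
      epochs[rr] <- mean(ep_f); tr_time[rr] <- sum(tr_f)
      te_time[rr] <- sum(te_f); mse[rr] <- mean(ms_f)
    }
  }

  metrics <- data.frame(
    metric = colnames(per_repeat),
    mean = colMeans(per_repeat),
    sd = apply(per_repeat, 2, stats::sd),
    row.names = NULL)
  structure(list(metrics = metrics, per_repeat = per_repeat,
                 confusions = confusions,
                 epochs = c(mean = mean(epochs), sd = stats::sd(epochs)),
                 mse = c(mean = mean(mse), sd = stats::sd(mse)),
                 train_time_s = c(mean = mean(tr_time), sd = stats::sd(tr_time)),
                 test_time_s = c(mean = mean(te_time), sd = stats::sd(te_time)),
                 algorithm = config$algorithm, k = k, repeats = repeats,
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s | %d-fold x %d repeats\n", x$algorithm, x$k,
              x$repeats))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-3s %7.3f (+/- %.3f) %%\n", m$metric[i], m$mean[i],
                m$sd[i]))
  }
  cat(sprintf("  epochs %.2f (+/- %.2f) | MSE %.4g | train %.3fs | test %.4fs\n",
              x$epochs[["mean"]], x$epochs[["sd"]], x$mse[["mean"]],
              x$train_time_s[["mean"]], x$test_time_s[["mean"]]))
  invisible(x)
}
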