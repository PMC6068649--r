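#' Detect alternating valley/peak landmarks in a PPG waveform
#'
#' Finds systolic peaks as local maxima passing a prominence threshold and a
#' minimum inter-peak distance, then places a valley (pulse foot) at the
#' minimum between consecutive peaks, before the first peak and after the
#' last one. The result is a strictly alternating valley, peak, valley, ...
#' sequence in which every peak is the maximum between its flanking valleys.
#'
#' @param recording A [ppg_recording()], normally smoothed/detrended first.
#' @param min_distance Minimum time between accepted peaks in seconds
#'   (default 0.4 s, i.e. at most 150 beats/min).
#' @param min_prominence Minimum topographic prominence of an accepted peak
#'   in amplitude units; default (`NULL`) is 10% of the signal's
#'   inter-quartile range.
#' @return A data frame with columns `type` (`"valley"`/`"peak"`), `index`
#'   (1-based sample index), `time` (s) and `value` (a.u.), ordered in time.
#'   If no peak qualifies an empty data frame is returned with a warning.
#' @examples
#' g <- generate_recording(beat_template(), 5)
#' lm <- detect_peaks_valleys(g$recording)
#' subset(lm, type == "peak")$time
#' @export
detect_peaks_valleys <- function(recording, min_distance = 0.4,
                                 min_prominence = NULL) {
  stopifnot(inherits(recording, "ppg_recording"))
  y <- recording$samples
  n <- length(y)
  if (is.null(min_prominence)) {
    min_prominence <- 0.1 * stats::IQR(y)
  }

  cand <- local_maxima(y)
  if (length(cand)) {
    prom <- peak_prominence(y, cand)
    keep <- prom >= min_prominence
    cand <- cand[keep]
    prom <- prom[keep]
  }
  if (length(cand)) {
    min_sep <- min_distance * recording$rate
    ord <- order(-prom, cand)       # strongest first, earlier on ties
    accepted <- integer(0)
    for (i in cand[ord]) {
      if (!length(accepted) || all(abs(accepted - i) >= min_sep)) {
        accepted <- c(accepted, i)
      }
    }
    cand <- sort(accepted)
  }
  if (!length(cand)) {
    warning("no peaks found; returning empty landmark set")
    return(data.frame(type = character(0), index = integer(0),
                      time = numeric(0), value = numeric(0)))
  }

  # valleys: minimum before the first peak, between peaks, after the last
  bounds <- c(1L, cand, n)
  valleys <- integer(length(cand) + 1)
  for (j in seq_along(valleys)) {
    lo <- bounds[j]; hi <- bounds[j + 1]
    seg <- lo:hi
    valleys[j] <- seg[which.min(y[seg])]
  }
  # re-anchor each peak at the maximum between its flanking valleys so the
  # alternation contract holds even for shoulder-type candidates
  for (j in seq_along(cand)) {
    seg <- valleys[j]:valleys[j + 1]
    cand[j] <- seg[which.max(y[seg])]
  }

  idx <- integer(2 * length(cand) + 1)
  idx[seq(1, length(idx), by = 2)] <- valleys
  idx[seq(2, length(idx), by = 2)] <- cand
  type <- rep(c("valley", "peak"), length.out = length(idx))
  data.frame(type = type, index = idx,
             time = (idx - 1) / recording$rate, value = y[idx])
}

# indices of strict local maxima (first sample of a plateau counts)
local_maxima <- function(y) {
  dy <- diff(y)
  s <- sign(dy)
  # carry last non-zero slope sign through plateaus
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  s_filled <- s
  last <- 0
  for (i in seq_along(s)) {
    if (s[i] != 0) last <- s[i] else s_filled[i] <- last
  }
  which(diff(s_filled) < 0 & s_filled[-length(s_filled)] > 0) + 1L
}

# topographic prominence of peaks at indices pk (sorted) in y
peak_prominence <- function(y, pk) {
  vapply(pk, function(i) {
    v <- y[i]
    left <- y[seq_len(i - 1)]
    higher_l <- which(left > v)
    base_l <- if (length(higher_l)) min(left[(max(higher_l) + 1):(i - 1)])
              else if (length(left)) min(left) else v
    right <- if (i < length(y)) y[(i + 1):length(y)] else numeric(0)
    higher_r <- which(right > v)
    base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1)])
              else if (length(right)) min(right) else v
    v - max(base_l, base_r)
  }, numeric(1))
}

#' Select the first k complete beats from a landmark sequence
#'
#' A complete beat is a (valley, peak, valley) triplet; consecutive beats
#' share their middle valleys. The standard analysis window used throughout
#' this package is the first 12 beats of a recording.
#'
#' @param landmarks Landmark data frame from [detect_peaks_valleys()].
#' @param k Number of beats to keep (default 12).
#' @return A data frame with one row per beat: `beat_index`, `t_n`, `t_pn`,
#'   `t_n1` (s), `v_n`, `v_p`, `v_n1` (a.u.).
#' @export
select_beats <- function(landmarks, k = 12) {
  pk <- which(landmarks$type == "peak")
  n_beats <- sum(pk > 1 & pk < nrow(landmarks))
  if (n_beats < k) {
    stop("only ", n_beats, " complete beats available, need ", k,
         " (", n_beats, " < ", k, ")")
  }
  pk <- pk[pk > 1 & pk < nrow(landmarks)][seq_len(k)]
  data.frame(
    beat_index = seq_len(k),
    t_n = landmarks$time[pk - 1],
    t_pn = landmarks$time[pk],
    t_n1 = landmarks$time[pk + 1],
    v_n = landmarks$value[pk - 1],
    v_p = landmarks$value[pk],
    v_n1 = landmarks$value[pk + 1])
}

#' Pulse rising slope
#'
#' `RS = (V_p - V_n) / (T_pn - T_n)`: amplitude gained from the pulse foot
#' to the systolic peak per unit time (a.u./s). Invariant under amplitude
#' offsets and time shifts.
#'
#' @param v_p,v_n Peak and foot values (a.u.).
#' @param t_pn,t_n Peak and foot times (s); `t_pn` must exceed `t_n`.
#' @return Rising slope in a.u./s (vectorised).
#' @examples
#' rising_slope(1, 0, 0.1, 0)  # 10
#' @export
rising_slope <- function(v_p, v_n, t_pn, t_n) {
  if (any(t_pn <= t_n)) {
    stop("t_pn must be strictly greater than t_n (zero/negative rise interval)")
  }
  (v_p - v_n) / (t_pn - t_n)
}

#' Pulse falling slope
#'
#' `FS = (V_{n+1} - V_p) / (T_{n+1} - T_pn)` is algebraically negative on a
#' descending limb; by the reporting convention used throughout this package
#' the magnitude is returned (all tabulated falling slopes are positive).
#' Set `signed = TRUE` for the raw signed value.
#'
#' @param v_n1,v_p Next-foot and peak values (a.u.).
#' @param t_n1,t_pn Next-foot and peak times (s); `t_n1` must exceed `t_pn`.
#' @param signed Return the signed slope instead of its magnitude.
#' @return Falling slope in a.u./s (vectorised).
#' @examples
#' falling_slope(0, 1, 0.2, 0)                 # 5
#' falling_slope(0, 1, 0.2, 0, signed = TRUE)  # -5
#' @export
falling_slope <- function(v_n1, v_p, t_n1, t_pn, signed = FALSE) {
  if (any(t_n1 <= t_pn)) {
    stop("t_n1 must be strictly greater than t_pn (zero/negative fall interval)")
  }
  fs <- (v_n1 - v_p) / (t_n1 - t_pn)
  if (signed) fs else abs(fs)
}

#' Min-max rescaling to the unit interval
#'
#' Affinely maps values so that `lower` goes to 0 and `upper` goes to 1:
#' `(x - min) / (max - min)`.
#'
#' @param x Numeric values.
#' @param lower,upper Range endpoints; default the range of `x`. Must differ.
#' @return Rescaled values.
#' @examples
#' rescale01(c(2, 4, 6))
#' @export
rescale01 <- function(x, lower = min(x), upper = max(x)) {
  if (upper <= lower) {
    stop("degenerate range: max must exceed min for rescaling")
  }
  (x - lower) / (upper - lower)
}

#' Mean/variance summary of a slope feature
#'
#' Summarises a set of per-beat feature values with the sample mean and the
#' n-1-denominator sample variance.
#'
#' @param values Numeric vector, length >= 2.
#' @param phase `"before"` or `"after"` treatment.
#' @param feature_name `"rs"` or `"fs"`.
#' @return A one-row data frame: `feature`, `phase`, `mean`, `variance`, `n`.
#' @examples
#' summarize_feature(c(1, 3), "before", "rs")  # variance (1-3)^2/2 = 2
#' @export
summarize_feature <- function(values, phase = c("before", "after"),
                              feature_name = c("rs", "fs")) {
  phase <- match.arg(phase)
  feature_name <- match.arg(feature_name)
  if (length(values) < 2) {
    stop("need at least 2 values for a mean/variance summary, got ",
         length(values))
  }
  data.frame(feature = feature_name, phase = phase,
             mean = mean(values), variance = stats::var(values),
             n = length(values))
}

#' Extract per-beat slope features from a recording
#'
#' Convenience wrapper: detect landmarks, select the first `k` beats and
#' compute rising/falling slopes per beat. Raises if any selected beat has a
#' non-positive rising or falling slope (landmark mis-ordering).
#'
#' @param recording A [ppg_recording()] (smooth/detrend first for noisy data).
#' @param k Number of beats (default 12).
#' @param rescale If `TRUE`, min-max rescale the RS and FS columns (each
#'   against its own range within this recording) after computing them.
#' @param ... Passed to [detect_peaks_valleys()].
#' @return Data frame: beat landmark columns from [select_beats()] plus
#'   `rs`, `fs` and `fs_signed` (a.u./s).
#' @export
extract_beat_features <- function(recording, k = 12, rescale = FALSE, ...) {
  landmarks <- detect_peaks_valleys(recording, ...)
  beats <- select_beats(landmarks, k = k)
  beats$rs <- rising_slope(beats$v_p, beats$v_n, beats$t_pn, beats$t_n)
  beats$fs_signed <- falling_slope(beats$v_n1, beats$v_p, beats$t_n1,
                                   beats$t_pn, signed = TRUE)
  beats$fs <- abs(beats$fs_signed)
  if (any(beats$rs <= 0) || any(beats$fs <= 0)) {
    stop("non-positive slope in selected beats: landmark mis-ordering ",
         "(peak not above both flanking valleys)")
  }
  if (rescale) {
    beats$rs <- rescale01(beats$rs)
    beats$fs <- rescale01(beats$fs)
  }
  beats
}
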