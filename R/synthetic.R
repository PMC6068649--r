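#' Beat template for the synthetic PPG generator
#'
#' Describes one idealised pulse: a half-cosine upstroke from the foot
#' (valley) to the systolic peak over `rise_time` seconds, followed by an
#' exponential-like decay back to the foot level over the remainder of the
#' period. The template is deliberately simple so that every beat landmark
#' (foot, peak, next foot) and hence the true rising/falling slopes have
#' closed forms: `RS = amplitude / rise_time` and
#' `FS = amplitude / (period - rise_time)` (slopes are landmark differences,
#' so they do not depend on the interior shape).
#'
#' @param period Beat period in seconds (> 0).
#' @param rise_time Foot-to-peak interval in seconds, `0 < rise_time < period`.
#' @param amplitude Peak amplitude above the foot, arbitrary units (> 0).
#' @param fall_shape Unitless decay-rate parameter of the falling limb
#'   (larger = faster initial decay); must be > 0.
#' @return An object of class `beat_template`.
#' @examples
#' beat_template(period = 0.8, rise_time = 0.12)
#' @export
beat_template <- function(period = 0.8, rise_time = 0.12, amplitude = 1,
                          fall_shape = 3) {
  if (!(period > 0)) stop("period must be > 0")
  if (!(rise_time > 0 && rise_time < period)) {
    stop("invalid template: rise_time must satisfy 0 < rise_time < period (got ",
         rise_time, " vs period ", period, ")")
  }
  if (!(amplitude > 0)) stop("amplitude must be > 0")
  if (!(fall_shape > 0)) stop("fall_shape must be > 0")
  structure(list(period = period, rise_time = rise_time,
                 amplitude = amplitude, fall_shape = fall_shape),
            class = "beat_template")
}

#' Noise and baseline-artefact specification
#'
#' Controls the nuisance components added on top of the noiseless pulse
#' train: a sinusoidal baseline drift, a constant offset, white measurement
#' noise, and a per-beat multiplicative amplitude jitter (beat-to-beat
#' physiological variability). Ground-truth landmarks are always computed
#' before offset/drift/noise are added; amplitude jitter is part of the truth
#' (it changes the beat itself, not the measurement).
#'
#' @param drift_amplitude Amplitude of the sinusoidal baseline drift (a.u.).
#' @param drift_period Period of the drift in seconds (> 0).
#' @param offset Constant baseline offset (a.u.).
#' @param noise_sd Standard deviation of additive white noise (a.u., >= 0).
#' @param amplitude_jitter SD of the lognormal per-beat amplitude factor
#'   (>= 0; 0.03 means beats vary by ~3%).
#' @param seed Optional integer seed making the stochastic components
#'   reproducible; `NULL` uses the current RNG state.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(drift_amplitude = 0, drift_period = 10, offset = 0,
                       noise_sd = 0, amplitude_jitter = 0, seed = NULL) {
  if (!(drift_period > 0)) stop("drift_period must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (amplitude_jitter < 0) stop("amplitude_jitter must be >= 0")
  structure(list(drift_amplitude = drift_amplitude,
                 drift_period = drift_period, offset = offset,
                 noise_sd = noise_sd, amplitude_jitter = amplitude_jitter,
                 seed = seed),
            class = "noise_spec")
}

# Evaluate the noiseless template at times t (seconds), with per-beat
# amplitudes amps (length >= number of beats spanned by t).
template_waveform <- function(template, t, amps) {
  beat <- pmin(floor(t / template$period) + 1L, length(amps))
  u <- t - (beat - 1L) * template$period
  a <- amps[beat]
  y <- numeric(length(t))
  rising <- u < template$rise_time
  y[rising] <- a[rising] / 2 *
    (1 - cos(pi * u[rising] / template$rise_time))
  s <- template$fall_shape
  fall_len <- template$period - template$rise_time
  v <- (u[!rising] - template$rise_time) / fall_len
  y[!rising] <- a[!rising] * (exp(-s * v) - exp(-s)) / (1 - exp(-s))
  y
}

#' Generate one synthetic PPG recording with ground truth
#'
#' Synthesises `n_beats` pulses from a [beat_template()], applies the
#' artefacts in a [noise_spec()], and returns both the recording and the
#' analytic ground truth: the true landmark times/values of every beat and
#' the true per-beat rising/falling slopes, computed from the noiseless
#' template (before offset, drift and additive noise).
#'
#' @param template A [beat_template()].
#' @param n_beats Number of beats to generate (>= 1).
#' @param rate Sampling rate in Hz (default 1000).
#' @param noise A [noise_spec()].
#' @param channel,phase,subject_id Metadata passed to [ppg_recording()].
#' @return A list with elements:
#'   \describe{
#'     \item{recording}{the [ppg_recording()] (noise applied);}
#'     \item{truth}{a data frame with one row per beat: `beat_index`, `t_n`,
#'       `t_pn`, `t_n1` (foot, peak, next-foot times in s), `v_n`, `v_p`,
#'       `v_n1` (values, a.u., pre-offset), `rs_true`, `fs_true` (a.u./s).}
#'   }
#' @examples
#' g <- generate_recording(beat_template(), n_beats = 3)
#' g$truth$rs_true
#' @export
generate_recording <- function(template, n_beats, rate = 1000,
                               noise = noise_spec(),
                               channel = "left", phase = "before",
                               subject_id = "synthetic") {
  stopifnot(inherits(template, "beat_template"), inherits(noise, "noise_spec"))
  if (!(n_beats >= 1)) stop("n_beats must be >= 1")
  if (!(rate > 0)) stop("rate must be > 0")

  if (!is.null(noise$seed)) set.seed(noise$seed)
  # draw beat jitter before measurement noise so the truth does not depend
  # on noise_sd
  # lognormal so beat amplitudes stay positive at any jitter level
  amps <- template$amplitude *
    exp(stats::rnorm(n_beats, 0, noise$amplitude_jitter))

  n <- round(n_beats * template$period * rate) + 1L
  t <- (seq_len(n) - 1L) / rate
  clean <- template_waveform(template, t, amps)
  samples <- clean + noise$offset +
    noise$drift_amplitude * sin(2 * pi * t / noise$drift_period) +
    stats::rnorm(n, 0, noise$noise_sd)

  b <- seq_len(n_beats)
  truth <- data.frame(
    beat_index = b,
    t_n = (b - 1) * template$period,
    t_pn = (b - 1) * template$period + template$rise_time,
    t_n1 = b * template$period,
    v_n = 0,
    v_p = amps,
    v_n1 = 0,
    rs_true = amps / template$rise_time,
    fs_true = amps / (template$period - template$rise_time)
  )

  list(recording = ppg_recording(samples, rate = rate, channel = channel,
                                 phase = phase, subject_id = subject_id),
       truth = truth)
}

#' Cohort specification for the synthetic generator
#'
#' Defines a cohort with known three-class stenosis structure. Each subject
#' draws a degree of stenosis (DOS) uniformly inside its class's range, and
#' the DOS is mapped to pulse morphology: the before-treatment rising slope
#' decreases linearly with DOS (`rs_base * (1 - dos_coupling * DOS/100)`,
#' stiffer/stenosed access = slower upstroke), and hemodialysis increases the
#' rising slope by a DOS-proportional fraction (`after_effect * DOS/100`),
#' matching the direction observed clinically (after-treatment slopes exceed
#' before-treatment ones, more so in stenosed patients). Lognormal
#' between-subject variation and Gaussian within-subject (before/after pair)
#' variation are superimposed. Vessel diameters consistent with each DOS are
#' also drawn so the labelling stage can be exercised end to end.
#'
#' The default class ranges mirror the reference 11-patient cohort: its DOS
#' values occupy roughly 14-29% (mild), 34-49% (moderate) and 70-95%
#' (severe), with gaps at the 30% and 50% partition boundaries.
#'
#' @param n_per_class Integer vector of length 3: subjects per class
#'   (default `c(5, 4, 2)`, the reference cohort's distribution).
#' @param dos_ranges List of 3 numeric ranges (percent) to draw DOS from.
#' @param rs_base Rising slope (a.u./s) of a healthy (DOS = 0) subject.
#' @param dos_coupling Fractional RS reduction at DOS = 100%.
#' @param after_effect Fractional RS increase after treatment at DOS = 100%
#'   (scaled by DOS/100; set 0 for a null, no-effect cohort).
#' @param subject_sd Lognormal SD of between-subject RS variation.
#' @param pair_sd SD of the relative within-subject before/after perturbation.
#' @param jitter_base,jitter_coupling Beat-to-beat relative amplitude
#'   variability: a subject at degree-of-stenosis DOS gets
#'   `jitter_base * (1 + jitter_coupling * DOS/100)` (stenotic access shows
#'   larger beat-to-beat slope variability, which is what makes the
#'   variance summary features informative).
#' @param segments_per_subject Recording segments per subject (default 2).
#'   Each segment yields its own before/after recording pair and its own
#'   evaluation vector, so a cohort of `n` patients contributes
#'   `n * segments_per_subject` samples - mirroring reference analyses in
#'   which the evaluated sample count exceeds the patient count because
#'   several signal segments are taken per patient.
#' @param segment_sd Lognormal SD of the segment-level slope perturbation.
#' @param beats_per_recording Beats synthesised per recording (>= 12 so the
#'   standard 12-beat analysis window is available).
#' @param period Beat period in seconds.
#' @param noise A [noise_spec()] applied to every recording (its `seed` and
#'   `amplitude_jitter` are ignored; seeding and jitter are controlled by
#'   [generate_cohort()]).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = c(5, 4, 2),
                        dos_ranges = list(c(18, 26), c(38, 46), c(72, 88)),
                        rs_base = 5, dos_coupling = 0.6, after_effect = 0.2,
                        subject_sd = 0.02, pair_sd = 0.02,
                        jitter_base = 0.02, jitter_coupling = 4,
                        segments_per_subject = 2, segment_sd = 0.015,
                        beats_per_recording = 15, period = 0.8,
                        noise = noise_spec(drift_amplitude = 0.1,
                                           drift_period = 12, offset = 0.5,
                                           noise_sd = 0.02)) {
  n_per_class <- as.integer(n_per_class)
  if (length(n_per_class) != 3 || any(n_per_class < 0)) {
    stop("n_per_class must be 3 non-negative integers")
  }
  if (all(n_per_class == 0)) stop("cohort must contain at least one subject")
  if (length(dos_ranges) != 3) stop("dos_ranges must list 3 ranges")
  bounds <- list(c(0, 30), c(30, 50), c(50, 100))
  for (k in 1:3) {
    r <- dos_ranges[[k]]
    if (length(r) != 2 || r[1] > r[2]) stop("dos_ranges[[", k, "]] invalid")
    if (n_per_class[k] > 0 &&
        (r[1] < bounds[[k]][1] || r[2] > bounds[[k]][2])) {
      stop("dos_ranges[[", k, "]] leaves the class-", k, " partition ",
           "[", bounds[[k]][1], ", ", bounds[[k]][2], "]")
    }
  }
  if (beats_per_recording < 12) {
    stop("beats_per_recording must be >= 12 (the analysis window)")
  }
  if (jitter_base < 0 || jitter_coupling < 0) {
    stop("jitter_base and jitter_coupling must be >= 0")
  }
  if (!(segments_per_subject >= 1)) stop("segments_per_subject must be >= 1")
  structure(list(n_per_class = n_per_class, dos_ranges = dos_ranges,
                 rs_base = rs_base, dos_coupling = dos_coupling,
                 after_effect = after_effect, subject_sd = subject_sd,
                 pair_sd = pair_sd, jitter_base = jitter_base,
                 jitter_coupling = jitter_coupling,
                 segments_per_subject = as.integer(segments_per_subject),
                 segment_sd = segment_sd,
                 beats_per_recording = beats_per_recording,
                 period = period, noise = noise),
            class = "cohort_spec")
}

#' Generate a synthetic dual-PPG cohort
#'
#' Draws a cohort under a [cohort_spec()]: per subject a DOS, vessel
#' diameters, and four recordings (left = treated hand and right = untreated
#' hand, each before and after treatment). The untreated hand receives no
#' treatment effect. Subject-level parameters are drawn first from the base
#' seed, then each recording gets an independent derived seed, so the
#' subject-level ground truth is identical whether or not waveforms are
#' materialised.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   `(spec, seed)`.
#' @param waveforms If `FALSE`, skip waveform synthesis and return only the
#'   patient table and ground-truth slope parameters (fast; used for
#'   statistical calibration studies).
#' @return A list of class `ppg_cohort`:
#'   \describe{
#'     \item{patients}{data frame with one row per evaluation sample
#'       (patient x segment): `subject_id` (sample id), `patient_id`,
#'       `segment`, `class`, `dos`, `D`, `d`, `hd_hand`, `rs_before_true`,
#'       `rs_after_true` (treated-hand true mean rising slopes, a.u./s);}
#'     \item{recordings}{(if `waveforms`) named list of
#'       [generate_recording()] results, names
#'       `<subject>_<channel>_<phase>`;}
#'     \item{spec, seed}{the inputs.}
#'   }
#' @examples
#' coh <- generate_cohort(cohort_spec(), seed = 1, waveforms = FALSE)
#' table(coh$patients$class)
#' @export
generate_cohort <- function(spec, seed, waveforms = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- as.integer(seed)
  set.seed(seed)

  n_pat <- sum(spec$n_per_class)
  pat_cls <- rep(1:3, times = spec$n_per_class)
  pat_ids <- sprintf("P%02d", seq_len(n_pat))

  pat_dos <- numeric(n_pat)
  for (k in 1:3) {
    sel <- pat_cls == k
    pat_dos[sel] <- stats::runif(sum(sel), spec$dos_ranges[[k]][1],
                                 spec$dos_ranges[[k]][2])
  }
  pat_D <- stats::runif(n_pat, 0.7, 1.7)
  pat_d <- pat_D * sqrt(1 - pat_dos / 100)
  subj_scale <- exp(stats::rnorm(n_pat, 0, spec$subject_sd))
  pat_rs <- spec$rs_base * (1 - spec$dos_coupling * pat_dos / 100) * subj_scale

  # expand patients into recording segments (one evaluation vector each)
  n_seg <- spec$segments_per_subject
  n_tot <- n_pat * n_seg
  pi <- rep(seq_len(n_pat), each = n_seg)
  ids <- if (n_seg == 1) pat_ids else
    sprintf("%ss%d", pat_ids[pi], rep(seq_len(n_seg), n_pat))
  cls <- pat_cls[pi]
  dos <- pat_dos[pi]

  rs_before <- pat_rs[pi] * exp(stats::rnorm(n_tot, 0, spec$segment_sd))
  pair_noise <- stats::rnorm(n_tot, 0, spec$pair_sd)
  rs_after <- rs_before * (1 + spec$after_effect * dos / 100 + pair_noise)
  if (any(rs_before <= 0) || any(rs_after <= 0)) {
    stop("cohort_spec parameters produced a non-positive rising slope")
  }
  # untreated (right) hand: no treatment effect, independent pair noise
  rs_right_before <- rs_before
  rs_right_after <- rs_before * (1 + stats::rnorm(n_tot, 0, spec$pair_sd))

  rec_seeds <- matrix(sample.int(.Machine$integer.max - 1L, n_tot * 4L),
                      nrow = n_tot)

  patients <- data.frame(
    subject_id = ids, patient_id = pat_ids[pi],
    segment = rep(seq_len(n_seg), n_pat),
    class = cls, dos = dos, D = pat_D[pi], d = pat_d[pi],
    hd_hand = "left", rs_before_true = rs_before, rs_after_true = rs_after,
    stringsAsFactors = FALSE)

  out <- list(patients = patients, spec = spec, seed = seed)

  if (waveforms) {
    recs <- list()
    combos <- expand.grid(phase = c("before", "after"),
                          channel = c("left", "right"),
                          stringsAsFactors = FALSE)
    for (i in seq_len(n_tot)) {
      rs_tab <- c(left_before = rs_before[i], left_after = rs_after[i],
                  right_before = rs_right_before[i],
                  right_after = rs_right_after[i])
      for (j in seq_len(nrow(combos))) {
        ch <- combos$channel[j]; ph <- combos$phase[j]
        rs <- rs_tab[[paste(ch, ph, sep = "_")]]
        tmpl <- beat_template(period = spec$period,
                              rise_time = 1 / rs,  # amplitude 1 => rise = 1/RS
                              amplitude = 1)
        ns <- spec$noise
        ns$amplitude_jitter <- spec$jitter_base *
          (1 + spec$jitter_coupling * dos[i] / 100)
        ns$seed <- rec_seeds[i, j]
        key <- paste(ids[i], ch, ph, sep = "_")
        recs[[key]] <- generate_recording(
          tmpl, n_beats = spec$beats_per_recording, rate = 1000, noise = ns,
          channel = ch, phase = ph, subject_id = ids[i])
      }
    }
    out$recordings <- recs
  }
  class(out) <- "ppg_cohort"
  out
}

#' @export
print.ppg_cohort <- function(x, ...) {
  cat(sprintf("<ppg_cohort> %d subjects (classes: %s) | seed %d | %s\n",
              nrow(x$patients),
              paste(tabulate(x$patients$class, 3), collapse = "/"),
              x$seed,
              if (is.null(x$recordings)) "no waveforms"
              else paste(length(x$recordings), "recordings")))
  invisible(x)
}

#' Write cohort ground truth to CSV
#'
#' @param truth A ground-truth data frame from [generate_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
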