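#' PPG recording object
#'
#' A `ppg_recording` holds one sampled photoplethysmography waveform together
#' with its acquisition metadata: sampling rate, hand (channel), hemodialysis
#' phase and subject identifier.
#'
#' @param samples Numeric vector of waveform amplitudes (arbitrary units).
#'   Must be finite and of length >= 2.
#' @param rate Sampling rate in Hz (default 1000, the acquisition rate of the
#'   dual-PPG measurement node this package targets).
#' @param channel Which hand the probe was on: `"left"` or `"right"`.
#' @param phase Hemodialysis phase: `"before"` or `"after"` treatment.
#' @param subject_id Opaque subject identifier string.
#'
#' @return An object of class `ppg_recording`: a list with elements
#'   `samples`, `rate`, `channel`, `phase`, `subject_id`.
#' @examples
#' rec <- ppg_recording(sin(seq(0, 4 * pi, length.out = 2000)), rate = 1000)
#' rec
#' @export
ppg_recording <- function(samples, rate = 1000,
                          channel = c("left", "right"),
                          phase = c("before", "after"),
                          subject_id = "anonymous") {
  channel <- match.arg(channel)
  phase <- match.arg(phase)
  samples <- as.numeric(samples)
  if (length(samples) < 2) {
    stop("a ppg_recording needs at least 2 samples, got ", length(samples))
  }
  if (!all(is.finite(samples))) {
    stop("ppg_recording samples must be finite (no NA/NaN/Inf)")
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("sampling rate must be a single positive number")
  }
  structure(
    list(samples = samples, rate = rate, channel = channel,
         phase = phase, subject_id = as.character(subject_id)),
    class = "ppg_recording"
  )
}

#' @export
print.ppg_recording <- function(x, ...) {
  dur <- (length(x$samples) - 1) / x$rate
  cat(sprintf(
    "<ppg_recording> subject %s | %s hand | %s HD | %d samples @ %g Hz (%.2f s)\n",
    x$subject_id, x$channel, x$phase, length(x$samples), x$rate, dur))
  invisible(x)
}

#' @export
length.ppg_recording <- function(x) length(x$samples)

#' Sample times of a recording
#'
#' @param recording A [ppg_recording()].
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
recording_times <- function(recording) {
  stopifnot(inherits(recording, "ppg_recording"))
  (seq_along(recording$samples) - 1) / recording$rate
}

new_recording_like <- function(recording, samples) {
  ppg_recording(samples, rate = recording$rate, channel = recording$channel,
                phase = recording$phase, subject_id = recording$subject_id)
}

#' Write / read a recording as two-column CSV
#'
#' The on-disk dialect is a two-column CSV (`time_s`, `amplitude`) preceded by
#' a single comment header line `# rate=<Hz> channel=<c> phase=<p> subject=<id>`
#' carrying the metadata.
#'
#' @param recording A [ppg_recording()].
#' @param path File path to write to / read from.
#' @return `write_recording_csv()` returns `path` invisibly;
#'   `read_recording_csv()` returns a [ppg_recording()].
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "ppg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate=%g channel=%s phase=%s subject=%s",
                     recording$rate, recording$channel, recording$phase,
                     recording$subject_id), con)
  utils::write.csv(
    data.frame(time_s = recording_times(recording),
               amplitude = recording$samples),
    con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "# ")) {
    stop("missing metadata header line in ", path)
  }
  fields <- strsplit(sub("^# ", "", header), " ")[[1]]
  kv <- do.call(rbind, strsplit(fields, "=", fixed = TRUE))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  df <- utils::read.csv(path, skip = 1)
  ppg_recording(df$amplitude, rate = as.numeric(meta[["rate"]]),
                channel = meta[["channel"]], phase = meta[["phase"]],
                subject_id = meta[["subject"]])
}
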