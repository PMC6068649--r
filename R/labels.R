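#' Degree of stenosis from vessel diameters
#'
#' `DOS% = (1 - d^2 / D^2) * 100`, where `d` is the stenotic lesion diameter
#' and `D` the normal vessel diameter (any single consistent unit; only the
#' ratio matters). 0% is a fully open vessel, 100% total occlusion.
#'
#' @param d Lesion diameter(s), `0 <= d <= D`.
#' @param D Normal vessel diameter(s), `> 0`.
#' @return DOS in percent, in `[0, 100]` (vectorised).
#' @examples
#' dos_percent(0.94, 1.04)  # 18.31
#' @export
dos_percent <- function(d, D) {
  if (any(D <= 0)) stop("normal diameter D must be > 0")
  if (any(d < 0) || any(d > D)) {
    stop("lesion diameter d must satisfy 0 <= d <= D")
  }
  (1 - d^2 / D^2) * 100
}

#' Three-class stenosis partition
#'
#' Maps a DOS percentage to severity class 1 (mild, DOS <= 30%), 2
#' (moderate, 30% < DOS <= 50%) or 3 (severe, DOS > 50%). The published
#' partition is ambiguous at exactly 30% and 50% (both neighbouring classes
#' are written with closed bounds); this implementation uses the half-open
#' convention `[0, 30], (30, 50], (50, 100]`, so DOS = 30 is class 1 and
#' DOS = 50 is class 2. No reference patient sits on a boundary.
#'
#' @param dos DOS in percent, in `[0, 100]` (vectorised).
#' @return Integer class labels in `{1, 2, 3}`.
#' @examples
#' dos_class(c(18.31, 44.3, 94.5))
#' @export
dos_class <- function(dos) {
  if (any(dos < 0) || any(dos > 100)) stop("DOS must be within [0, 100]")
  ifelse(dos <= 30, 1L, ifelse(dos <= 50, 2L, 3L))
}

#' One-hot class targets
#'
#' Encodes class labels 1..3 as the network target rows `[1 0 0]`,
#' `[0 1 0]`, `[0 0 1]`.
#'
#' @param class_label Integer labels in `{1, 2, 3}`.
#' @return A `length(class_label) x 3` 0/1 matrix.
#' @export
class_one_hot <- function(class_label) {
  if (any(!class_label %in% 1:3)) stop("class labels must be in {1, 2, 3}")
  m <- matrix(0, nrow = length(class_label), ncol = 3)
  m[cbind(seq_along(class_label), class_label)] <- 1
  m
}

#' Label a patient table with DOS and severity class
#'
#' Computes the DOS from the diameter columns, assigns the three-class
#' partition and one-hot targets, and (if a `dos_printed` column is present)
#' flags rows whose tabulated DOS disagrees with the recomputed one beyond
#' `tolerance` - typically because the tabulated diameters were rounded
#' after the original DOS was computed. Flagged rows are reported via a
#' message, never treated as errors.
#'
#' @param patients Data frame with columns `D` and `d` (and optionally
#'   `subject_id`, `dos_printed`).
#' @param tolerance Allowed |recomputed - tabulated| before flagging
#'   (default 0.005, i.e. agreement at 2 decimals).
#' @return The input data frame with added columns `dos`, `class`,
#'   `dos_mismatch` (logical, `NA` when no `dos_printed` column exists) and
#'   attribute `one_hot` (the target matrix).
#' @examples
#' label_patients(hd_patient_table())
#' @export
label_patients <- function(patients, tolerance = 0.005) {
  stopifnot(all(c("D", "d") %in% names(patients)))
  patients$dos <- dos_percent(patients$d, patients$D)
  patients$class <- dos_class(patients$dos)
  if ("dos_printed" %in% names(patients)) {
    patients$dos_mismatch <-
      abs(patients$dos - patients$dos_printed) > tolerance
    if (any(patients$dos_mismatch)) {
      ids <- if ("subject_id" %in% names(patients)) {
        patients$subject_id[patients$dos_mismatch]
      } else which(patients$dos_mismatch)
      message("DOS recomputed from diameters disagrees with the tabulated ",
              "value (rounded diameters?) for: ", paste(ids, collapse = ", "))
    }
  } else {
    patients$dos_mismatch <- NA
  }
  attr(patients, "one_hot") <- class_one_hot(patients$class)
  patients
}

#' Bundled 11-patient hemodialysis reference cohort
#'
#' The clinical reference tables shipped with the package:
#' `hd_patient_table()` returns the cohort's vessel diameters (`D` normal,
#' `d` lesion, one consistent unit), tabulated DOS, age, gender and treated
#' hand; `hd_slope_table()` returns the per-patient mean rising/falling
#' slopes of the treated hand before and after a hemodialysis session (long
#' format: `subject_id`, `feature` in `rs`/`fs`, `phase` in
#' `before`/`after`, `value`).
#'
#' @return A data frame (see above).
#' @examples
#' mean(hd_patient_table()$age)
#' @export
hd_patient_table <- function() {
  utils::read.csv(system.file("extdata", "hd_patients.csv",
                              package = "ppgstenosis"),
                  stringsAsFactors = FALSE)
}

#' @rdname hd_patient_table
#' @export
hd_slope_table <- function() {
  utils::read.csv(system.file("extdata", "hd_slopes.csv",
                              package = "ppgstenosis"),
                  stringsAsFactors = FALSE)
}
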