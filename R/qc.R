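#' Motion exclusion by mean RMS displacement
#'
#' Flags subjects whose average root-mean-square scanner movement exceeds
#' the cutoff (strictly greater than; the default 1.7 mm is one voxel of
#' the study acquisition, so a subject at exactly the cutoff is retained).
#' Retained subjects carry their RMS value forward as the `movement`
#' nuisance covariate of the ROI models.
#'
#' @param summaries data.frame with columns `subject_id` and
#'   `mean_rms_mm` (finite, non-negative).
#' @param threshold_mm exclusion cutoff in millimeters.
#' @return list with `retained` and `excluded` data.frames (each with an
#'   `excluded` logical column); the two partitions are disjoint and
#'   exhaustive.
#' @export
apply_motion_exclusion <- function(summaries, threshold_mm = 1.7) {
  stopifnot(is.data.frame(summaries),
            all(c("subject_id", "mean_rms_mm") %in% names(summaries)))
  rms <- summaries$mean_rms_mm
  if (any(!is.finite(rms)) || any(rms < 0)) {
    stop("mean_rms_mm must be finite and non-negative")
  }
  if (!is.finite(threshold_mm) || threshold_mm < 0) {
    stop("threshold_mm must be finite and non-negative")
  }
  summaries$excluded <- rms > threshold_mm
  list(retained = summaries[!summaries$excluded, , drop = FALSE],
       excluded = summaries[summaries$excluded, , drop = FALSE])
}
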