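#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname maskVolume
#' @export
setMethod("maskVolume", "ROIMask", function(x) {
  mm3ToL(sum(x@mask) * voxelVolume(x@spacing))
})

#' Lesion-to-liver volume ratio
#'
#' The pipeline's biomarker: the fraction of the liver occupied by
#' hypoattenuating lesion tissue. A lesion volume exceeding the liver volume
#' is an error, not a clamp — it signals a segmentation defect upstream.
#'
#' @param lesionVolume lesion volume, L.
#' @param liverVolume liver volume, L (> 0).
#' @return \code{lesionVolume / liverVolume}, in \code{[0, 1]}. Tabular
#'   output conventionally rounds this to 4 decimals.
#' @examples
#' computeRatio(1.650, 2.335)  # 0.7066 at 4 decimals
#' @export
computeRatio <- function(lesionVolume, liverVolume) {
  if (!is.finite(liverVolume) || liverVolume <= 0)
    stop(sprintf("liver volume must be positive, got %g L", liverVolume))
  if (!is.finite(lesionVolume) || lesionVolume < 0)
    stop(sprintf("lesion volume must be non-negative, got %g L",
                 lesionVolume))
  if (lesionVolume > liverVolume)
    stop(sprintf(
      "lesion volume (%.3f L) exceeds liver volume (%.3f L): segmentation defect",
      lesionVolume, liverVolume))
  lesionVolume / liverVolume
}

#' Build a per-patient volumetry report
#'
#' @param patientId patient label.
#' @param liverMask,lesionMask \linkS4class{ROIMask}s sharing a grid; the
#'   lesion mask must be a subset of the liver mask.
#' @param thresholds optional named numeric record of the HU bounds used
#'   (as returned by \code{\link{segmentLesion}}).
#' @return a \linkS4class{VolumeReport}.
#' @export
buildReport <- function(patientId, liverMask, lesionMask,
                        thresholds = numeric(0)) {
  stopifnot(is(liverMask, "ROIMask"), is(lesionMask, "ROIMask"))
  if (!identical(dim(liverMask@mask), dim(lesionMask@mask)))
    stop("liver and lesion masks have different grid shapes")
  if (!identical(liverMask@spacing, lesionMask@spacing))
    stop("liver and lesion masks have different voxel spacing")
  if (any(lesionMask@mask & !liverMask@mask))
    stop("lesion mask is not a subset of the liver mask")
  liverL <- maskVolume(liverMask)
  lesionL <- maskVolume(lesionMask)
  new("VolumeReport", patientId = as.character(patientId),
      liverVolume = liverL, lesionVolume = lesionL,
      ratio = computeRatio(lesionL, liverL),
      thresholds = thresholds)
}

#' Volume report as a cohort-table row
#'
#' Renders a report with the tabular rounding convention: volumes to 3
#' decimals (L), ratio to 4 decimals. Internal computation keeps full
#' precision; only this rendering rounds.
#'
#' @param report a \linkS4class{VolumeReport}.
#' @param digitsVolume,digitsRatio decimals for volumes and ratio.
#' @return one-row \code{data.frame} with columns \code{patient_id},
#'   \code{roi_liver_L}, \code{roi_lesion_L}, \code{ratio}.
#' @export
reportRow <- function(report, digitsVolume = 3, digitsRatio = 4) {
  stopifnot(is(report, "VolumeReport"))
  data.frame(patient_id = report@patientId,
             roi_liver_L = round(report@liverVolume, digitsVolume),
             roi_lesion_L = round(report@lesionVolume, digitsVolume),
             ratio = round(report@ratio, digitsRatio),
             stringsAsFactors = FALSE)
}

#' Append a volume report to a cohort table on disk
#'
#' The cohort table is the CSV exchange format consumed by the statistics
#' layer: one row per patient with \code{patient_id}, \code{roi_liver_L},
#' \code{roi_lesion_L}, \code{ratio} (plus any clinical columns added
#' elsewhere).
#'
#' @param report a \linkS4class{VolumeReport}.
#' @param path CSV path; created with a header if absent.
#' @return \code{path}, invisibly.
#' @export
appendReport <- function(report, path) {
  row <- reportRow(report)
  if (file.exists(path)) {
    existing <- utils::read.csv(path, stringsAsFactors = FALSE)
    utils::write.csv(rbind(existing[names(row)], row), path,
                     row.names = FALSE)
  } else {
    utils::write.csv(row, path, row.names = FALSE)
  }
  invisible(path)
}
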