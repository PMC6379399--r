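#' @include AllGenerics.R
NULL

## Central S4 data model: CT volumes, ROI masks, seeds and HU intervals.
## All grids are 3D arrays in (i, j, k) index order after canonical
## reorientation at load time; indices are 1-based inside R (plain-text seed
## files use the 0-based convention of the imaging tools, converted on read).

.maskRoles <- c("liver", "low_density", "enhancement", "lesion")

#' CT volume in Hounsfield units
#'
#' A 3D scalar grid of CT attenuation values (Hounsfield units, HU: water 0,
#' air -1000) with physical voxel spacing. Volumes read from NIfTI are
#' reoriented to the closest canonical (RAS) axis order so that voxel indices
#' are unambiguous; any rescale slope/intercept declared in the header is
#' applied, and values are kept as floating point thereafter (diffusion
#' output is non-integer).
#'
#' @slot data 3D numeric array, HU.
#' @slot spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @slot origin numeric length-3, physical position of the first voxel (mm).
#' @slot axisOrder single string tagging the anatomical axis convention
#'   (\code{"RAS"} after canonical reorientation).
#' @export
setClass("CTVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 axisOrder = "character"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), axisOrder = "RAS"))

setValidity("CTVolume", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, sprintf("data must be a 3D array, got %d dimension(s)",
                          length(dim(object@data))))
  if (length(object@spacing) != 3L)
    msg <- c(msg, "spacing must have length 3")
  else if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
    msg <- c(msg, sprintf("spacing must be strictly positive, got (%s)",
                          paste(format(object@spacing), collapse = ", ")))
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have length 3")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "data contains non-finite values (NaN/Inf)")
  if (length(object@axisOrder) != 1L)
    msg <- c(msg, "axisOrder must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a CTVolume
#'
#' @param data 3D numeric array of HU values.
#' @param spacing per-axis voxel size in mm (length 3, all positive).
#' @param origin physical position of the first voxel in mm.
#' @param axisOrder anatomical axis convention tag.
#' @return a \linkS4class{CTVolume}.
#' @examples
#' vol <- CTVolume(array(0, c(8, 8, 4)), spacing = c(0.7, 0.7, 5))
#' voxelSpacing(vol)
#' @export
CTVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     axisOrder = "RAS") {
  new("CTVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), axisOrder = axisOrder)
}

#' Region-of-interest mask
#'
#' A boolean voxel grid aligned to a parent \linkS4class{CTVolume}, tagged
#' with the anatomical role it plays in the pipeline: the liver, the
#' hypoattenuating (low-density) tissue, the enhancing parenchyma, or the
#' derived lesion region.
#'
#' @slot mask 3D logical array, same shape as the parent volume.
#' @slot role one of \code{"liver"}, \code{"low_density"},
#'   \code{"enhancement"}, \code{"lesion"}.
#' @slot spacing voxel spacing inherited from the parent volume (mm).
#' @export
setClass("ROIMask",
  representation(mask = "array", role = "character", spacing = "numeric"),
  prototype(role = "liver", spacing = c(1, 1, 1)))

setValidity("ROIMask", function(object) {
  msg <- character(0)
  if (length(dim(object@mask)) != 3L)
    msg <- c(msg, "mask must be a 3D array")
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be logical")
  if (anyNA(object@mask))
    msg <- c(msg, "mask contains NA")
  if (length(object@role) != 1L || !object@role %in% .maskRoles)
    msg <- c(msg, sprintf("role must be one of %s",
                          paste(.maskRoles, collapse = ", ")))
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be length 3 and strictly positive")
  if (length(msg)) msg else TRUE
})

#' Construct an ROIMask
#'
#' @param mask 3D logical array.
#' @param role anatomical role tag (see \linkS4class{ROIMask}).
#' @param spacing voxel spacing in mm, or a \linkS4class{CTVolume} to
#'   inherit shape/spacing checks from.
#' @param parent optional parent \linkS4class{CTVolume}; when given, the
#'   mask shape must match the parent grid and spacing is taken from it.
#' @return an \linkS4class{ROIMask}.
#' @export
ROIMask <- function(mask, role, spacing = c(1, 1, 1), parent = NULL) {
  if (!is.null(parent)) {
    stopifnot(is(parent, "CTVolume"))
    if (!identical(dim(mask), dim(parent@data)))
      stop(sprintf("mask shape (%s) does not match parent volume shape (%s)",
                   paste(dim(mask), collapse = "x"),
                   paste(dim(parent@data), collapse = "x")))
    spacing <- parent@spacing
  }
  storage.mode(mask) <- "logical"
  new("ROIMask", mask = mask, role = role, spacing = as.numeric(spacing))
}

#' Seed voxels for region growing
#'
#' Seed points are 1-based voxel index triples inside the grid of the volume
#' they annotate. An optional bounding scribble (an approximate manual
#' delineation of the organ) can restrict where growth is allowed.
#'
#' @slot points integer matrix, one \code{(i, j, k)} triple per row.
#' @slot bounding an \linkS4class{ROIMask} or \code{NULL}.
#' @export
setClass("SeedSet",
  representation(points = "matrix", bounding = "ANY"),
  prototype(bounding = NULL))

setValidity("SeedSet", function(object) {
  msg <- character(0)
  if (ncol(object@points) != 3L)
    msg <- c(msg, "points must have 3 columns (i, j, k)")
  if (nrow(object@points) > 0 &&
      (anyNA(object@points) || any(object@points < 1)))
    msg <- c(msg, "seed indices must be >= 1 (1-based) and non-missing")
  if (!is.null(object@bounding) && !is(object@bounding, "ROIMask"))
    msg <- c(msg, "bounding must be NULL or an ROIMask")
  if (length(msg)) msg else TRUE
})

#' Construct a SeedSet
#'
#' @param points matrix (or length-3 vector) of 1-based voxel index triples.
#' @param bounding optional \linkS4class{ROIMask} bounding scribble.
#' @return a \linkS4class{SeedSet}.
#' @examples
#' SeedSet(c(5, 5, 3))
#' @export
SeedSet <- function(points, bounding = NULL) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  storage.mode(points) <- "integer"
  dimnames(points) <- NULL
  new("SeedSet", points = points, bounding = bounding)
}

#' Hounsfield-unit threshold interval
#'
#' An inclusive HU interval \code{[lo, hi]} driving region growing, tagged
#' with the tissue role whose scribble it was estimated from. Both ends are
#' closed, so touching low-density/enhancement intervals yield a well-defined
#' lesion interval.
#'
#' @slot lo lower bound, HU.
#' @slot hi upper bound, HU (\code{lo <= hi}).
#' @slot sourceRole role tag of the scribble the interval derives from.
#' @export
setClass("ThresholdInterval",
  representation(lo = "numeric", hi = "numeric", sourceRole = "character"))

setValidity("ThresholdInterval", function(object) {
  msg <- character(0)
  if (length(object@lo) != 1L || length(object@hi) != 1L ||
      !is.finite(object@lo) || !is.finite(object@hi))
    msg <- c(msg, "lo and hi must be single finite numbers")
  else if (object@lo > object@hi)
    msg <- c(msg, sprintf("lo (%g) must not exceed hi (%g)",
                          object@lo, object@hi))
  if (length(object@sourceRole) != 1L ||
      !object@sourceRole %in% .maskRoles)
    msg <- c(msg, sprintf("sourceRole must be one of %s",
                          paste(.maskRoles, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a ThresholdInterval
#'
#' @param lo,hi inclusive interval bounds in HU.
#' @param sourceRole tissue role the interval was estimated from.
#' @return a \linkS4class{ThresholdInterval}.
#' @examples
#' ThresholdInterval(40, 90, "low_density")
#' @export
ThresholdInterval <- function(lo, hi, sourceRole) {
  new("ThresholdInterval", lo = as.numeric(lo), hi = as.numeric(hi),
      sourceRole = sourceRole)
}

#' Per-patient volumetry report
#'
#' The row type of the cohort table: liver volume, lesion volume (litres),
#' their ratio, and the HU threshold bounds (a, b = low-density interval,
#' c, d = enhancement interval) the segmentation used.
#'
#' @slot patientId patient label.
#' @slot liverVolume liver volume, L (> 0).
#' @slot lesionVolume lesion volume, L (between 0 and \code{liverVolume}).
#' @slot ratio \code{lesionVolume / liverVolume}, dimensionless in [0, 1].
#' @slot thresholds named numeric record of the HU bounds used
#'   (\code{a, b, c, d, lesion_lo, lesion_hi}); may be empty when volumes
#'   were supplied directly.
#' @export
setClass("VolumeReport",
  representation(patientId = "character", liverVolume = "numeric",
                 lesionVolume = "numeric", ratio = "numeric",
                 thresholds = "numeric"),
  prototype(thresholds = numeric(0)))

setValidity("VolumeReport", function(object) {
  msg <- character(0)
  if (!(length(object@liverVolume) == 1L && object@liverVolume > 0))
    msg <- c(msg, "liverVolume must be a single positive number")
  if (!(length(object@lesionVolume) == 1L && object@lesionVolume >= 0))
    msg <- c(msg, "lesionVolume must be a single non-negative number")
  else if (length(object@liverVolume) == 1L &&
           object@lesionVolume > object@liverVolume)
    msg <- c(msg, sprintf(
      "lesionVolume (%.3f L) exceeds liverVolume (%.3f L): segmentation defect",
      object@lesionVolume, object@liverVolume))
  if (length(object@ratio) == 1L && length(object@liverVolume) == 1L &&
      length(object@lesionVolume) == 1L &&
      abs(object@ratio - object@lesionVolume / object@liverVolume) > 1e-12)
    msg <- c(msg, "ratio must equal lesionVolume / liverVolume")
  if (length(msg)) msg else TRUE
})

## --- accessors -------------------------------------------------------------

#' @rdname voxelData
#' @export
setMethod("voxelData", "CTVolume", function(x) x@data)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ROIMask", function(x) x@spacing)

#' @rdname maskArray
#' @export
setMethod("maskArray", "ROIMask", function(x) x@mask)

#' @rdname maskRole
#' @export
setMethod("maskRole", "ROIMask", function(x) x@role)

#' @rdname seedPoints
#' @export
setMethod("seedPoints", "SeedSet", function(x) x@points)

#' Interval bounds as a numeric vector
#'
#' @param x a \linkS4class{ThresholdInterval}.
#' @return named numeric \code{c(lo =, hi =)}.
#' @export
intervalBounds <- function(x) {
  stopifnot(is(x, "ThresholdInterval"))
  c(lo = x@lo, hi = x@hi)
}

## --- show methods ----------------------------------------------------------

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("CTVolume %dx%dx%d voxels, spacing (%s) mm [%s]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, trim = TRUE), collapse = ", "),
              object@axisOrder))
  cat(sprintf("  HU range [%.1f, %.1f], extent (%s) mm\n",
              min(object@data), max(object@data),
              paste(format(d * object@spacing, trim = TRUE), collapse = ", ")))
})

setMethod("show", "ROIMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("ROIMask <%s> %dx%dx%d voxels, %d set, spacing (%s) mm\n",
              object@role, d[1], d[2], d[3], sum(object@mask),
              paste(format(object@spacing, trim = TRUE), collapse = ", ")))
})

setMethod("show", "SeedSet", function(object) {
  cat(sprintf("SeedSet with %d seed(s)%s\n", nrow(object@points),
              if (is.null(object@bounding)) "" else ", bounded"))
})

setMethod("show", "ThresholdInterval", function(object) {
  cat(sprintf("ThresholdInterval [%g, %g] HU (from %s)\n",
              object@lo, object@hi, object@sourceRole))
})

setMethod("show", "VolumeReport", function(object) {
  cat(sprintf("VolumeReport %s: liver %.3f L, lesion %.3f L, Ratio %.4f\n",
              object@patientId, object@liverVolume, object@lesionVolume,
              object@ratio))
  if (length(object@thresholds))
    cat("  thresholds:",
        paste(sprintf("%s=%g", names(object@thresholds), object@thresholds),
              collapse = " "), "\n")
})
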