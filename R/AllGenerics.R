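#' Voxel data of a CT volume
#'
#' @param x a \linkS4class{CTVolume}.
#' @return the 3D numeric array of Hounsfield units.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Voxel spacing in millimetres
#'
#' @param x a \linkS4class{CTVolume} or \linkS4class{ROIMask}.
#' @return numeric length-3 vector of per-axis voxel size (mm).
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Logical voxel array of a mask
#'
#' @param x an \linkS4class{ROIMask}.
#' @return 3D logical array.
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' Anatomical role of a mask
#'
#' @param x an \linkS4class{ROIMask}.
#' @return one of \code{"liver"}, \code{"low_density"}, \code{"enhancement"},
#'   \code{"lesion"}.
#' @export
setGeneric("maskRole", function(x) standardGeneric("maskRole"))

#' Seed voxel coordinates
#'
#' @param x a \linkS4class{SeedSet}.
#' @return integer matrix with one 1-based \code{(i, j, k)} voxel index per
#'   row.
#' @export
setGeneric("seedPoints", function(x) standardGeneric("seedPoints"))

#' Physical volume of a mask in litres
#'
#' Counts the set voxels, multiplies by the voxel volume
#' (\code{\link{voxelVolume}}, mm^3) and converts to litres
#' (\code{1 L = 1e6 mm^3}). Voxels are treated as filled cells; there is no
#' partial-volume modelling.
#'
#' @param x an \linkS4class{ROIMask}.
#' @return volume in litres.
#' @examples
#' m <- ROIMask(array(c(rep(TRUE, 1000), rep(FALSE, 24 * 1000 - 1000)),
#'                    dim = c(10, 10, 240)),
#'              role = "liver", spacing = c(1, 1, 1))
#' maskVolume(m)  # 0.001 L
#' @export
setGeneric("maskVolume", function(x) standardGeneric("maskVolume"))
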