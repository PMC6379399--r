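#' @include AllClasses.R
NULL

#' Read a CT volume from NIfTI
#'
#' Reads a 3D NIfTI-1 file, applies any rescale slope/intercept declared in
#' the header so the returned grid is in calibrated Hounsfield units, and
#' reorients the grid to the closest canonical (RAS) axis order so that
#' voxel indices are unambiguous across files.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file with 3D scalar
#'   data.
#' @param reorient reorient to canonical RAS axis order (default TRUE).
#' @return a \linkS4class{CTVolume}.
#' @seealso \code{\link{writeVolume}}
#' @export
readVolume <- function(path, reorient = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  if (reorient) {
    ort <- try(RNifti::orientation(img), silent = TRUE)
    if (!inherits(ort, "try-error") && !identical(ort, "RAS"))
      RNifti::orientation(img) <- "RAS"
  }
  hdr <- RNifti::niftiHeader(img)
  dat <- array(as.numeric(img), dim = dim(img))
  if (length(dim(dat)) == 4L && dim(dat)[4] == 1L)
    dat <- array(dat, dim(dat)[1:3])
  if (length(dim(dat)) != 3L)
    stop(sprintf("expected 3D data in %s, got %d dimension(s)",
                 path, length(dim(dat))))
  slope <- hdr$scl_slope
  inter <- hdr$scl_inter
  if (is.finite(slope) && slope != 0 && slope != 1)
    dat <- dat * slope + inter
  else if (is.finite(inter) && (!is.finite(slope) || slope %in% c(0, 1)) &&
           inter != 0)
    dat <- dat + inter
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop(sprintf("non-positive voxel spacing (%s) in header of %s",
                 paste(format(sp), collapse = ", "), path))
  if (any(!is.finite(dat)))
    stop(sprintf("volume %s contains non-finite values after rescale", path))
  orig <- hdr[c("qoffset_x", "qoffset_y", "qoffset_z")]
  orig <- vapply(orig, function(v) if (is.finite(v)) v else 0, numeric(1))
  CTVolume(dat, spacing = sp, origin = unname(orig),
           axisOrder = if (reorient) "RAS" else "native")
}

#' Write a CT volume to NIfTI
#'
#' HU values are stored as 32-bit float; no rescale slope is introduced, so
#' a round trip through \code{\link{readVolume}} reproduces the grid to
#' single precision and the spacing exactly.
#'
#' @param vol a \linkS4class{CTVolume}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "CTVolume"))
  img <- RNifti::asNifti(vol@data)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read an ROI mask from NIfTI
#'
#' Masks are stored as \code{{0, 1}} integer grids; any nonzero voxel is
#' treated as set. The mask must match its parent volume's grid shape.
#'
#' @param path path to the mask file.
#' @param parent the \linkS4class{CTVolume} the mask annotates.
#' @param role anatomical role tag for the mask.
#' @return an \linkS4class{ROIMask}.
#' @export
readMask <- function(path, parent, role = "liver") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  stopifnot(is(parent, "CTVolume"))
  img <- RNifti::readNifti(path)
  ort <- try(RNifti::orientation(img), silent = TRUE)
  if (!inherits(ort, "try-error") && !identical(ort, "RAS"))
    RNifti::orientation(img) <- "RAS"
  m <- as.array(img)
  if (length(dim(m)) == 4L && dim(m)[4] == 1L) m <- array(m, dim(m)[1:3])
  if (!identical(dim(m), dim(parent@data)))
    stop(sprintf("mask shape (%s) does not match parent volume shape (%s)",
                 paste(dim(m), collapse = "x"),
                 paste(dim(parent@data), collapse = "x")))
  ROIMask(m != 0, role = role, parent = parent)
}

#' Write an ROI mask to NIfTI
#'
#' @param mask an \linkS4class{ROIMask}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "ROIMask"))
  img <- RNifti::asNifti(array(as.integer(mask@mask), dim(mask@mask)))
  RNifti::pixdim(img) <- mask@spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read seed points from a plain-text table
#'
#' Seed files hold one \code{x y z} triple per line, 0-based (the convention
#' of most imaging toolkits); indices are converted to R's 1-based convention
#' on read. Lines starting with \code{#} are ignored.
#'
#' @param path path to the whitespace-delimited seed file.
#' @param vol optional \linkS4class{CTVolume}; when given, seeds are checked
#'   against the grid bounds.
#' @return a \linkS4class{SeedSet}.
#' @export
readSeeds <- function(path, vol = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("x", "y", "z"))
  pts <- as.matrix(tab) + 1L
  ss <- SeedSet(pts)
  if (!is.null(vol)) .checkSeedsInGrid(ss, dim(vol@data))
  ss
}

.checkSeedsInGrid <- function(seeds, dims) {
  pts <- seeds@points
  for (r in seq_len(nrow(pts))) {
    if (any(pts[r, ] < 1L) || any(pts[r, ] > dims))
      stop(sprintf("seed %d at (%s) lies outside the %s grid",
                   r, paste(pts[r, ] - 1L, collapse = ", "),
                   paste(dims, collapse = "x")))
  }
  invisible(TRUE)
}

#' Volume of a single voxel
#'
#' @param spacing numeric length-3 voxel size, mm.
#' @return voxel volume in mm^3 (product of the three components).
#' @examples
#' voxelVolume(c(0.7, 0.7, 5.0))  # 2.45 mm^3
#' @export
voxelVolume <- function(spacing) {
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop(sprintf("spacing must be 3 strictly positive values, got (%s)",
                 paste(format(spacing), collapse = ", ")))
  prod(spacing)
}

#' Convert cubic millimetres to litres
#'
#' @param mm3 volume in mm^3.
#' @return volume in litres (\code{mm3 / 1e6}).
#' @examples
#' mm3ToL(2334821.84)  # 2.33482184 L, i.e. 2.335 L at 3 decimals
#' @export
mm3ToL <- function(mm3) mm3 / 1e6

## Evaluate expr under a fixed RNG seed without disturbing the caller's RNG
## stream (no global state leaks out of generator calls).
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
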