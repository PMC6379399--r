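#' @include AllClasses.R
NULL

#' Region-growing configuration
#'
#' @param connectivity voxel adjacency: 6 (faces only, the default; resists
#'   leakage through diagonal noise bridges) or 26 (faces, edges, corners).
#' @param keep \code{"seed_components"} (only voxels connected to a seed are
#'   kept; the default) — retained for completeness, growing from seeds only
#'   ever produces seed components.
#' @return a named list.
#' @export
growConfig <- function(connectivity = 6L, keep = "seed_components") {
  if (!connectivity %in% c(6L, 26L))
    stop("connectivity must be 6 or 26")
  keep <- match.arg(keep, "seed_components")
  list(connectivity = as.integer(connectivity), keep = keep)
}

.neighborOffsets <- function(connectivity) {
  if (connectivity == 6L) {
    rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L), c(0L, 1L, 0L),
          c(0L, 0L, -1L), c(0L, 0L, 1L))
  } else {
    off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    storage.mode(off) <- "integer"
    off[rowSums(abs(off)) > 0L, , drop = FALSE]
  }
}

#' Estimate a Hounsfield threshold interval from a scribble
#'
#' The interval is the \code{[pLo, pHi]} percentile bracket of the HU values
#' under the scribble, computed on the (denoised) volume. At
#' \code{pLo = 0, pHi = 100} this reduces to the scribble min/max; the
#' defaults \code{(1, 99)} trim stray voxels at either tail.
#'
#' @param vol a \linkS4class{CTVolume} (typically the denoised volume).
#' @param scribble a non-empty \linkS4class{ROIMask} drawn on one tissue.
#' @param pLo,pHi percentiles in \code{[0, 100]}, \code{pLo < pHi}.
#' @return a \linkS4class{ThresholdInterval} tagged with the scribble role.
#' @export
estimateThreshold <- function(vol, scribble, pLo = 1, pHi = 99) {
  stopifnot(is(vol, "CTVolume"), is(scribble, "ROIMask"))
  if (!identical(dim(scribble@mask), dim(vol@data)))
    stop("scribble shape does not match volume shape")
  if (!any(scribble@mask))
    stop(sprintf("empty %s scribble: cannot estimate a threshold",
                 scribble@role))
  if (!(pLo >= 0 && pHi <= 100 && pLo < pHi))
    stop("need 0 <= pLo < pHi <= 100")
  vals <- vol@data[scribble@mask]
  q <- stats::quantile(vals, c(pLo, pHi) / 100, names = FALSE, type = 7)
  ThresholdInterval(q[1], q[2], scribble@role)
}

#' Merge low-density and enhancement thresholds into the lesion interval
#'
#' Given the low-density interval \code{[a, b]} and the enhancement interval
#' \code{[c, d]}, the lesion interval is \code{[a, (b + c)/2]}: its upper
#' bound is moved to the midpoint between the top of the hypoattenuating
#' tissue and the bottom of the enhancing parenchyma, splitting the HU gap
#' between the two tissues. Both ends are closed, so touching intervals
#' (\code{b = c}) yield \code{[a, b]}.
#'
#' @param lowDensity \linkS4class{ThresholdInterval} from the low-density
#'   scribble (\code{[a, b]}).
#' @param enhancement \linkS4class{ThresholdInterval} from the enhancement
#'   scribble (\code{[c, d]}).
#' @return a \linkS4class{ThresholdInterval} with role \code{"lesion"}.
#' @examples
#' lesionInterval(ThresholdInterval(40, 90, "low_density"),
#'                ThresholdInterval(110, 160, "enhancement"))  # [40, 100]
#' @export
lesionInterval <- function(lowDensity, enhancement) {
  stopifnot(is(lowDensity, "ThresholdInterval"),
            is(enhancement, "ThresholdInterval"))
  a <- lowDensity@lo; b <- lowDensity@hi; cc <- enhancement@lo
  hi <- (b + cc) / 2
  if (hi < a)
    stop(sprintf(
      "empty lesion interval: (b + c)/2 = %g falls below a = %g", hi, a))
  if (b >= cc && !isTRUE(all.equal(b, cc)))
    warning(sprintf(
      "low-density [%g, %g] and enhancement [%g, %g] intervals overlap",
      a, b, cc, enhancement@hi))
  ThresholdInterval(a, hi, "lesion")
}

#' Threshold-constrained seeded region growing
#'
#' Returns the set of voxels connected (6- or 26-adjacency) to any seed
#' through voxels whose HU lies inside the closed interval
#' \code{[lo, hi]}, optionally intersected with a bounding mask. The result
#' is deterministic: it depends only on the voxel set, not on seed order or
#' traversal order.
#'
#' @param vol a \linkS4class{CTVolume}.
#' @param seeds a \linkS4class{SeedSet} (or matrix of 1-based index
#'   triples). Every seed must lie inside the grid, inside the bounding mask
#'   when one applies, and its HU must lie inside \code{interval}.
#' @param interval a \linkS4class{ThresholdInterval}.
#' @param cfg configuration from \code{\link{growConfig}}.
#' @param bounding optional \linkS4class{ROIMask} restricting growth; when
#'   \code{NULL}, the bounding scribble carried by \code{seeds} (if any) is
#'   used.
#' @param role role tag for the returned mask (defaults to the interval's
#'   source role).
#' @return an \linkS4class{ROIMask}.
#' @export
regionGrow <- function(vol, seeds, interval, cfg = growConfig(),
                       bounding = NULL, role = NULL) {
  stopifnot(is(vol, "CTVolume"), is(interval, "ThresholdInterval"))
  if (!is(seeds, "SeedSet")) seeds <- SeedSet(seeds)
  if (is.null(bounding)) bounding <- seeds@bounding
  dims <- dim(vol@data)
  pts <- seeds@points
  if (nrow(pts) == 0L) stop("empty seed set")
  .checkSeedsInGrid(seeds, dims)
  arr <- vol@data
  candidate <- arr >= interval@lo & arr <= interval@hi
  if (!is.null(bounding)) {
    if (!identical(dim(bounding@mask), dims))
      stop("bounding mask shape does not match volume shape")
    candidate <- candidate & bounding@mask
  }
  lin0 <- pts[, 1] + (pts[, 2] - 1L) * dims[1] +
    (pts[, 3] - 1L) * dims[1] * dims[2]
  for (r in seq_len(nrow(pts))) {
    if (!is.null(bounding) && !bounding@mask[lin0[r]])
      stop(sprintf("seed %d at (%s) lies outside the bounding mask",
                   r, paste(pts[r, ] - 1L, collapse = ", ")))
    hu <- arr[lin0[r]]
    if (hu < interval@lo || hu > interval@hi)
      stop(sprintf(
        "seed %d at (%s) has HU %.2f outside the interval [%g, %g]",
        r, paste(pts[r, ] - 1L, collapse = ", "), hu,
        interval@lo, interval@hi))
  }
  visited <- .floodFrontier(candidate, unique(lin0),
                            .neighborOffsets(cfg$connectivity), dims)
  ROIMask(array(visited, dims),
          role = if (is.null(role)) interval@sourceRole else role,
          spacing = vol@spacing)
}

## Breadth-first wavefront flood fill over a logical candidate grid, fully
## vectorised per frontier. `start` are linear indices (assumed candidate).
.floodFrontier <- function(candidate, start, offsets, dims) {
  visited <- logical(length(candidate))
  visited[start] <- TRUE
  frontier <- start
  nxy <- dims[1] * dims[2]
  while (length(frontier)) {
    fc <- arrayInd(frontier, dims)
    nxt <- integer(0)
    for (k in seq_len(nrow(offsets))) {
      n1 <- fc[, 1] + offsets[k, 1]
      n2 <- fc[, 2] + offsets[k, 2]
      n3 <- fc[, 3] + offsets[k, 3]
      ok <- n1 >= 1L & n1 <= dims[1] & n2 >= 1L & n2 <= dims[2] &
        n3 >= 1L & n3 <= dims[3]
      if (!any(ok)) next
      lin <- n1[ok] + (n2[ok] - 1L) * dims[1] + (n3[ok] - 1L) * nxy
      lin <- lin[candidate[lin] & !visited[lin]]
      if (length(lin)) {
        visited[lin] <- TRUE
        nxt <- c(nxt, lin)
      }
    }
    frontier <- nxt
  }
  visited
}

## Connected-component labelling over a logical mask (used to place one seed
## per lesion blob in phantom annotations).
.labelComponents <- function(mask, connectivity = 6L) {
  dims <- dim(mask)
  offsets <- .neighborOffsets(connectivity)
  labels <- integer(length(mask))
  remaining <- which(mask)
  lab <- 0L
  while (length(remaining)) {
    lab <- lab + 1L
    comp <- .floodFrontier(mask, remaining[1], offsets, dims)
    labels[comp] <- lab
    remaining <- remaining[!comp[remaining]]
  }
  array(labels, dims)
}

#' Extract the liver by scribble-derived threshold and region growing
#'
#' Estimates the liver HU interval from the scribble
#' (\code{\link{estimateThreshold}}), then grows from the seeds inside the
#' manual approximate delineation of the organ.
#'
#' @param vol the (denoised) \linkS4class{CTVolume}.
#' @param scribble \linkS4class{ROIMask} over liver tissue, the threshold
#'   source.
#' @param seeds \linkS4class{SeedSet} inside the liver.
#' @param pLo,pHi percentile bracket for threshold estimation.
#' @param cfg \code{\link{growConfig}}.
#' @param bounding optional \linkS4class{ROIMask} with the approximate organ
#'   delineation restricting growth; defaults to \code{scribble} itself.
#' @return list with elements \code{mask} (\linkS4class{ROIMask}, role
#'   \code{"liver"}) and \code{interval} (\linkS4class{ThresholdInterval}).
#' @export
segmentLiver <- function(vol, scribble, seeds, pLo = 1, pHi = 99,
                         cfg = growConfig(), bounding = scribble) {
  interval <- estimateThreshold(vol, scribble, pLo, pHi)
  mask <- regionGrow(vol, seeds, interval, cfg, bounding = bounding,
                     role = "liver")
  list(mask = mask, interval = interval)
}

#' Extract hypoattenuating lesions inside a liver mask
#'
#' Estimates the low-density interval \code{[a, b]} and the enhancement
#' interval \code{[c, d]} from their scribbles, merges them into the lesion
#' interval \code{[a, (b + c)/2]} (\code{\link{lesionInterval}}), and grows
#' from the lesion seeds with growth bounded by the liver mask — the lesion
#' is hepatic by definition, and the constraint keeps low-HU ascites outside
#' the liver from leaking into the lesion ROI. The returned mask is always a
#' subset of the liver mask.
#'
#' @param vol the (denoised) \linkS4class{CTVolume}.
#' @param liverMask \linkS4class{ROIMask} from \code{\link{segmentLiver}}.
#' @param lowDensityScribble,enhancementScribble scribbles over the
#'   hypoattenuating tissue and the enhancing parenchyma.
#' @param seeds \linkS4class{SeedSet} inside the lesions (and inside the
#'   liver mask).
#' @param pLo,pHi percentile bracket for threshold estimation.
#' @param cfg \code{\link{growConfig}}.
#' @return list with elements \code{mask} (role \code{"lesion"}),
#'   \code{interval} (the lesion interval) and \code{thresholds}, a named
#'   numeric vector of the four bounds \code{a, b, c, d} plus the derived
#'   \code{lesion_lo}, \code{lesion_hi}.
#' @export
segmentLesion <- function(vol, liverMask, lowDensityScribble,
                          enhancementScribble, seeds, pLo = 1, pHi = 99,
                          cfg = growConfig()) {
  stopifnot(is(liverMask, "ROIMask"))
  lowInt <- estimateThreshold(vol, lowDensityScribble, pLo, pHi)
  enhInt <- estimateThreshold(vol, enhancementScribble, pLo, pHi)
  lesInt <- lesionInterval(lowInt, enhInt)
  mask <- regionGrow(vol, seeds, lesInt, cfg, bounding = liverMask,
                     role = "lesion")
  list(mask = mask, interval = lesInt,
       thresholds = c(a = lowInt@lo, b = lowInt@hi,
                      c = enhInt@lo, d = enhInt@hi,
                      lesion_lo = lesInt@lo, lesion_hi = lesInt@hi))
}
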