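#' @include AllClasses.R segmentation.R
NULL

## 6-neighbourhood morphology on logical 3D arrays (shift-based; edges are
## treated as background for dilation and as missing neighbours for erosion).
.shiftPad <- function(a, axis, by, pad) {
  d <- dim(a)
  n <- d[axis]
  idx <- seq_len(n) + by
  valid <- idx >= 1L & idx <= n
  res <- switch(axis,
                a[pmin(pmax(idx, 1L), n), , , drop = FALSE],
                a[, pmin(pmax(idx, 1L), n), , drop = FALSE],
                a[, , pmin(pmax(idx, 1L), n), drop = FALSE])
  if (!all(valid)) {
    if (axis == 1L) res[!valid, , ] <- pad
    if (axis == 2L) res[, !valid, ] <- pad
    if (axis == 3L) res[, , !valid] <- pad
  }
  res
}

.dilate6 <- function(mask, iterations = 1L) {
  for (i in seq_len(iterations)) {
    out <- mask
    for (ax in 1:3) for (s in c(-1L, 1L))
      out <- out | .shiftPad(mask, ax, s, FALSE)
    mask <- out
  }
  mask
}

.erode6 <- function(mask, iterations = 1L) {
  for (i in seq_len(iterations)) {
    out <- mask
    for (ax in 1:3) for (s in c(-1L, 1L))
      out <- out & .shiftPad(mask, ax, s, TRUE)
    mask <- out
  }
  mask
}

#' Configuration for the synthetic CT liver phantom
#'
#' The phantom emulates the imaging appearance the pipeline assumes on
#' hepatic-venous-phase contrast CT: an enhanced liver (ellipsoid) of
#' parenchyma around 110 HU, hypoattenuating lesion blobs around 60 HU
#' inside it (congested tissue with delayed contrast inflow), air background
#' at -1000 HU, optional ascites shell near 10 HU, plus additive Gaussian
#' noise. It makes no claim to anatomical realism or CT physics (no partial
#' volume, beam hardening or reconstruction kernel effects).
#'
#' @param dim grid shape in voxels.
#' @param spacing voxel size, mm (default 2 x 2 x 5 mm thick-slice CT).
#' @param backgroundHU background attenuation (air, -1000 HU).
#' @param liverCenter ellipsoid centre in mm (defaults to the grid centre).
#' @param liverSemiaxes ellipsoid semi-axes in mm.
#' @param parenchymaHU,parenchymaSD enhanced parenchyma mean and SD, HU.
#' @param lesionHU,lesionSD hypoattenuating lesion mean and SD, HU; the
#'   lesion mean must lie below the parenchyma mean.
#' @param nLesions number of spheroidal lesion blobs.
#' @param lesionRadiusRange range (mm) for each blob semi-axis, drawn
#'   uniformly per axis.
#' @param noiseSD global additive noise SD, HU.
#' @param ascites add a fluid shell around the liver at \code{ascitesHU}.
#' @param ascitesHU ascites attenuation, HU.
#' @return a validated named list.
#' @export
phantomConfig <- function(dim = c(80L, 80L, 24L), spacing = c(2, 2, 5),
                          backgroundHU = -1000,
                          liverCenter = NULL, liverSemiaxes = c(62, 50, 45),
                          parenchymaHU = 110, parenchymaSD = 8,
                          lesionHU = 60, lesionSD = 8,
                          nLesions = 12L, lesionRadiusRange = c(12, 26),
                          noiseSD = 5, ascites = FALSE, ascitesHU = 10) {
  dim <- as.integer(dim)
  extent <- dim * spacing
  if (is.null(liverCenter)) liverCenter <- extent / 2
  if (lesionHU >= parenchymaHU)
    stop(sprintf(
      "lesion mean (%g HU) must lie below parenchyma mean (%g HU): the disease signature is hypoattenuation",
      lesionHU, parenchymaHU))
  if (any(liverCenter - liverSemiaxes < 0) ||
      any(liverCenter + liverSemiaxes > extent))
    stop("liver ellipsoid extends outside the grid")
  if (any(c(parenchymaSD, lesionSD, noiseSD) < 0))
    stop("SDs must be non-negative")
  if (length(lesionRadiusRange) != 2L || any(lesionRadiusRange <= 0) ||
      diff(lesionRadiusRange) < 0)
    stop("lesionRadiusRange must be an increasing positive pair (mm)")
  list(dim = dim, spacing = as.numeric(spacing), backgroundHU = backgroundHU,
       liverCenter = as.numeric(liverCenter),
       liverSemiaxes = as.numeric(liverSemiaxes),
       parenchymaHU = parenchymaHU, parenchymaSD = parenchymaSD,
       lesionHU = lesionHU, lesionSD = lesionSD,
       nLesions = as.integer(nLesions),
       lesionRadiusRange = as.numeric(lesionRadiusRange),
       noiseSD = noiseSD, ascites = ascites, ascitesHU = ascitesHU)
}

#' Generate a synthetic CT liver phantom with ground truth
#'
#' Builds the phantom described by \code{\link{phantomConfig}}: the liver is
#' an ellipsoid, lesions are a union of random axis-aligned spheroidal blobs
#' centred on liver voxels and clipped to the liver, per-tissue HU values
#' are Gaussian, and global noise is added last. All randomness flows from
#' the single \code{seed}; the caller's RNG state is untouched.
#'
#' @param cfg configuration from \code{\link{phantomConfig}}.
#' @param seed integer RNG seed; the same seed reproduces the phantom
#'   bit-identically.
#' @return list: \code{volume} (\linkS4class{CTVolume}), \code{liverMask}
#'   and \code{lesionMask} (ground-truth \linkS4class{ROIMask}s), and
#'   \code{manifest} — a list recording the exact truth voxel counts,
#'   volumes (L) and lesion-to-liver ratio.
#' @export
makePhantom <- function(cfg = phantomConfig(), seed = 1L) {
  .withSeed(seed, {
    d <- cfg$dim
    sp <- cfg$spacing
    # voxel-centre coordinates in mm
    cx <- (seq_len(d[1]) - 0.5) * sp[1]
    cy <- (seq_len(d[2]) - 0.5) * sp[2]
    cz <- (seq_len(d[3]) - 0.5) * sp[3]
    X <- array(rep(cx, times = d[2] * d[3]), d)
    Y <- array(rep(rep(cy, each = d[1]), times = d[3]), d)
    Z <- array(rep(cz, each = d[1] * d[2]), d)
    ell <- function(ctr, ax)
      ((X - ctr[1]) / ax[1])^2 + ((Y - ctr[2]) / ax[2])^2 +
        ((Z - ctr[3]) / ax[3])^2 <= 1
    liver <- ell(cfg$liverCenter, cfg$liverSemiaxes)
    lesion <- array(FALSE, d)
    liverIdx <- which(liver)
    for (b in seq_len(cfg$nLesions)) {
      ctrIdx <- liverIdx[sample.int(length(liverIdx), 1L)]
      ctr <- c(X[ctrIdx], Y[ctrIdx], Z[ctrIdx])
      ax <- runif(3, cfg$lesionRadiusRange[1], cfg$lesionRadiusRange[2])
      lesion <- lesion | ell(ctr, ax)
    }
    lesion <- lesion & liver
    arr <- array(cfg$backgroundHU, d)
    if (cfg$ascites) {
      shell <- .dilate6(liver, 2L) & !liver
      arr[shell] <- cfg$ascitesHU
    }
    npar <- sum(liver & !lesion)
    arr[liver & !lesion] <- rnorm(npar, cfg$parenchymaHU, cfg$parenchymaSD)
    arr[lesion] <- rnorm(sum(lesion), cfg$lesionHU, cfg$lesionSD)
    if (cfg$noiseSD > 0)
      arr <- arr + rnorm(length(arr), 0, cfg$noiseSD)
    vol <- CTVolume(arr, spacing = sp)
    liverMask <- ROIMask(liver, "liver", spacing = sp)
    lesionMask <- ROIMask(lesion, "lesion", spacing = sp)
    list(volume = vol, liverMask = liverMask, lesionMask = lesionMask,
         manifest = list(
           seed = seed,
           liverVoxels = sum(liver), lesionVoxels = sum(lesion),
           liverVolumeL = maskVolume(liverMask),
           lesionVolumeL = maskVolume(lesionMask),
           ratio = sum(lesion) / sum(liver)))
  })
}

#' Derive operator annotations from phantom ground truth
#'
#' Stands in for the manual interaction the clinical pipeline needs: a
#' liver scribble strictly inside the organ (threshold source), a generous
#' bounding delineation (eroded/dilated truth), scribbles on lesion and
#' clean-parenchyma tissue, and one seed per lesion blob. Seeds are placed
#' at the voxel whose HU (on \code{vol}, normally the denoised volume) is
#' closest to the component's median HU, emulating an operator clicking
#' representative tissue.
#'
#' @param phantom output of \code{\link{makePhantom}}.
#' @param vol the volume segmentation will run on (usually the denoised
#'   phantom volume); defaults to the raw phantom volume.
#' @return list: \code{liverScribble}, \code{liverBounding},
#'   \code{liverSeeds}, \code{lowDensityScribble},
#'   \code{enhancementScribble}, \code{lesionSeeds}.
#' @export
phantomAnnotations <- function(phantom, vol = phantom$volume) {
  liver <- phantom$liverMask@mask
  lesion <- phantom$lesionMask@mask
  sp <- phantom$liverMask@spacing
  arr <- vol@data
  dims <- dim(arr)

  liverScrib <- .erode6(liver, 2L)
  bounding <- .dilate6(liver, 2L)
  lowScrib <- .erode6(lesion, 1L)
  if (!any(lowScrib)) lowScrib <- lesion
  enhScrib <- .erode6(liver & !.dilate6(lesion, 2L), 2L)
  if (!any(enhScrib)) enhScrib <- liver & !lesion

  medianSeed <- function(idx) {
    med <- stats::median(arr[idx])
    idx[which.min(abs(arr[idx] - med))]
  }
  # the liver scribble spans the whole organ, lesions included: ROI_liver
  # must contain the hypoattenuating tissue for the Ratio to make sense
  liverSeed <- medianSeed(which(liverScrib))
  labs <- .labelComponents(lowScrib)
  lesionSeedIdx <- vapply(seq_len(max(labs)),
                          function(l) medianSeed(which(labs == l)),
                          integer(1))
  toPts <- function(lin) arrayInd(lin, dims)
  list(
    liverScribble = ROIMask(liverScrib, "liver", spacing = sp),
    liverBounding = ROIMask(bounding, "liver", spacing = sp),
    liverSeeds = SeedSet(toPts(liverSeed)),
    lowDensityScribble = ROIMask(lowScrib, "low_density", spacing = sp),
    enhancementScribble = ROIMask(enhScrib, "enhancement", spacing = sp),
    lesionSeeds = SeedSet(toPts(lesionSeedIdx)))
}

#' Default severity-group parameters of the reference cohort
#'
#' Group sizes, Ratio and liver-function summaries (mean, sample SD) for the
#' mild / moderate / severe severity classes of the transcribed reference
#' cohort, as shipped in \code{inst/extdata/group_summaries.csv}. These are
#' the default parameters of \code{\link{cohortConfig}}.
#'
#' @param variable which variable's per-group summaries to return.
#' @return \code{data.frame} with columns \code{group, n, mean, sd}.
#' @export
severityGroupDefaults <- function(variable = "ratio") {
  gs <- referenceGroupSummaries()
  out <- gs[gs$table == "severity_labs" | gs$table == "severity",
            c("variable", "group", "n", "mean", "sd")]
  out <- out[out$variable == variable, c("group", "n", "mean", "sd")]
  if (!nrow(out)) stop(sprintf("unknown variable '%s'", variable))
  rownames(out) <- NULL
  out
}

#' Configuration for the synthetic cohort generator
#'
#' Each group draws its Ratio from a normal distribution truncated to
#' \code{[0, 1]} (rejection sampling keeps group means near the configured
#' values; truncation bias is negligible at these SDs) and each lab value
#' from a normal floored at 0.
#'
#' @param groups \code{data.frame} with columns \code{group, n, mean, sd}
#'   giving the Ratio distribution per group; defaults to the reference
#'   cohort's severity groups.
#' @param labs optional named list of \code{data.frame}s (same columns) for
#'   lab variables; defaults to the reference cohort's ALT, AST and total
#'   bilirubin severity summaries.
#' @return a validated named list.
#' @export
cohortConfig <- function(groups = severityGroupDefaults("ratio"),
                         labs = list(
                           alt = severityGroupDefaults("alt"),
                           ast = severityGroupDefaults("ast"),
                           total_bilirubin =
                             severityGroupDefaults("total_bilirubin"))) {
  stopifnot(all(c("group", "n", "mean", "sd") %in% names(groups)))
  if (any(groups$n < 2L)) stop("every group needs n >= 2")
  if (any(groups$sd < 0)) stop("SDs must be non-negative")
  for (nm in names(labs)) {
    if (!identical(labs[[nm]]$group, groups$group))
      stop(sprintf("lab '%s' group labels/order differ from the Ratio groups",
                   nm))
  }
  list(groups = groups, labs = labs)
}

#' Generate a synthetic cohort table
#'
#' @param cfg configuration from \code{\link{cohortConfig}}.
#' @param seed integer RNG seed; deterministic per seed, no global RNG
#'   state is disturbed.
#' @return \code{data.frame}: \code{patient_id}, \code{group}, \code{ratio},
#'   one column per configured lab variable.
#' @export
makeCohort <- function(cfg = cohortConfig(), seed = 1L) {
  .withSeed(seed, {
    rtrunc01 <- function(n, mean, sd) {
      if (sd == 0) return(rep(mean, n))
      out <- numeric(0)
      while (length(out) < n) {
        x <- rnorm(2 * n, mean, sd)
        out <- c(out, x[x >= 0 & x <= 1])
      }
      out[seq_len(n)]
    }
    rows <- lapply(seq_len(nrow(cfg$groups)), function(i) {
      g <- cfg$groups[i, ]
      df <- data.frame(group = g$group,
                       ratio = rtrunc01(g$n, g$mean, g$sd),
                       stringsAsFactors = FALSE)
      for (nm in names(cfg$labs)) {
        lg <- cfg$labs[[nm]][i, ]
        df[[nm]] <- pmax(0, rnorm(g$n, lg$mean, lg$sd))
      }
      df
    })
    out <- do.call(rbind, rows)
    out <- cbind(patient_id = sprintf("S%02d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}
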