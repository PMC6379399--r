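test_that("threshold estimation brackets the scribble HU distribution", {
  arr <- array(-1000, c(10, 10, 4))
  arr[2:5, 2:5, 2] <- 100
  vol <- CTVolume(arr)
  scrib <- ROIMask(arr == 100, "liver", parent = vol)
  int <- estimateThreshold(vol, scrib, 0, 100)
  expect_equal(intervalBounds(int), c(lo = 100, hi = 100))

  arr2 <- array(0, c(10, 1, 1))
  arr2[, 1, 1] <- seq(10, 100, by = 10)
  vol2 <- CTVolume(arr2)
  scrib2 <- ROIMask(array(TRUE, dim(arr2)), "liver", parent = vol2)
  expect_equal(intervalBounds(estimateThreshold(vol2, scrib2, 0, 100)),
               c(lo = 10, hi = 100))

  # percentiles of a large normal patch agree with the closed-form quantiles
  set.seed(31)
  n <- 1e4
  arr3 <- array(rnorm(n, 110, 10), c(100, 100, 1))
  vol3 <- CTVolume(arr3)
  scrib3 <- ROIMask(array(TRUE, dim(arr3)), "enhancement", parent = vol3)
  int3 <- estimateThreshold(vol3, scrib3, 1, 99)
  expect_lt(abs(int3@lo - qnorm(0.01, 110, 10)), 1)
  expect_lt(abs(int3@hi - qnorm(0.99, 110, 10)), 1)
  expect_equal(int3@sourceRole, "enhancement")

  empty <- ROIMask(array(FALSE, dim(arr3)), "liver", parent = vol3)
  expect_error(estimateThreshold(vol3, empty), "empty")
})

test_that("the lesion interval is [a, (b + c)/2] with sane degenerate cases", {
  low <- ThresholdInterval(40, 90, "low_density")
  enh <- ThresholdInterval(110, 160, "enhancement")
  les <- lesionInterval(low, enh)
  expect_equal(intervalBounds(les), c(lo = 40, hi = 100))
  expect_equal(les@sourceRole, "lesion")

  # touching intervals: (b + b)/2 = b
  expect_equal(
    intervalBounds(lesionInterval(ThresholdInterval(40, 90, "low_density"),
                                  ThresholdInterval(90, 150, "enhancement"))),
    c(lo = 40, hi = 90))
  # midpoint below a: empty interval is an error
  expect_error(
    lesionInterval(ThresholdInterval(50, 60, "low_density"),
                   ThresholdInterval(30, 80, "enhancement")),
    "empty lesion interval")
  # overlapping tissue intervals warn but proceed
  expect_warning(
    lesionInterval(ThresholdInterval(40, 120, "low_density"),
                   ThresholdInterval(100, 160, "enhancement")),
    "overlap")
})

test_that("region growing matches a brute-force flood-fill oracle", {
  # trivial identity: uniform in-range block surrounded by out-of-range
  arr <- array(-1000, c(8, 8, 4))
  arr[3:6, 3:6, 2:3] <- 50
  vol <- CTVolume(arr)
  m <- regionGrow(vol, SeedSet(c(4, 4, 2)), ThresholdInterval(0, 100, "liver"))
  expect_identical(maskArray(m), arr == 50)

  # two seeds in disjoint components: the union
  arr2 <- array(-1000, c(10, 4, 2))
  arr2[1:3, 1:2, 1] <- 10
  arr2[7:9, 1:2, 1] <- 10
  vol2 <- CTVolume(arr2)
  m2 <- regionGrow(vol2, SeedSet(rbind(c(2, 1, 1), c(8, 1, 1))),
                   ThresholdInterval(0, 20, "liver"))
  expect_identical(maskArray(m2), arr2 == 10)

  # randomized equivalence, both connectivities, with and without bounding
  set.seed(32)
  for (i in 1:100) {
    arr <- array(sample(0:9, 20 * 20 * 10, replace = TRUE), c(20, 20, 10))
    lo <- sample(0:4, 1); hi <- sample(5:9, 1)
    conn <- if (i %% 2) 6L else 26L
    bounding <- NULL
    if (i %% 5 == 0) {
      bm <- array(FALSE, dim(arr))
      bm[3:18, 3:18, 2:9] <- TRUE
      bounding <- ROIMask(bm, "liver", spacing = c(1, 1, 1))
    }
    inr <- arr >= lo & arr <= hi
    if (!is.null(bounding)) inr <- inr & maskArray(bounding)
    cand <- which(inr)
    if (!length(cand)) next
    seed <- arrayInd(cand[sample(length(cand), 1)], dim(arr))
    got <- regionGrow(CTVolume(arr), SeedSet(seed),
                      ThresholdInterval(lo, hi, "liver"),
                      growConfig(connectivity = conn), bounding = bounding)
    want <- oracleFloodFill(arr, seed, lo, hi, conn,
                            if (is.null(bounding)) NULL
                            else maskArray(bounding))
    expect_identical(maskArray(got), want)
  }
})

test_that("region growing is deterministic, seed-containing and monotone", {
  set.seed(33)
  arr <- array(sample(0:9, 15 * 15 * 6, replace = TRUE), c(15, 15, 6))
  vol <- CTVolume(arr)
  cand <- which(arr >= 3 & arr <= 6)
  seeds <- arrayInd(cand[sample(length(cand), 4)], dim(arr))
  int <- ThresholdInterval(3, 6, "liver")
  m1 <- regionGrow(vol, SeedSet(seeds), int)
  # permuted seed order: bit-identical
  m2 <- regionGrow(vol, SeedSet(seeds[c(3, 1, 4, 2), ]), int)
  expect_identical(maskArray(m1), maskArray(m2))
  # contains every seed; every set voxel lies in the interval
  for (r in seq_len(nrow(seeds)))
    expect_true(maskArray(m1)[seeds[r, 1], seeds[r, 2], seeds[r, 3]])
  expect_true(all(arr[maskArray(m1)] >= 3 & arr[maskArray(m1)] <= 6))
  # widening the interval never shrinks the region
  wide <- regionGrow(vol, SeedSet(seeds), ThresholdInterval(2, 7, "liver"))
  expect_true(all(maskArray(wide)[maskArray(m1)]))
})

test_that("out-of-interval or out-of-bounds seeds are rejected by name", {
  arr <- array(-1000, c(6, 6, 3))
  arr[2:5, 2:5, 2] <- 100
  vol <- CTVolume(arr)
  expect_error(regionGrow(vol, SeedSet(c(1, 1, 1)),
                          ThresholdInterval(50, 150, "liver")),
               "HU -1000.*outside the interval")
  expect_error(regionGrow(vol, SeedSet(c(7, 1, 1)),
                          ThresholdInterval(50, 150, "liver")),
               "outside the .* grid")
  bm <- ROIMask(array(FALSE, dim(arr)), "liver", spacing = c(1, 1, 1))
  expect_error(regionGrow(vol, SeedSet(c(3, 3, 2)),
                          ThresholdInterval(50, 150, "liver"),
                          bounding = bm),
               "bounding")
})

test_that("liver segmentation recovers a perfect-contrast phantom exactly", {
  ph <- simplePhantom(noise = 0)
  scrib <- ROIMask(ph$truth, "liver", spacing = ph$spacing)
  ctr <- matrix(round(dim(ph$truth) / 2), ncol = 3)
  res <- segmentLiver(ph$vol, scrib, SeedSet(ctr), pLo = 0, pHi = 100)
  expect_identical(maskArray(res$mask), ph$truth)
  expect_equal(intervalBounds(res$interval), c(lo = 100, hi = 100))

  # seed in the background: named rejection
  expect_error(segmentLiver(ph$vol, scrib, SeedSet(c(1, 1, 1)),
                            pLo = 0, pHi = 100),
               "outside the interval|bounding")
})

test_that("liver segmentation is robust to noise after denoising", {
  ph <- simplePhantom(dims = c(28, 28, 12), noise = 5, seed = 34)
  dn <- anisotropicDiffusion(ph$vol)
  scrib <- ROIMask(ph$truth, "liver", spacing = ph$spacing)
  bounding <- ROIMask(sosct:::.dilate6(ph$truth, 2L), "liver",
                      spacing = ph$spacing)
  ctr <- matrix(round(dim(ph$truth) / 2), ncol = 3)
  res <- segmentLiver(dn, scrib, SeedSet(ctr), pLo = 0.5, pHi = 99.5,
                      bounding = bounding)
  expect_gte(diceCoef(maskArray(res$mask), ph$truth), 0.99)
})

test_that("lesion segmentation is confined to the liver and finds the blobs", {
  # perfect contrast: 60 HU blobs inside a 110 HU liver
  ph <- simplePhantom(dims = c(28, 28, 12), liverHU = 110, noise = 0)
  arr <- voxelData(ph$vol)
  lesion <- array(FALSE, dim(arr))
  lesion[8:12, 8:12, 4:6] <- ph$truth[8:12, 8:12, 4:6]
  lesion[18:22, 16:20, 6:8] <- ph$truth[18:22, 16:20, 6:8]
  arr[lesion] <- 60
  vol <- CTVolume(arr, spacing = ph$spacing)
  liverMask <- ROIMask(ph$truth, "liver", spacing = ph$spacing)
  res <- segmentLesion(vol, liverMask,
                       ROIMask(lesion, "low_density", spacing = ph$spacing),
                       ROIMask(ph$truth & !lesion, "enhancement",
                               spacing = ph$spacing),
                       SeedSet(rbind(c(10, 10, 5), c(20, 18, 7))),
                       pLo = 0, pHi = 100)
  expect_identical(maskArray(res$mask), lesion)
  expect_equal(unname(res$thresholds[c("a", "b", "c", "d")]),
               c(60, 60, 110, 110))
  expect_equal(intervalBounds(res$interval), c(lo = 60, hi = 85))
  # subset invariant
  expect_false(any(maskArray(res$mask) & !maskArray(liverMask)))

  # seeds outside the liver mask are refused
  expect_error(
    segmentLesion(vol, liverMask,
                  ROIMask(lesion, "low_density", spacing = ph$spacing),
                  ROIMask(ph$truth & !lesion, "enhancement",
                          spacing = ph$spacing),
                  SeedSet(c(1, 1, 1)), pLo = 0, pHi = 100),
    "bounding")
})
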