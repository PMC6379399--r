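test_that("diffusion is the identity on constant volumes and at 0 iterations", {
  const <- CTVolume(array(40, c(7, 7, 3)))
  out <- anisotropicDiffusion(const, diffusionParams(iterations = 5))
  expect_equal(voxelData(out), voxelData(const))

  set.seed(21)
  noisy <- CTVolume(array(rnorm(7 * 7 * 3, 40, 10), c(7, 7, 3)))
  expect_identical(
    voxelData(anisotropicDiffusion(noisy, diffusionParams(iterations = 0))),
    voxelData(noisy))
})

test_that("each update matches a straight-loop finite-difference oracle", {
  # single bright voxel, exponential conduction, kappa 30, dt 0.125
  arr <- array(0, c(5, 5, 1))
  arr[3, 3, 1] <- 100
  gexp <- function(d) exp(-(d / 30)^2)
  out <- anisotropicDiffusion(
    CTVolume(arr), diffusionParams(iterations = 1, timeStep = 0.125,
                                   kappa = 30, mode = "slice_2d"))
  expect_equal(voxelData(out), oracleDiffusion(arr, 1, 0.125, gexp),
               tolerance = 1e-12)

  # random fields, both conduction functions, both modes, several iterations
  set.seed(22)
  for (rep in 1:4) {
    arr <- array(rnorm(6 * 5 * 4, 50, 30), c(6, 5, 4))
    cond <- if (rep %% 2) "exponential" else "rational"
    gfun <- if (rep %% 2) gexp else function(d) 1 / (1 + (d / 30)^2)
    mode <- if (rep <= 2) "slice_2d" else "volume_3d"
    axes <- if (rep <= 2) 1:2 else 1:3
    dt <- if (rep <= 2) 0.2 else 1 / 6
    out <- anisotropicDiffusion(
      CTVolume(arr), diffusionParams(iterations = 3, timeStep = dt,
                                     kappa = 30, conduction = cond,
                                     mode = mode))
    expect_equal(voxelData(out), oracleDiffusion(arr, 3, dt, gfun, axes),
                 tolerance = 1e-12)
  }
})

test_that("zero-flux boundaries conserve the global intensity sum", {
  set.seed(23)
  for (mode in c("slice_2d", "volume_3d")) {
    vol <- CTVolume(array(rnorm(12 * 10 * 6, 60, 40), c(12, 10, 6)))
    u <- vol
    for (it in 1:6) {
      u <- anisotropicDiffusion(u, diffusionParams(iterations = 1,
                                                   timeStep = 0.125,
                                                   mode = mode))
      expect_equal(sum(voxelData(u)), sum(voxelData(vol)), tolerance = 1e-10)
    }
  }
})

test_that("diffusion obeys the extremum principle", {
  set.seed(24)
  for (i in 1:5) {
    arr <- array(rnorm(10 * 10 * 4, 0, 100), c(10, 10, 4))
    mode <- if (i %% 2) "slice_2d" else "volume_3d"
    dt <- if (mode == "slice_2d") 0.25 else 1 / 6
    out <- voxelData(anisotropicDiffusion(
      CTVolume(arr), diffusionParams(iterations = 5, timeStep = dt,
                                     mode = mode)))
    expect_gte(min(out), min(arr) - 1e-12)
    expect_lte(max(out), max(arr) + 1e-12)
  }
})

test_that("edges survive anisotropic but not isotropic smoothing", {
  # two-level step phantom with noise: within-level variance must fall,
  # while the between-level contrast falls by less than a g == 1 linear
  # filter with the same iterations and step loses
  set.seed(25)
  arr <- array(0, c(20, 20, 2))
  left <- rep(rep(c(TRUE, FALSE), each = 10), times = 20 * 2)
  dim(left) <- c(20, 20, 2)
  arr[left] <- rnorm(sum(left), 0, 8)
  arr[!left] <- rnorm(sum(!left), 100, 8)
  pm <- voxelData(anisotropicDiffusion(
    CTVolume(arr), diffusionParams(iterations = 8, timeStep = 0.125,
                                   kappa = 25)))
  iso <- oracleDiffusion(arr, 8, 0.125, function(d) rep(1, length(d)))
  expect_lt(var(pm[left]), var(arr[left]))
  expect_lt(var(pm[!left]), var(arr[!left]))
  contrast <- function(x) abs(mean(x[!left]) - mean(x[left]))
  lossPM <- contrast(arr) - contrast(pm)
  lossIso <- contrast(arr) - contrast(iso)
  expect_lt(lossPM, lossIso)
})

test_that("unstable time steps are rejected with the bound stated", {
  expect_error(diffusionParams(timeStep = 0.3, mode = "slice_2d"), "0.25")
  expect_error(diffusionParams(timeStep = 0.2, mode = "volume_3d"),
               "0.166")
  expect_error(diffusionParams(kappa = -1), "kappa")
  expect_error(diffusionParams(iterations = -1), "iterations")
  # defaults follow the published protocol
  p <- diffusionParams()
  expect_equal(p$iterations, 4L)
  expect_equal(p$timeStep, 0.125)
})
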