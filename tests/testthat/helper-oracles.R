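# Independent brute-force oracles, deliberately written as plain voxel-by-
# voxel loops so they share no code path with the package implementations.

# Stack-based flood fill: connected voxels with lo <= value <= hi, optional
# bounding mask, 6- or 26-adjacency.
oracleFloodFill <- function(arr, seeds, lo, hi, connectivity = 6,
                            bounding = NULL) {
  dims <- dim(arr)
  offs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (connectivity == 6 && abs(dx) + abs(dy) + abs(dz) != 1) next
    offs[[length(offs) + 1]] <- c(dx, dy, dz)
  }
  ok <- function(i, j, k) {
    v <- arr[i, j, k]
    v >= lo && v <= hi && (is.null(bounding) || bounding[i, j, k])
  }
  visited <- array(FALSE, dims)
  stack <- lapply(seq_len(nrow(seeds)), function(r) seeds[r, ])
  for (s in stack) visited[s[1], s[2], s[3]] <- TRUE
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (o in offs) {
      n <- cur + o
      if (any(n < 1) || any(n > dims)) next
      if (visited[n[1], n[2], n[3]]) next
      if (!ok(n[1], n[2], n[3])) next
      visited[n[1], n[2], n[3]] <- TRUE
      stack[[length(stack) + 1]] <- n
    }
  }
  visited
}

# Straight-loop Perona-Malik update with replicated edges. gfun maps the
# neighbour difference to a conduction coefficient.
oracleDiffusion <- function(arr, iterations, dt, gfun, axes = 1:2) {
  dims <- dim(arr)
  offs <- list()
  for (ax in axes) for (s in c(-1, 1)) {
    o <- c(0, 0, 0)
    o[ax] <- s
    offs[[length(offs) + 1]] <- o
  }
  for (it in seq_len(iterations)) {
    out <- arr
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
      for (k in seq_len(dims[3])) {
        acc <- 0
        for (o in offs) {
          ni <- min(max(i + o[1], 1), dims[1])
          nj <- min(max(j + o[2], 1), dims[2])
          nk <- min(max(k + o[3], 1), dims[3])
          d <- arr[ni, nj, nk] - arr[i, j, k]
          acc <- acc + gfun(d) * d
        }
        out[i, j, k] <- arr[i, j, k] + dt * acc
      }
    arr <- out
  }
  arr
}

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Small uniform-liver phantom used by several segmentation tests: ellipsoid
# at liverHU in an air background, optional noise.
simplePhantom <- function(dims = c(24, 24, 10), liverHU = 100, noise = 0,
                          seed = 1) {
  set.seed(seed)
  sp <- c(2, 2, 5)
  cx <- (seq_len(dims[1]) - 0.5) * sp[1]
  cy <- (seq_len(dims[2]) - 0.5) * sp[2]
  cz <- (seq_len(dims[3]) - 0.5) * sp[3]
  X <- array(rep(cx, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(cy, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(cz, each = dims[1] * dims[2]), dims)
  ctr <- dims * sp / 2
  ax <- dims * sp / 2 - 2 * sp
  inside <- ((X - ctr[1]) / ax[1])^2 + ((Y - ctr[2]) / ax[2])^2 +
    ((Z - ctr[3]) / ax[3])^2 <= 1
  arr <- array(-1000, dims)
  arr[inside] <- liverHU
  if (noise > 0) arr <- arr + rnorm(length(arr), 0, noise)
  list(vol = CTVolume(arr, spacing = sp), truth = inside, spacing = sp)
}
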