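test_that("percentile thresholds follow the I_10/I_90 interpolation rule", {
  # hand-built slice with known 10th/90th percentiles
  slice <- matrix(seq(0, 999), 25, 40)
  qs <- sort(as.numeric(slice))
  # independent sort-based type-7 quantile
  q7 <- function(p) {
    h <- (length(qs) - 1) * p + 1
    lo <- floor(h)
    qs[lo] + (h - lo) * (qs[lo + 1] - qs[lo])
  }
  for (vu in c(0, 0.3, 0.5, 1)) {
    rec <- sliceThresholdPercentile(slice, vu)
    expect_equal(rec$I_10, q7(0.1))
    expect_equal(rec$I_90, q7(0.9))
    expect_equal(rec$I_T, q7(0.1) + vu * (q7(0.9) - q7(0.1)))
  }
  # degenerate constant slice
  rec <- sliceThresholdPercentile(matrix(7, 5, 5), 0.5)
  expect_true(rec$degenerate)
  expect_equal(rec$I_T, 7)
  expect_error(sliceThresholdPercentile(slice, 1.5), "0, 1")
})

test_that("Otsu threshold separates modes and matches the exhaustive search", {
  two <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  rec <- sliceThresholdOtsu(two)
  expect_gt(rec$I_T, 10)
  expect_lt(rec$I_T, 200)

  set.seed(42)
  slice <- matrix(c(rnorm(5000, 50, 10), rnorm(5000, 180, 10)), 100, 100)
  slice[slice < 0] <- 0
  rec <- sliceThresholdOtsu(slice)
  # exhaustive between-class-variance search over the same 256 bins
  v <- as.numeric(slice)
  edges <- seq(min(v), max(v), length.out = 257)
  best <- c(-Inf, NA)
  for (k in 1:255) {
    t <- edges[k + 1]
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    bcv <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (bcv > best[1]) best <- c(bcv, t)
  }
  expect_lt(abs(rec$I_T - best[2]), 10)

  expect_true(sliceThresholdOtsu(matrix(3, 4, 4))$degenerate)
})

test_that("Otsu agrees with an independent implementation on bimodal data", {
  skip_if_not_installed("EBImage")
  set.seed(7)
  slice <- matrix(c(rnorm(5000, 0.2, 0.04), rnorm(5000, 0.7, 0.04)), 100)
  slice[slice < 0] <- 0; slice[slice > 1] <- 1
  ours <- sliceThresholdOtsu(slice)$I_T
  ref <- EBImage::otsu(EBImage::Image(slice), range = range(slice))
  # the between-class variance is nearly flat across the (almost empty)
  # inter-mode valley, so implementations may settle on different points of
  # the plateau; both must fall well inside the valley
  expect_gt(min(ours, ref), 0.32)
  expect_lt(max(ours, ref), 0.58)
})

test_that("noise-only slices are classified as background", {
  set.seed(3)
  noise <- matrix(abs(rnorm(10000, 0, 0.05)), 100, 100)
  expect_true(sliceThresholdOtsu(noise)$degenerate)
  # but genuine sparse signal is kept
  signal <- noise
  signal[1:10, 1:30] <- 1
  expect_false(sliceThresholdOtsu(signal)$degenerate)
})

test_that("binarization is per-slice local and strict at the threshold", {
  set.seed(5)
  arr <- array(runif(6 * 10 * 10), c(6, 10, 10))
  stack <- ImageStack(arr, unit_geom)
  b1 <- binarize(stack, "percentile", v_u = 0.5)
  arr2 <- arr
  arr2[3, , ] <- arr2[3, , ] * 10
  b2 <- binarize(ImageStack(arr2, unit_geom), "percentile", v_u = 0.5)
  other <- setdiff(1:6, 3)
  expect_identical(materialMask(b1$volume)[other, , ],
                   materialMask(b2$volume)[other, , ])

  # uniform stack: threshold equals value, strict '>' leaves no material
  u <- binarize(ImageStack(array(1, c(3, 4, 4)), unit_geom),
                "percentile", v_u = 0.5)
  expect_equal(sum(materialMask(u$volume)), 0)
  expect_true(all(u$thresholds$degenerate))
})

test_that("per-slice thresholds compensate depth-dependent intensity drift", {
  # z-invariant scene: same bright disc in every slice, intensity halved
  # from first to last slice
  base <- matrix(0.05, 40, 40)
  base[15:25, 15:25] <- 1
  arr <- array(0, c(20, 40, 40))
  for (z in 1:20) arr[z, , ] <- base * (1 - 0.5 * (z - 1) / 19)
  b <- binarize(ImageStack(arr, unit_geom), "otsu")
  frac <- apply(materialMask(b$volume), 1, mean)
  expect_lt(max(frac) - min(frac), 0.02)
})

test_that("gaussian blur: identity at width 0, constants invariant, profile
          matches the sampled Gaussian", {
  set.seed(2)
  arr <- array(runif(4 * 8 * 8), c(4, 8, 8))
  stack <- ImageStack(arr, unit_geom)
  expect_equal(intensities(gaussianBlur(stack, 0)), arr)
  cst <- ImageStack(array(3, c(4, 8, 8)), unit_geom)
  expect_equal(intensities(gaussianBlur(cst, 1.5)), array(3, c(4, 8, 8)),
               tolerance = 1e-12)

  # single bright voxel: profile equals the normalized sampled Gaussian
  w <- 1.5
  spike <- array(0, c(21, 21, 21)); spike[11, 11, 11] <- 1
  blurred <- intensities(gaussianBlur(ImageStack(spike, unit_geom), w))
  r <- ceiling(3 * w)
  k <- exp(-0.5 * ((-r:r) / w)^2); k <- k / sum(k)
  for (dist in 0:2) {
    expected <- k[r + 1 + dist] * k[r + 1]^2
    expect_equal(blurred[11, 11, 11 + dist], expected, tolerance = 0.01)
  }
})

test_that("morphological closing bridges gaps below twice the element radius", {
  a <- array(FALSE, c(9, 9, 12))
  a[4:6, 4:6, 2:4] <- TRUE
  a[4:6, 4:6, 7:9] <- TRUE # 2-voxel gap at x = 5:6
  v <- BinaryVolume(a, unit_geom)
  expect_equal(countComponents(materialMask(v)), 2)
  closed <- morphologicalClose(v, c(2, 2, 2))
  expect_equal(countComponents(materialMask(closed)), 1)
  small <- morphologicalClose(v, c(0.5, 0.5, 0.5))
  expect_equal(countComponents(materialMask(small)), 2)
  expect_identical(materialMask(small), a)
})

test_that("closing is extensive and idempotent; convex solids unchanged", {
  cube <- array(FALSE, c(9, 9, 9)); cube[3:7, 3:7, 3:7] <- TRUE
  v <- BinaryVolume(cube, unit_geom)
  expect_identical(materialMask(morphologicalClose(v, c(1, 1, 1))), cube)
  for (seed in 1:3) {
    v <- random_volume(seed, n = 14, close_radius = 0)
    c1 <- morphologicalClose(v, c(1.5, 1.5, 1.5))
    expect_true(all(materialMask(v) <= materialMask(c1))) # extensive
    c2 <- morphologicalClose(c1, c(1.5, 1.5, 1.5))
    expect_identical(materialMask(c1), materialMask(c2)) # idempotent
  }
})

test_that("small-cluster removal follows the fraction-of-total rule", {
  a <- array(FALSE, c(5, 12, 120))
  a[2:4, 2:11, 2:35] <- TRUE # 1020 voxels
  a[2, 2, 110:114] <- TRUE # 5 voxels
  out <- removeSmallClusters(BinaryVolume(a, unit_geom), 0.01)
  expect_equal(out$cluster_sizes, c(1020L, 5L))
  expect_equal(sum(materialMask(out$volume)), 1020)

  # single cluster always survives
  one <- BinaryVolume(array(TRUE, c(3, 3, 3)), unit_geom)
  expect_equal(sum(materialMask(removeSmallClusters(one, 1)$volume)), 27)

  # 600/300/100 with fraction 0.2: only the 100 goes; two labels remain
  b <- array(FALSE, c(8, 15, 40))
  b[2:7, 2:11, 2:11] <- TRUE    # 600
  b[2:7, 2:11, 20:24] <- TRUE   # 300
  b[2:5, 2:6, 30:34] <- TRUE    # 100
  out <- removeSmallClusters(BinaryVolume(b, unit_geom), 0.2)
  expect_equal(out$cluster_sizes, c(600L, 300L, 100L))
  expect_equal(sum(materialMask(out$volume)), 900)
  expect_equal(max(out$labels), 2)

  expect_error(removeSmallClusters(BinaryVolume(b, unit_geom), 1),
               "no structure survives")
})

test_that("hole filling is size-limited and only fills 3D-enclosed voids", {
  cube <- array(FALSE, c(7, 7, 7)); cube[2:6, 2:6, 2:6] <- TRUE
  cav1 <- cube; cav1[4, 4, 4] <- FALSE
  out <- fillHoles(BinaryVolume(cav1, unit_geom), 5)
  expect_identical(materialMask(out), cube)

  cav27 <- array(FALSE, c(9, 9, 9)); cav27[2:8, 2:8, 2:8] <- TRUE
  cav27[4:6, 4:6, 4:6] <- FALSE
  out <- fillHoles(BinaryVolume(cav27, unit_geom), 5)
  expect_identical(materialMask(out), cav27)

  # hollow tube open at both ends: lumen touches the faces, never filled
  tube <- array(FALSE, c(9, 9, 9))
  tube[2:8, 2:8, ] <- TRUE
  tube[4:6, 4:6, ] <- FALSE
  out <- fillHoles(BinaryVolume(tube, unit_geom), 1000)
  expect_identical(materialMask(out), tube)
})

test_that("the preprocessing report reconciles input and output volumes", {
  set.seed(9)
  arr <- array(runif(10 * 20 * 20), c(10, 20, 20))
  arr[4:7, 5:15, 5:15] <- arr[4:7, 5:15, 5:15] + 2
  out <- preprocessVolume(ImageStack(arr, unit_geom), sigma = 3)
  m0 <- materialMask(out$binarized)
  m1 <- materialMask(out$volume)
  expect_length(intersect(out$report$added, out$report$removed), 0)
  expect_setequal(out$report$added, setdiff(which(m1), which(m0)))
  expect_setequal(out$report$removed, setdiff(which(m0), which(m1)))
  expect_equal(nrow(out$report$thresholds), 10)
})

test_that("diagnostic overlays encode material in green and exclusions in red", {
  arr <- array(0, c(3, 4, 4)); arr[2, 2, 2] <- 1; arr[2, 3, 3] <- 0.5
  stack <- ImageStack(arr, unit_geom)
  m <- array(FALSE, c(3, 4, 4)); m[2, 2, 2] <- TRUE
  ov <- binarizationOverlay(stack, BinaryVolume(m, unit_geom))
  expect_equal(ov[2, 2, 2, ], c(0, 1, 0))       # material: green
  expect_equal(ov[2, 3, 3, ], c(0.5, 0, 0))     # bright non-material: red
  expect_equal(ov[1, 1, 1, ], c(0, 0, 0))       # dark voxels stay black

  before <- m
  after <- array(FALSE, c(3, 4, 4)); after[2, 2, 2] <- TRUE
  after[2, 2, 3] <- TRUE
  d <- preprocessDiffOverlay(BinaryVolume(before, unit_geom),
                             BinaryVolume(after, unit_geom))
  expect_equal(d[2, 2, 2, ], c(1, 1, 1)) # unchanged: white
  expect_equal(d[2, 2, 3, ], c(0, 1, 0)) # added: green
})
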