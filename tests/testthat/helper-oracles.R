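# Shared fixtures and independent oracles for the test suite. The oracles
# are deliberately naive (cell-set enumeration, pairwise flood fill) so they
# share no code with the package implementations they check.

unit_geom <- VoxelGeometry(1, 1, 1, "sigma")

# Euler characteristic by explicit enumeration of the cubical-complex cells
# of every foreground voxel (vertices - edges + faces - cubes), using string
# keys: slow, brute force, independent of the package's array-shift version.
naive_chi <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  cells <- new.env(hash = TRUE)
  for (r in seq_len(nrow(w))) {
    z <- w[r, 1]; y <- w[r, 2]; x <- w[r, 3]
    for (az in 0:2) for (ay in 0:2) for (ax in 0:2) {
      key <- paste(2 * z + az, 2 * y + ay, 2 * x + ax)
      assign(key, c(az %% 2, ay %% 2, ax %% 2), envir = cells)
    }
  }
  chi <- 0L
  for (key in ls(cells)) {
    odd <- sum(as.integer(strsplit(key, " ")[[1]]) %% 2)
    chi <- chi + if (odd %% 2 == 0) 1L else -1L
  }
  chi
}

# straight voxel line along an axis inside an array
line_volume <- function(n = 11, shape = c(3, 3, n)) {
  a <- array(FALSE, shape)
  a[2, 2, seq_len(n)] <- TRUE
  a
}

# three-armed junction drawn as thin voxel lines meeting at a centre
y_skeleton <- function(arm = 10, pad = 2) {
  side <- 2 * (arm + pad) + 1
  c0 <- arm + pad + 1
  a <- array(FALSE, c(5, side, side))
  a[3, c0, c0:(c0 + arm)] <- TRUE
  a[3, c0, (c0 - arm):c0] <- TRUE
  a[3, c0:(c0 + arm), c0] <- TRUE
  a
}

# closed diamond ring of 20 voxels in a plane: every voxel has exactly two
# (diagonal) neighbours, so the ring is a clean single-voxel cycle (an
# axis-aligned square ring is not: its corner-adjacent voxels see each other
# diagonally and classify as branch voxels)
ring_volume <- function() {
  a <- array(FALSE, c(3, 13, 13))
  for (dy in -5:5) {
    dx <- 5 - abs(dy)
    a[2, 7 + dy, 7 + dx] <- TRUE
    a[2, 7 + dy, 7 - dx] <- TRUE
  }
  a
}

# a random test volume of the kind used in the thinning robustness checks
random_volume <- function(seed, n = 16, fill = 0.3, close_radius = 1) {
  set.seed(seed)
  a <- array(stats::runif(n^3) < fill, c(n, n, n))
  v <- BinaryVolume(a, unit_geom)
  if (close_radius > 0) v <- morphologicalClose(v, rep(close_radius, 3))
  v
}

# full image-stack pipeline used by the phantom recovery checks
run_stack_pipeline <- function(stack, sigma = 1, margin = 0) {
  pre <- preprocessVolume(stack, sigma = sigma, method = "otsu")
  sk <- thinVolume(pre$volume)
  gr <- cleanGraph(extractGraph(sk, sigma = sigma))
  csk <- graphToSkeleton(gr, stackDim(sk))
  list(graph = gr, skeleton = csk,
       report = analyzeNetwork(gr, csk, margin = margin))
}
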