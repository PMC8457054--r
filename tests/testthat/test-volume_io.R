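test_that("TIFF stacks round-trip losslessly for 8- and 16-bit data", {
  geom <- VoxelGeometry(0.1, 0.1, 0.2, "um")
  for (mx in c(255, 65535)) {
    set.seed(1)
    arr <- array(sample(0:mx, 5 * 6 * 7, replace = TRUE), c(5, 6, 7))
    stack <- ImageStack(arr, geom)
    path <- tempfile(fileext = ".tif")
    writeStack(stack, path)
    back <- readStack(path, geom)
    expect_identical(stackDim(back), c(5L, 6L, 7L))
    expect_equal(intensities(back), intensities(stack))
  }
})

test_that("all-zero and binary stacks read back as written", {
  geom <- unit_geom
  path <- tempfile(fileext = ".tif")
  writeStack(ImageStack(array(0, c(3, 4, 4)), geom), path)
  expect_true(all(intensities(readStack(path, geom)) == 0))

  # one material voxel -> exactly one 255 pixel
  v <- array(FALSE, c(3, 4, 4)); v[2, 2, 3] <- TRUE
  writeStack(BinaryVolume(v, geom), path)
  back <- intensities(readStack(path, geom))
  expect_equal(sum(back == 255), 1)
  expect_equal(sum(back), 255)
})

test_that("RGB pages are rejected with the page named", {
  path <- tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, c(4, 4, 3)), path)
  expect_error(readStack(path, unit_geom), "page 1")
})

test_that("coordinate tables parse whitespace, commas and comments", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("# a comment", "0 0 0", "5 0 0"), path)
  ps <- readCoordinates(path, sigma = 1)
  expect_equal(nrow(particlePositions(ps)), 2)
  expect_equal(boundingBox(ps)["min", "x"], 0)
  expect_equal(boundingBox(ps)["max", "x"], 5)

  writeLines("1.5, 2.5, 3.5", path)
  ps <- readCoordinates(path, sigma = 1)
  expect_equal(unname(particlePositions(ps)[1, ]), c(1.5, 2.5, 3.5))
})

test_that("coordinate parse errors carry the line number", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("1 2 3", "4 5"), path)
  expect_error(readCoordinates(path, 1), "line 2")
  writeLines(c("1 2 3", "4 x 6"), path)
  expect_error(readCoordinates(path, 1), "line 2")
  writeLines("# only a comment", path)
  expect_error(readCoordinates(path, 1), "no particles")
})

test_that("coordinate write/read round-trips", {
  ps <- ParticleSet(matrix(c(0.25, 1, 2, 3.5, 4, 5), 2, 3, byrow = TRUE),
                    sigma = 1)
  path <- tempfile(fileext = ".txt")
  writeCoordinates(ps, path)
  back <- readCoordinates(path, sigma = 1)
  expect_equal(particlePositions(back), particlePositions(ps))
})

test_that("default PSF is normalized, centred and anisotropic as requested", {
  geom <- unit_geom
  psf <- defaultPSF(geom, sigma_xy = 1.2, sigma_z = 2.4)
  expect_equal(sum(psf@weights), 1, tolerance = 1e-12)
  expect_true(all(dim(psf@weights) %% 2 == 1))
  # axial extent about twice the lateral extent
  above <- which(psf@weights > 1e-6, arr.ind = TRUE)
  z_ext <- diff(range(above[, 1])) + 1
  x_ext <- diff(range(above[, 3])) + 1
  expect_gt(z_ext / x_ext, 1.6)
  expect_lt(z_ext / x_ext, 2.4)

  # delta limit: widths far below the voxel collapse to one voxel
  expect_warning(tiny <- defaultPSF(geom, 1e-4, 1e-4), "delta")
  expect_equal(dim(tiny@weights), c(3L, 3L, 3L))
  expect_equal(max(tiny@weights), 1)
})

test_that("sphere rendering is binary, permutation-invariant and shifts with
          integer voxel translations", {
  geom <- VoxelGeometry(0.1, 0.1, 0.1, "um")
  box <- rbind(c(0, 0, 0), c(3, 3, 3))
  p1 <- ParticleSet(rbind(c(1.5, 1.5, 1.5), c(1.9, 1.5, 1.5)), 1, box)
  img <- projectParticles(p1, geom, pad = 0)
  expect_true(all(intensities(img) %in% c(0, 1)))
  # centre voxel of a particle is lit
  expect_equal(intensities(img)[15, 15, 15], 1)
  # overlapping spheres form one component
  expect_equal(countComponents(intensities(img) > 0), 1)

  p2 <- ParticleSet(rbind(c(1.9, 1.5, 1.5), c(1.5, 1.5, 1.5)), 1, box)
  expect_identical(intensities(projectParticles(p2, geom, pad = 0)),
                   intensities(img))

  shift <- c(0.5, 0.3, -0.2) # 5, 3, -2 voxels
  p3 <- ParticleSet(sweep(particlePositions(p1), 2, shift, "+"), 1, box)
  a <- intensities(img)
  b <- intensities(projectParticles(p3, geom, pad = 0))
  idx <- 5:24
  expect_identical(b[idx - 2, idx + 3, idx + 5], a[idx, idx, idx])
})

test_that("digital ball size matches the particle diameter", {
  geom <- VoxelGeometry(0.1, 0.1, 0.1, "um")
  ps <- ParticleSet(matrix(c(1.5, 1.5, 1.5), 1), 1,
                    rbind(c(0, 0, 0), c(3, 3, 3)))
  img <- intensities(projectParticles(ps, geom, pad = 0))
  on_axis <- img[15, 15, ]
  expect_equal(sum(on_axis), 10) # ~10 voxels across for sigma/dx = 10
})

test_that("PSF convolution conserves total intensity before rescaling", {
  geom <- VoxelGeometry(0.1, 0.1, 0.1, "um")
  ps <- ParticleSet(matrix(c(1.5, 1.5, 1.5), 1), 1,
                    rbind(c(0, 0, 0), c(3, 3, 3)))
  binary <- intensities(projectParticles(ps, geom, pad = 0))
  psf <- defaultPSF(geom, 0.1, 0.15)
  conv <- netskel:::fftConvolve3d(binary, psf@weights)
  expect_equal(sum(conv), sum(binary), tolerance = 1e-9)
})
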