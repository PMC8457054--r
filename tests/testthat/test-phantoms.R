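test_that("tube phantoms carry verified simply-connected ground truth", {
  tb <- makeTube(20, 3, "x")
  expect_equal(countComponents(materialMask(tb$volume)), 1)
  expect_equal(eulerCharacteristic(materialMask(tb$volume)), 1)
  expect_equal(tb$truth$n_nodes, 2L)
  expect_equal(tb$truth$n_links, 1L)

  # radius 0: already a single-voxel-thin line
  thin <- makeTube(9, 0, "z")
  m <- materialMask(thin$volume)
  expect_equal(sum(m), 9)
  expect_identical(m, materialMask(thinVolume(thin$volume)))
})

test_that("arc phantom ground truth matches the analytic arc length", {
  arc <- makeArc(arc_radius = 20, angle = pi / 2, thickness = 2)
  expect_equal(arc$truth$arc_length, pi / 2 * 20)
  sk <- thinVolume(arc$volume)
  gr <- cleanGraph(extractGraph(sk, sigma = 4))
  expect_equal(nrow(networkLinks(gr)), 1)
  # skeleton length close to the analytic arc length (discretization slack)
  expect_lt(abs(networkLinks(gr)$length - arc$truth$arc_length) /
              arc$truth$arc_length, 0.1)
})

test_that("junction phantoms encode raw and cleaned truth", {
  arms3 <- list(list(direction = c(1, 0, 0), length = 12),
                list(direction = c(-1, 0, 0), length = 12),
                list(direction = c(0, 1, 0), length = 12))
  j3 <- makeJunction(arms3, radius = 2, sigma = 4)
  expect_equal(j3$truth$n_nodes, 4L)
  expect_equal(j3$truth$n_links, 3L)
  expect_equal(j3$truth$clean_n_nodes, 4L)

  arms4 <- c(arms3, list(list(direction = c(0, -1, 0), length = 12)))
  j4 <- makeJunction(arms4, radius = 2, sigma = 4)
  expect_equal(j4$truth$n_links / j4$truth$n_nodes, 4 / 5)

  # arms of 5, 5 and 1 sigma: cleaned truth collapses to one through link
  arms_spur <- list(list(direction = c(1, 0, 0), length = 20),
                    list(direction = c(-1, 0, 0), length = 20),
                    list(direction = c(0, 1, 0), length = 4))
  js <- makeJunction(arms_spur, radius = 2, sigma = 4)
  expect_equal(js$truth$clean_n_nodes, 2L)
  expect_equal(js$truth$clean_n_links, 1L)
  expect_error(makeJunction(arms3[1:2]), "3 arms")
})

test_that("torus phantoms have chi 0 and compose additively", {
  tor <- makeTorus(8, 2)
  m <- materialMask(tor$volume)
  expect_equal(eulerCharacteristic(m), 0)
  expect_equal(countComponents(m), 1)
  # two disjoint tori: chi stays 0, components add
  d <- dim(m)
  both <- array(FALSE, c(d[1], d[2], 2 * d[3] + 3))
  both[, , seq_len(d[3])] <- m
  both[, , d[3] + 3 + seq_len(d[3])] <- m
  expect_equal(eulerCharacteristic(both), 0)
  expect_equal(countComponents(both), 2)
  expect_error(makeTorus(5, 6), "smaller")
})

test_that("bead networks are reproducible and geometrically consistent", {
  bn1 <- makeBeadNetwork(n_nodes = 30, box_size = 16, seed = 5)
  bn2 <- makeBeadNetwork(n_nodes = 30, box_size = 16, seed = 5)
  expect_identical(particlePositions(bn1$particles),
                   particlePositions(bn2$particles))
  expect_identical(bn1$truth$edges, bn2$truth$edges)

  pos <- bn1$truth$nodes
  ee <- bn1$truth$edges
  # node separation and edge lengths respect the generator constraints
  expect_gte(min(dist(pos)), 3.5)
  expect_lt(max(ee[, "length"]), 8)
  deg <- tabulate(c(ee[, 1], ee[, 2]), nbins = nrow(pos))
  expect_lte(max(deg), 3)
  # one connected component
  g <- igraph::graph_from_edgelist(ee[, 1:2], directed = FALSE)
  expect_equal(igraph::count_components(g), 1)
  # beads lie inside the imaging box
  b <- particlePositions(bn1$particles)
  expect_true(all(b >= 0 & b <= 16))
  expect_error(makeBeadNetwork(bead_spacing = 1.5), "contiguous")
})

test_that("bead spacing lays overlapping beads along every edge", {
  bn <- makeBeadNetwork(n_nodes = 30, box_size = 16, seed = 5,
                        bead_spacing = 0.5)
  b <- particlePositions(bn$particles)
  # nearest-neighbour distance of interior beads never exceeds the spacing
  d <- as.matrix(dist(b))
  diag(d) <- Inf
  expect_lte(max(apply(d, 1, min)), 0.5 + 1e-6)
})

test_that("the corruption model applies drift then noise with clipping", {
  arr <- array(1, c(100, 6, 6))
  stack <- ImageStack(arr, unit_geom)
  # identity with no noise and no drift
  same <- corruptStack(stack, noise_sd = 0, drift_per_slice = 0, seed = 1)
  expect_identical(intensities(same), arr)
  # drift: last slice mean ~ 0.8x the first for 100 slices at 0.002/slice
  drifted <- corruptStack(stack, noise_sd = 0, drift_per_slice = 0.002,
                          seed = 1)
  expect_equal(mean(intensities(drifted)[100, , ]) /
                 mean(intensities(drifted)[1, , ]), 0.802, tolerance = 1e-9)
  # noise: per-voxel residual sd close to the requested value
  big <- ImageStack(array(10, c(40, 40, 40)), unit_geom)
  noisy <- corruptStack(big, noise_sd = 0.3, drift_per_slice = 0, seed = 2)
  res <- intensities(noisy) - 10
  expect_lt(abs(sd(res) - 0.3) / 0.3, 0.05)
  # reproducibility
  noisy2 <- corruptStack(big, noise_sd = 0.3, drift_per_slice = 0, seed = 2)
  expect_identical(intensities(noisy), intensities(noisy2))
})
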