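mk_point_graph <- function(pos, links = NULL, sigma = 1, box_max = 10) {
  n <- nrow(pos)
  nodes <- data.frame(id = seq_len(n), kind = rep("end", n),
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      degree = integer(n), cycle_anchor = rep(FALSE, n),
                      stringsAsFactors = FALSE)
  vox <- lapply(seq_len(n), function(i)
    matrix(pmax(1, round(c(pos[i, 3], pos[i, 2], pos[i, 1]) + 0.5)), 1, 3,
           dimnames = list(NULL, c("z", "y", "x"))))
  if (is.null(links)) {
    ldf <- netskel:::.empty_links()
    paths <- list()
  } else {
    ldf <- data.frame(id = seq_len(nrow(links)), node_a = links[, 1],
                      node_b = links[, 2], length = links[, 3], n_path = 2L)
    paths <- lapply(seq_len(nrow(links)), function(k)
      rbind(vox[[links[k, 1]]], vox[[links[k, 2]]]))
  }
  g <- new("NetworkGraph", nodes = nodes, nodeVoxels = vox, links = ldf,
           paths = paths, geometry = unit_geom,
           box = rbind(min = c(x = 0, y = 0, z = 0),
                       max = c(x = box_max, y = box_max, z = box_max)),
           sigma = sigma)
  g@nodes$degree <- netskel:::.node_degrees(g@nodes, g@links)
  g
}

test_that("network summary divides interior counts by the shrunken volume", {
  pos <- rbind(c(3, 3, 3), c(6, 3, 3), c(3, 6, 3), c(3, 3, 6), # interior
               c(0.5, 5, 5)) # inside the 2-margin shell
  links <- rbind(c(1, 2, 3), c(1, 3, 3), c(1, 4, 3), c(1, 5, 3))
  gr <- mk_point_graph(pos, links, sigma = 1, box_max = 10)
  s <- summarizeNetwork(gr, margin = 2)
  expect_equal(s$N_N, 4)
  expect_equal(s$N_L, 3) # the link into the shell is excluded
  expect_equal(s$analysis_volume, 6^3)
  expect_equal(s$rho_N, 4 / 216)
  expect_equal(s$rho_L, 3 / 216)
  expect_equal(s$links_per_node, 0.75)
})

test_that("density unit conversion scales with sigma cubed", {
  pos <- rbind(c(3, 3, 3), c(6, 3, 3))
  gr <- mk_point_graph(pos, rbind(c(1, 2, 3)), sigma = 2, box_max = 10)
  s <- summarizeNetwork(gr, margin = 0)
  expect_equal(s$rho_N_sigma, s$rho_N * 8)
  expect_equal(s$rho_L_sigma, s$rho_L * 8)
})

test_that("a node exactly on a face is included at margin 0", {
  pos <- rbind(c(0, 5, 5), c(10, 5, 5))
  gr <- mk_point_graph(pos, NULL, box_max = 10)
  s <- summarizeNetwork(gr, margin = 0)
  expect_equal(s$N_N, 2)
  # and links_per_node is flagged missing when no node survives
  empty <- mk_point_graph(pos[0, , drop = FALSE])
  s0 <- summarizeNetwork(empty, margin = 0)
  expect_true(is.na(s0$links_per_node))
})

test_that("link-length histogram is a normalized density", {
  pos <- rbind(c(1, 1, 1), c(2, 1, 1), c(3, 1, 1), c(4, 1, 1),
               c(5, 1, 1), c(6, 1, 1))
  links <- rbind(c(1, 2, 1), c(3, 4, 1), c(5, 6, 3))
  gr <- mk_point_graph(pos, links)
  h <- linkLengthHistogram(gr, bins = c(0, 2, 4))
  expect_equal(h$counts, c(2L, 1L))
  expect_equal(h$normalized, c(1 / 3, 1 / 6))
  expect_equal(sum(h$normalized * diff(h$bin_edges)), 1)
  expect_equal(sum(h$counts), 3)

  set.seed(4)
  lens <- rexp(400, rate = 0.5) + 0.01
  n <- length(lens) + 1
  pos2 <- cbind(seq_len(n) * 0.001, 1, 1)
  links2 <- cbind(seq_len(n - 1), 2:n, lens)
  gr2 <- mk_point_graph(pos2, links2)
  h2 <- linkLengthHistogram(gr2, bins = 30)
  expect_equal(sum(h2$normalized * diff(h2$bin_edges)), 1, tolerance = 1e-9)
  expect_equal(sum(h2$counts), 400)

  expect_true(linkLengthHistogram(mk_point_graph(pos[0, , drop = FALSE]))$empty)
})

test_that("straight spanning lines have tortuosity exactly 1", {
  a <- array(FALSE, c(11, 5, 5))
  a[1:11, 3, 3] <- TRUE
  sk <- Skeleton(a, unit_geom)
  tr <- tortuosity(NULL, sk, face_margin = 1)
  expect_equal(tr$xi_mean, 1)
  expect_true(tr$percolating)

  # two disjoint spanning lines: mean 1, sd 0
  b <- a; b[1:11, 5, 5] <- TRUE
  tr2 <- tortuosity(NULL, Skeleton(b, unit_geom), face_margin = 1)
  expect_equal(tr2$xi_mean, 1)
  expect_equal(tr2$xi_std, 0)
  expect_equal(tr2$n_paths, 2)
})

test_that("non-percolating skeletons are flagged", {
  a <- array(FALSE, c(9, 9, 9))
  a[4:6, 5, 5] <- TRUE # short interior stick
  tr <- tortuosity(NULL, Skeleton(a, unit_geom), face_margin = 0.5)
  expect_false(tr$percolating)
  expect_true(is.na(tr$xi_mean))
})

test_that("a discretized semicircle has tortuosity close to pi/2", {
  arc <- makeArc(arc_radius = 30, angle = pi, thickness = 2)
  sk <- thinVolume(arc$volume)
  gr <- cleanGraph(extractGraph(sk, sigma = 4))
  tr <- tortuosity(gr, sk)
  expect_equal(tr$n_paths, 1)
  expect_lt(abs(tr$xi_mean - pi / 2) / (pi / 2), 0.05)
})

test_that("intensive statistics are unchanged when the system is doubled", {
  one <- array(FALSE, c(11, 7, 7)); one[1:11, 4, 4] <- TRUE
  two <- array(FALSE, c(11, 7, 14))
  two[1:11, 4, 4] <- TRUE; two[1:11, 4, 11] <- TRUE
  g1 <- cleanGraph(extractGraph(Skeleton(one, unit_geom), sigma = 1))
  g2 <- cleanGraph(extractGraph(Skeleton(two, unit_geom), sigma = 1))
  s1 <- summarizeNetwork(g1, margin = 0)
  s2 <- summarizeNetwork(g2, margin = 0)
  expect_equal(s2$rho_N, s1$rho_N)
  expect_equal(s2$rho_L, s1$rho_L)
  t1 <- tortuosity(g1, Skeleton(one, unit_geom), face_margin = 1)
  t2 <- tortuosity(g2, Skeleton(two, unit_geom), face_margin = 1)
  expect_equal(t1$xi_mean, t2$xi_mean)
})

test_that("analyzeNetwork bundles summary, histogram and tortuosity", {
  sky <- Skeleton(y_skeleton(arm = 8), unit_geom)
  gr <- cleanGraph(extractGraph(sky, sigma = 1))
  rep <- analyzeNetwork(gr, sky, margin = 0)
  expect_equal(rep$summary$links_per_node, 0.75)
  expect_equal(sum(rep$histogram$counts), rep$summary$N_L)
  expect_equal(nrow(rep$components), 1)

  empty <- extractGraph(Skeleton(array(FALSE, c(3, 3, 3)), unit_geom),
                        sigma = 1)
  rep0 <- analyzeNetwork(empty, NULL, margin = 0)
  expect_equal(rep0$summary$N_N, 0)
  expect_true(rep0$histogram$empty)
})
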