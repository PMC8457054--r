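# Synthetic phantoms with known ground-truth topology: solid tubes, arcs,
# junctions, tori, and beads-on-a-graph gel networks, plus an imaging
# corruption model (per-slice intensity drift + additive noise). Every
# solid phantom's ground truth (component count, Euler characteristic) is
# verified at generation time against the whole-volume topology oracle.

.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.unit_geom <- function() VoxelGeometry(1, 1, 1, "sigma")

.verify_truth <- function(mask, truth) {
  comp <- countComponents(mask, 26)
  chi <- eulerCharacteristic(mask)
  if (!is.null(truth$components) && comp != truth$components)
    stop("phantom ground truth violated: expected ", truth$components,
         " component(s), found ", comp)
  if (!is.null(truth$chi) && chi != truth$chi)
    stop("phantom ground truth violated: expected chi = ", truth$chi,
         ", found ", chi)
  invisible(TRUE)
}

# mark all voxels whose centre lies within `radius` of the segment p-q
# (voxel units); returns a logical array of dim `shape`
.paint_capsule <- function(arr, p, q, radius) {
  n <- dim(arr)
  lo <- pmax(1, floor(pmin(p, q) - radius - 1))
  hi <- pmin(c(n[3], n[2], n[1]), ceiling(pmax(p, q) + radius + 1))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  cx <- xs - 0.5; cy <- ys - 0.5; cz <- zs - 0.5
  v <- q - p
  L2 <- sum(v^2)
  # distance from voxel centre to the segment
  gx <- array(rep(cx, each = length(zs) * length(ys)),
              c(length(zs), length(ys), length(xs)))
  gy <- array(rep(rep(cy, each = length(zs)), length(xs)),
              c(length(zs), length(ys), length(xs)))
  gz <- array(rep(cz, length(ys) * length(xs)),
              c(length(zs), length(ys), length(xs)))
  if (L2 == 0) {
    t <- 0
    d2 <- (gx - p[1])^2 + (gy - p[2])^2 + (gz - p[3])^2
  } else {
    t <- ((gx - p[1]) * v[1] + (gy - p[2]) * v[2] + (gz - p[3]) * v[3]) / L2
    t[t < 0] <- 0; t[t > 1] <- 1
    d2 <- (gx - (p[1] + t * v[1]))^2 + (gy - (p[2] + t * v[2]))^2 +
      (gz - (p[3] + t * v[3]))^2
  }
  sub <- arr[zs, ys, xs, drop = FALSE]
  dim(sub) <- dim(d2)
  sub <- sub | (d2 <= radius^2 + 1e-9)
  arr[zs, ys, xs] <- sub
  arr
}

#' Solid tube phantom
#'
#' A solid digital cylinder along one axis, centred in the volume. Ground
#' truth: one simply connected component (chi = 1), skeletonizing to a
#' single path with 2 end nodes and one link of approximately the axis
#' length. \code{radius = 0} produces a single-voxel-thin line (already a
#' skeleton).
#'
#' @param length axis length in voxels.
#' @param radius tube radius in voxels (0 for a thin line).
#' @param axis \code{"x"}, \code{"y"} or \code{"z"}.
#' @param shape grid dimensions (nz, ny, nx); the tube must fit.
#' @return list with \code{volume} (a \code{BinaryVolume}, unit isotropic
#'   voxels in sigma units) and \code{truth} (list: \code{components},
#'   \code{chi}, \code{n_nodes}, \code{n_links}, \code{length}).
#' @export
makeTube <- function(length, radius, axis = "x", shape = NULL) {
  margin <- ceiling(radius) + 3
  alen <- ceiling(length)
  if (is.null(shape)) {
    # flush along the tube axis (caps clipped at the box faces, as a strand
    # crossing the imaging window would be), padded transversally
    shape <- switch(axis,
                    x = c(2 * margin + 1, 2 * margin + 1, alen),
                    y = c(2 * margin + 1, alen, 2 * margin + 1),
                    z = c(alen, 2 * margin + 1, 2 * margin + 1))
  }
  n <- shape
  ctr <- c(n[3], n[2], n[1]) / 2 # (x, y, z) voxel units
  dirv <- switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  ext <- c(n[3], n[2], n[1])[dirv == 1]
  p <- ctr * (1 - dirv) + (ext - length) / 2 * dirv
  q <- ctr * (1 - dirv) + (ext + length) / 2 * dirv
  tr <- (ctr * (1 - dirv))[(1 - dirv) == 1]
  if (any(tr - radius < 0))
    stop("tube does not fit in the requested shape")
  arr <- array(FALSE, n)
  arr <- .paint_capsule(arr, p, q, max(radius, 1e-6))
  # expected backbone length in the voxel-centre metric: an L-voxel-long
  # straight skeleton has L - 1 unit steps between voxel centres
  truth <- list(components = 1L, chi = 1L, n_nodes = 2L, n_links = 1L,
                length = alen - 1)
  .verify_truth(arr, truth)
  list(volume = BinaryVolume(arr, .unit_geom()), truth = truth)
}

#' Solid circular-arc tube phantom
#'
#' A solid tube bent along a circular arc in the xy-plane (constant z),
#' spanning the given angle. A half-turn (\code{angle = pi}) spans the box
#' along x with chord equal to the diameter, so the true tortuosity of the
#' centreline is pi/2. Ground truth arc length is \code{angle * arc_radius}.
#'
#' @param arc_radius radius of curvature of the centreline, in voxels.
#' @param angle swept angle in radians (default \code{pi}: a semicircle).
#' @param thickness tube radius in voxels.
#' @return list with \code{volume} and \code{truth} (\code{components},
#'   \code{chi}, \code{arc_length}, \code{chord}).
#' @export
makeArc <- function(arc_radius, angle = pi, thickness = 2) {
  pad <- ceiling(thickness) + 3
  # centreline: (R sin t, R cos t) for t in [-angle/2, angle/2]
  tseq <- seq(-angle / 2, angle / 2, length.out = max(64, ceiling(
    angle * arc_radius * 4)))
  px <- arc_radius * sin(tseq)
  py <- arc_radius * cos(tseq)
  # flush along x (the chord axis), so the arc spans the box; padded in y, z
  x0 <- min(px); y0 <- min(py) - pad
  nx <- ceiling(max(px) - min(px))
  ny <- ceiling(max(py) - min(py)) + 2 * pad
  nz <- 2 * pad + 1
  arr <- array(FALSE, c(nz, ny, nx))
  zc <- nz / 2
  for (i in seq_len(length(tseq) - 1)) {
    p <- c(px[i] - x0, py[i] - y0, zc)
    q <- c(px[i + 1] - x0, py[i + 1] - y0, zc)
    arr <- .paint_capsule(arr, p, q, max(thickness, 1e-6))
  }
  truth <- list(components = 1L, chi = 1L, arc_length = angle * arc_radius,
                chord = 2 * arc_radius * sin(angle / 2))
  .verify_truth(arr, truth)
  list(volume = BinaryVolume(arr, .unit_geom()), truth = truth)
}

#' Junction phantom
#'
#' Solid arms radiating from a central point. Ground truth (before
#' cleaning): one branching node, plus one end node and one link per arm.
#' The cleaned truth applies the standard cleaning cascade at the given
#' sigma: arms shorter than \code{1.5 * sigma} are pruned; if only two arms
#' survive, the junction becomes a canal node and is merged away.
#'
#' @param arms list of arms, each \code{list(direction = unit 3-vector
#'   (x, y, z), length = voxels)}; at least 3.
#' @param radius arm radius in voxels.
#' @param sigma particle diameter in voxels (for the cleaned truth).
#' @return list with \code{volume} and \code{truth} (\code{n_nodes},
#'   \code{n_links}, plus \code{clean_n_nodes}, \code{clean_n_links}).
#' @export
makeJunction <- function(arms, radius = 2, sigma = 4) {
  if (length(arms) < 3) stop("a junction needs at least 3 arms")
  maxlen <- max(vapply(arms, function(a) a$length, 0))
  pad <- ceiling(maxlen + radius) + 3
  n <- rep(2 * pad + 1, 3)
  ctr <- rep(pad + 0.5, 3)
  arr <- array(FALSE, n)
  for (a in arms) {
    dirv <- a$direction / sqrt(sum(a$direction^2))
    arr <- .paint_capsule(arr, ctr, ctr + a$length * dirv,
                          max(radius, 1e-6))
  }
  kept <- vapply(arms, function(a) a$length >= 1.5 * sigma, TRUE)
  nk <- sum(kept)
  clean_counts <- if (nk >= 3) c(nk + 1L, nk)
  else if (nk == 2) c(2L, 1L)
  else if (nk == 1) c(2L, 1L)
  else c(0L, 0L)
  truth <- list(components = 1L, chi = 1L,
                n_nodes = length(arms) + 1L, n_links = length(arms),
                clean_n_nodes = clean_counts[1],
                clean_n_links = clean_counts[2])
  .verify_truth(arr, truth)
  list(volume = BinaryVolume(arr, .unit_geom()), truth = truth)
}

#' Solid torus phantom
#'
#' A solid torus around the z axis. Ground truth: one component, one tunnel,
#' no cavity, so chi = 0; the skeleton is a single closed cycle with no end
#' points.
#'
#' @param major_radius centreline radius in voxels.
#' @param minor_radius tube radius in voxels (must be < major_radius);
#'   0 gives an already-thin voxel ring.
#' @return list with \code{volume} and \code{truth}.
#' @export
makeTorus <- function(major_radius, minor_radius) {
  if (minor_radius >= major_radius)
    stop("minor radius must be smaller than the major radius")
  pad <- ceiling(minor_radius) + 3
  nxy <- ceiling(2 * (major_radius + minor_radius)) + 2 * pad
  nz <- 2 * pad + ceiling(2 * minor_radius) + 1
  arr <- array(FALSE, c(nz, nxy, nxy))
  ctr <- c(nxy / 2, nxy / 2, nz / 2)
  tseq <- seq(0, 2 * pi, length.out = max(64, ceiling(
    2 * pi * major_radius * 4)))
  for (i in seq_len(length(tseq) - 1)) {
    p <- ctr + c(major_radius * cos(tseq[i]), major_radius * sin(tseq[i]), 0)
    q <- ctr + c(major_radius * cos(tseq[i + 1]),
                 major_radius * sin(tseq[i + 1]), 0)
    arr <- .paint_capsule(arr, p, q, max(minor_radius, 1e-6))
  }
  truth <- list(components = 1L, chi = 0L, n_end_points = 0L)
  .verify_truth(arr, truth)
  list(volume = BinaryVolume(arr, .unit_geom()), truth = truth)
}

# minimum distance between two segments p1-q1 and p2-q2, each restricted to
# the parameter range [t0, 1] measured away from a shared endpoint
.seg_seg_dist <- function(p1, q1, p2, q2, nt = 21) {
  t <- seq(0, 1, length.out = nt)
  a <- p1 %o% (1 - t) + q1 %o% t # 3 x nt
  b <- p2 %o% (1 - t) + q2 %o% t
  d2 <- outer(colSums(a^2), rep(1, nt)) + outer(rep(1, nt), colSums(b^2)) -
    2 * crossprod(a, b)
  sqrt(max(0, min(d2)))
}

.point_seg_dist <- function(x, p, q) {
  v <- q - p
  L2 <- sum(v^2)
  t <- if (L2 == 0) 0 else max(0, min(1, sum((x - p) * v) / L2))
  sqrt(sum((x - p - t * v)^2))
}

#' Beads-on-a-graph gel network phantom
#'
#' Emulates a particulate gel strand network cropped by an imaging window.
#' Node positions are sampled in a region extending \code{ext} beyond the
#' box on every side (so strands genuinely cross the box faces, as in a real
#' image of a larger gel), with a minimum mutual distance. Candidate edges
#' connect nodes closer than \code{cutoff}; edges are accepted greedily
#' (shortest first) only if the new strand keeps a physical clearance from
#' all non-endpoint nodes and previously accepted strands, and makes an
#' angle of at least \code{min_angle} degrees with strands sharing an
#' endpoint, while keeping every node at degree \code{max_degree} or below.
#' Crossing or hugging strands would fuse in the rendered image; moreover,
#' the medial axis of two sigma-thick strands crossing at angle theta splits
#' into two branch points roughly sigma/tan(theta/2) apart, so 4-fold
#' junctions do not reduce to a single branch point at the standard
#' 0.9 sigma node-collection scale -- the generator therefore emits the
#' 3-fold junctions that dominate dilute gels. The network is restricted to
#' its largest connected
#' component and beads of diameter sigma are laid along every edge at
#' \code{bead_spacing}; beads outside the box are cropped away.
#'
#' The ground truth carries the generated graph after standard cleaning
#' (degree-2 nodes of the generated topology are canal nodes and merge, so
#' the cleaned counts are the reference for pipeline recovery); its box slot
#' is the imaging box, so \code{\link{summarizeNetwork}} with a margin gives
#' directly comparable interior counts.
#'
#' All lengths are in units of the particle diameter sigma.
#'
#' @param n_nodes number of candidate nodes sampled.
#' @param box_size cubic imaging-box edge length (sigma units).
#' @param cutoff maximum strand length between connected nodes (default 7).
#' @param bead_spacing spacing of beads along edges (default 0.5; must be
#'   <= 1 so that consecutive beads overlap).
#' @param min_node_dist minimum distance between sampled nodes (default 3.5,
#'   so junction blobs stay well separated at strand-width resolution).
#' @param clearance minimum distance between a strand and non-incident
#'   nodes/strands (default 2.2).
#' @param min_angle minimum angle in degrees between strands sharing a node
#'   (default 50).
#' @param max_degree maximum node degree (default 3).
#' @param ext sampling extension beyond each box face (default 4).
#' @param face_gap exclusion band just outside each face (default 2.5): no
#'   node may sit between a face and \code{face_gap} beyond it. Two strands
#'   leaving a shared node are fused (their surfaces closer than the closing
#'   scale) out to roughly (1.5 sigma)/(2 sin(min_angle/2)) from the node;
#'   an invisible junction that close behind a face would poke a fused
#'   phantom junction into the image that the geometric ground truth cannot
#'   account for.
#' @param seed integer seed; generation is fully reproducible.
#' @return list with \code{particles} (a \code{ParticleSet}, sigma = 1,
#'   box = the imaging box) and \code{truth} (list: \code{nodes},
#'   \code{edges}, \code{n_nodes}, \code{n_links}, \code{clean_n_nodes},
#'   \code{clean_n_links}, \code{graph} (the cleaned true
#'   \code{NetworkGraph}, box = the imaging box)).
#' @export
makeBeadNetwork <- function(n_nodes = 50, box_size = 20, cutoff = 8,
                            bead_spacing = 0.5, min_node_dist = 3.5,
                            clearance = 2.2, min_angle = 50, max_degree = 3,
                            ext = 4, face_gap = 2.5, seed = 1) {
  if (bead_spacing > 1)
    stop("bead_spacing must be <= sigma so beads stay contiguous")
  .with_seed(seed, {
    lo <- -ext; hi <- box_size + ext
    in_gap <- function(x) any((x > -face_gap & x < 0) |
                                (x > box_size & x < box_size + face_gap))
    # A usable gel phantom must be one well-connected network filling the
    # imaging box, and must not place features exactly at the cleaning
    # thresholds (a face stub whose pruning depends on the sub-voxel tip
    # position is measurement-degenerate). Retry the (deterministic,
    # RNG-continuing) sampling until the largest component holds >= 70% of
    # the nodes, extends beyond the box on every side, and the cropped
    # ground truth is insensitive to the tip-retreat model.
    best <- NULL
    for (attempt in 1:40) {
      draw <- .draw_bead_graph(n_nodes, lo, hi, in_gap, min_node_dist,
                               cutoff, clearance, min_angle, max_degree)
      frac <- nrow(draw$pos) / n_nodes
      spans <- all(apply(draw$pos, 2, min) <= 0) &&
        all(apply(draw$pos, 2, max) >= box_size)
      stable <- FALSE
      if (frac >= 0.7 && spans) {
        c1 <- .crop_truth(draw$pos, draw$ee, box_size, tip_retreat = 0.1)
        c2 <- .crop_truth(draw$pos, draw$ee, box_size, tip_retreat = 0.5)
        stable <- nrow(networkNodes(c1)) == nrow(networkNodes(c2)) &&
          nrow(networkLinks(c1)) == nrow(networkLinks(c2))
        if (stable) {
          # at least two strand crossings on every box face, so tortuosity
          # pools over enough spanning paths to be a stable statistic
          fn <- networkNodes(c1)
          eps <- 0.6
          n_face <- c(sum(fn$x < eps), sum(fn$x > box_size - eps),
                      sum(fn$y < eps), sum(fn$y > box_size - eps),
                      sum(fn$z < eps), sum(fn$z > box_size - eps))
          stable <- all(n_face >= 2)
        }
      }
      if (is.null(best) || frac > best$frac)
        best <- c(draw, list(frac = frac))
      if (frac >= 0.7 && spans && stable) { best <- draw; break }
    }
    pos <- best$pos
    ee <- best$ee
    lens <- sqrt(rowSums((pos[ee[, 1], , drop = FALSE] -
                            pos[ee[, 2], , drop = FALSE])^2))
    # beads: one at every node, then evenly along each edge
    beads <- pos
    for (k in seq_len(nrow(ee))) {
      nb <- ceiling(lens[k] / bead_spacing)
      if (nb >= 2) {
        tt <- seq(0, 1, length.out = nb + 1)[2:nb]
        beads <- rbind(beads,
                       t(pos[ee[k, 1], ] %o% (1 - tt) +
                           pos[ee[k, 2], ] %o% tt))
      }
    }
    # a bead exactly at every face crossing, so clipped strands are rendered
    # all the way to the face with no cropping slack
    for (k in seq_len(nrow(ee))) {
      p <- pos[ee[k, 1], ]; q <- pos[ee[k, 2], ]
      v <- q - p
      t0 <- 0; t1 <- 1
      for (ax in 1:3) {
        if (v[ax] == 0) {
          if (p[ax] < 0 || p[ax] > box_size) { t0 <- 1; t1 <- 0; break }
        } else {
          ta <- (0 - p[ax]) / v[ax]; tb <- (box_size - p[ax]) / v[ax]
          t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
        }
      }
      if (t0 >= t1) next
      if (t0 > 0) beads <- rbind(beads, p + t0 * v)
      if (t1 < 1) beads <- rbind(beads, p + t1 * v)
    }
    inside <- beads[, 1] >= 0 & beads[, 1] <= box_size &
      beads[, 2] >= 0 & beads[, 2] <= box_size &
      beads[, 3] >= 0 & beads[, 3] <= box_size
    beads <- beads[inside, , drop = FALSE]
    colnames(beads) <- c("x", "y", "z")
    particles <- ParticleSet(beads, sigma = 1,
                             box = rbind(c(0, 0, 0), rep(box_size, 3)))
    truth_graph <- .truth_graph(pos, ee, lens, box_size)
    clean <- cleanGraph(truth_graph)
    cropped <- .crop_truth(pos, ee, box_size)
    truth <- list(nodes = pos, edges = cbind(ee, length = lens),
                  n_nodes = nrow(pos), n_links = nrow(ee),
                  clean_n_nodes = nrow(networkNodes(clean)),
                  clean_n_links = nrow(networkLinks(clean)),
                  graph = clean,
                  cropped_graph = cropped,
                  crop_n_nodes = nrow(networkNodes(cropped)),
                  crop_n_links = nrow(networkLinks(cropped)))
    list(particles = particles, truth = truth)
  })
}

# One sampling round for the bead-network generator: node positions with a
# minimum separation (outside the face exclusion band), greedy edge
# acceptance under the clearance/angle/degree constraints, restricted to
# the largest connected component. Returns pos (kept nodes) and ee (edge
# index pairs into pos).
.draw_bead_graph <- function(n_nodes, lo, hi, in_gap, min_node_dist,
                             cutoff, clearance, min_angle, max_degree) {
  pos <- matrix(numeric(0), 0, 3)
  tries <- 0
  while (nrow(pos) < n_nodes && tries < n_nodes * 500) {
    cand <- stats::runif(3, lo, hi)
    if (!in_gap(cand) &&
        (nrow(pos) == 0 ||
           min(sqrt(colSums((t(pos) - cand)^2))) >= min_node_dist))
      pos <- rbind(pos, cand)
    tries <- tries + 1
  }
  n <- nrow(pos)
  dmat <- as.matrix(stats::dist(pos))
  cand <- which(dmat < cutoff & upper.tri(dmat), arr.ind = TRUE)
  cand <- cand[order(dmat[cand]), , drop = FALSE]
  acc <- matrix(integer(0), 0, 2)
  degree <- integer(n)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (degree[i] >= max_degree || degree[j] >= max_degree) next
    p <- pos[i, ]; q <- pos[j, ]
    u <- (q - p) / sqrt(sum((q - p)^2))
    ok <- TRUE
    # clearance from non-endpoint nodes
    for (m in seq_len(n)) {
      if (m == i || m == j) next
      if (.point_seg_dist(pos[m, ], p, q) < clearance) { ok <- FALSE; break }
    }
    if (ok && nrow(acc) > 0) for (e in seq_len(nrow(acc))) {
      a <- acc[e, 1]; b <- acc[e, 2]
      shared <- intersect(c(a, b), c(i, j))
      if (length(shared) > 0) {
        s <- shared[1]
        v1 <- if (s == i) u else -u
        w <- pos[setdiff(c(a, b), s)[1], ] - pos[s, ]
        v2 <- w / sqrt(sum(w^2))
        if (sum(v1 * v2) > cos(min_angle * pi / 180)) { ok <- FALSE; break }
      } else {
        if (.seg_seg_dist(p, q, pos[a, ], pos[b, ]) < clearance) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) {
      acc <- rbind(acc, c(i, j))
      degree[i] <- degree[i] + 1L
      degree[j] <- degree[j] + 1L
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(acc)) g <- igraph::add_edges(g, t(acc))
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  pos <- pos[keep, , drop = FALSE]
  ee <- acc[acc[, 1] %in% keep & acc[, 2] %in% keep, , drop = FALSE]
  ee <- cbind(match(ee[, 1], keep), match(ee[, 2], keep))
  list(pos = pos, ee = ee)
}

# Clip the true strand network at the imaging box: edges are intersected
# with the box, crossings create degree-1 face nodes, and the result goes
# through the standard cleaning, giving the ground truth for what a pipeline
# run on the cropped rendering should recover. The medial axis of a
# sigma-thick tube clipped at a face ends about one particle radius inside
# the material (the centre of the last maximal inscribed ball), so face
# stubs are shortened by sigma/2 before cleaning.
.crop_truth <- function(pos, ee, box_size, tip_retreat = 0.25) {
  inside <- function(x) all(x >= 0 & x <= box_size)
  new_pos <- pos
  is_orig <- rep(TRUE, nrow(pos))
  edges <- matrix(integer(0), 0, 2)
  lens <- numeric(0)
  add_node <- function(x) {
    new_pos <<- rbind(new_pos, x)
    is_orig <<- c(is_orig, FALSE)
    nrow(new_pos)
  }
  for (k in seq_len(nrow(ee))) {
    p <- pos[ee[k, 1], ]; q <- pos[ee[k, 2], ]
    v <- q - p
    t0 <- 0; t1 <- 1
    for (ax in 1:3) {
      if (v[ax] == 0) {
        if (p[ax] < 0 || p[ax] > box_size) { t0 <- 1; t1 <- 0; break }
      } else {
        ta <- (0 - p[ax]) / v[ax]; tb <- (box_size - p[ax]) / v[ax]
        t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
      }
    }
    if (t0 >= t1) next
    len_full <- sqrt(sum(v^2))
    a_face <- !(t0 == 0 && inside(p))
    b_face <- !(t1 == 1 && inside(q))
    if (a_face) t0 <- t0 + tip_retreat / len_full
    if (b_face) t1 <- t1 - tip_retreat / len_full
    if (t0 >= t1) next
    a <- if (a_face) add_node(p + t0 * v) else ee[k, 1]
    b <- if (b_face) add_node(p + t1 * v) else ee[k, 2]
    edges <- rbind(edges, c(a, b))
    lens <- c(lens, (t1 - t0) * len_full)
  }
  used <- sort(unique(c(edges)))
  keep_iso <- which(is_orig & .inside_rows(new_pos, box_size) &
                      !(seq_len(nrow(new_pos)) %in% used))
  keep <- sort(unique(c(used, keep_iso)))
  map <- match(seq_len(nrow(new_pos)), keep)
  g <- .truth_graph(new_pos[keep, , drop = FALSE],
                    cbind(map[edges[, 1]], map[edges[, 2]]),
                    lens, box_size)
  cleanGraph(g)
}

.inside_rows <- function(m, box_size) {
  m[, 1] >= 0 & m[, 1] <= box_size & m[, 2] >= 0 & m[, 2] <= box_size &
    m[, 3] >= 0 & m[, 3] <= box_size
}

# Build a NetworkGraph straight from true node positions and edges so the
# standard cleaning semantics can be applied to the generated topology.
.truth_graph <- function(pos, edges, lens, box_size) {
  geom <- .unit_geom()
  nn <- nrow(pos)
  nodes <- data.frame(id = seq_len(nn), kind = "end",
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      degree = 0L, cycle_anchor = FALSE,
                      stringsAsFactors = FALSE)
  vox <- lapply(seq_len(nn), function(i) {
    vm <- matrix(pmax(1, ceiling(c(pos[i, 3], pos[i, 2], pos[i, 1]))), 1, 3)
    colnames(vm) <- c("z", "y", "x")
    vm
  })
  nl <- nrow(edges)
  links <- data.frame(id = seq_len(nl), node_a = edges[, 1],
                      node_b = edges[, 2], length = lens,
                      n_path = 2L)
  paths <- lapply(seq_len(nl), function(k) rbind(vox[[edges[k, 1]]],
                                                 vox[[edges[k, 2]]]))
  box <- rbind(min = c(x = 0, y = 0, z = 0),
               max = c(x = box_size, y = box_size, z = box_size))
  nodes$degree <- .node_degrees(nodes, links)
  nodes$kind <- ifelse(nodes$degree >= 3, "branching",
                       ifelse(nodes$degree == 1, "end", "end"))
  new("NetworkGraph", nodes = nodes, nodeVoxels = vox, links = links,
      paths = paths, geometry = geom, box = box, sigma = 1)
}

#' Imaging corruption model
#'
#' Emulates depth-dependent intensity loss and detector noise: slice z
#' (1-based) is multiplied by \code{1 - drift_per_slice * (z - 1)}, then
#' independent Gaussian noise is added and the result clipped at 0.
#'
#' @param stack an \code{ImageStack}.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param drift_per_slice fractional intensity loss per slice.
#' @param seed integer seed.
#' @return a corrupted \code{ImageStack}.
#' @export
corruptStack <- function(stack, noise_sd = 0.05, drift_per_slice = 0.002,
                         seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  arr <- intensities(stack)
  nz <- dim(arr)[1]
  fac <- 1 - drift_per_slice * (seq_len(nz) - 1)
  fac[fac < 0] <- 0
  arr <- sweep(arr, 1, fac, "*")
  if (noise_sd > 0) {
    noise <- .with_seed(seed, stats::rnorm(length(arr), 0, noise_sd))
    arr <- arr + noise
  }
  arr[arr < 0] <- 0
  ImageStack(array(arr, dim(arr)), geometry(stack))
}
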