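# Quantitative network statistics: node/link counts and densities, the
# normalized link-length distribution, and tortuosity, with a margin-based
# box-edge correction.

#' Summary counts and densities of a cleaned network
#'
#' Counts nodes and links, the average number of links per node, and their
#' densities. Box-edge effects are corrected by a margin exclusion zone:
#' nodes whose position lies strictly within \code{margin} of any box face
#' are excluded from the node count, links with either endpoint excluded are
#' excluded from the link count, and densities divide by the volume of the
#' margin-shrunken box. A margin of 0 disables the correction (nodes exactly
#' on a face are then included: closed-box convention).
#'
#' Densities are reported both per cubic unit of the graph's geometry and
#' per sigma cubed.
#'
#' @param graph a cleaned \code{NetworkGraph}.
#' @param margin physical exclusion margin; conventional default 1.5 sigma.
#' @return a list of class \code{netskel_summary}: \code{N_N}, \code{N_L},
#'   \code{links_per_node}, \code{rho_N}, \code{rho_L} (native units),
#'   \code{rho_N_sigma}, \code{rho_L_sigma}, \code{analysis_volume},
#'   \code{unit}, \code{margin}, \code{kept_nodes} (ids).
#' @export
summarizeNetwork <- function(graph, margin = 1.5 * particleSigma(graph)) {
  nodes <- networkNodes(graph)
  links <- networkLinks(graph)
  box <- boundingBox(graph)
  sigma <- particleSigma(graph)
  lo <- box[1, ] + margin
  hi <- box[2, ] - margin
  if (any(hi <= lo))
    stop("margin larger than half the box extent; nothing to analyze")
  keep <- nodes$x >= lo["x"] & nodes$x <= hi["x"] &
    nodes$y >= lo["y"] & nodes$y <= hi["y"] &
    nodes$z >= lo["z"] & nodes$z <= hi["z"]
  kept_ids <- nodes$id[keep]
  n_n <- sum(keep)
  if (nrow(links) > 0) {
    lk <- links$node_a %in% kept_ids & links$node_b %in% kept_ids
  } else lk <- logical(0)
  n_l <- sum(lk)
  vol <- prod(hi - lo)
  res <- list(N_N = n_n, N_L = n_l,
              links_per_node = if (n_n > 0) n_l / n_n else NA_real_,
              rho_N = n_n / vol, rho_L = n_l / vol,
              rho_N_sigma = n_n / vol * sigma^3,
              rho_L_sigma = n_l / vol * sigma^3,
              analysis_volume = vol, unit = unitLabel(geometry(graph)),
              margin = margin, kept_nodes = kept_ids,
              kept_links = if (nrow(links) > 0) links$id[lk] else integer(0))
  class(res) <- "netskel_summary"
  res
}

#' @export
print.netskel_summary <- function(x, ...) {
  cat(sprintf("Network summary (margin %g %s):\n", x$margin, x$unit))
  cat(sprintf("  N_N = %d, N_L = %d, N_L/N_N = %s\n", x$N_N, x$N_L,
              ifelse(is.na(x$links_per_node), "NA",
                     sprintf("%.3f", x$links_per_node))))
  cat(sprintf("  rho_N = %.4g %s^-3 (%.4g sigma^-3)\n", x$rho_N, x$unit,
              x$rho_N_sigma))
  cat(sprintf("  rho_L = %.4g %s^-3 (%.4g sigma^-3)\n", x$rho_L, x$unit,
              x$rho_L_sigma))
  invisible(x)
}

#' Normalized link-length histogram
#'
#' Histogram of link path lengths, normalized as a probability density over
#' length (the integral of the normalized count over length is 1).
#'
#' @param graph a \code{NetworkGraph}.
#' @param bins either a single integer (number of equal-width bins from 0 to
#'   the maximum length; default 20) or a numeric vector of increasing bin
#'   edges.
#' @param margin physical edge-exclusion margin applied to the links (via
#'   their endpoint nodes), default 0.
#' @return a list of class \code{netskel_histogram}: \code{bin_edges},
#'   \code{counts}, \code{normalized}, \code{n_links}, \code{empty}.
#' @export
linkLengthHistogram <- function(graph, bins = 20, margin = 0) {
  links <- networkLinks(graph)
  if (margin > 0) {
    s <- summarizeNetwork(graph, margin)
    links <- links[links$id %in% s$kept_links, , drop = FALSE]
  }
  len <- links$length
  if (length(len) == 0) {
    out <- list(bin_edges = numeric(0), counts = integer(0),
                normalized = numeric(0), n_links = 0L, empty = TRUE)
    class(out) <- "netskel_histogram"
    return(out)
  }
  if (length(bins) == 1) {
    edges <- seq(0, max(len), length.out = as.integer(bins) + 1L)
    if (max(len) == 0) edges <- seq(0, 1, length.out = as.integer(bins) + 1L)
  } else {
    edges <- sort(bins)
  }
  k <- findInterval(len, edges, rightmost.closed = TRUE, left.open = TRUE)
  k[len == edges[1]] <- 1L # lengths exactly at the lower edge
  inside <- k >= 1 & k <= length(edges) - 1
  counts <- tabulate(k[inside], length(edges) - 1L)
  widths <- diff(edges)
  norm <- counts / (sum(counts) * widths)
  out <- list(bin_edges = edges, counts = counts, normalized = norm,
              n_links = length(len), empty = FALSE)
  class(out) <- "netskel_histogram"
  out
}

# Length of a voxel-centre polyline resampled every `k` vertices (both
# endpoints always kept). Summing raw voxel steps overestimates the length
# of smooth curves by the lattice staircase bias (up to ~8% in-plane);
# coarse polygonal resampling removes that bias while remaining exact for
# straight paths.
.polyline_length <- function(pts, k) {
  n <- nrow(pts)
  if (n < 2) return(0)
  idx <- unique(c(seq(1, n, by = max(1L, as.integer(k))), n))
  q <- pts[idx, , drop = FALSE]
  sum(sqrt(rowSums((q[-1, , drop = FALSE] -
                      q[-nrow(q), , drop = FALSE])^2)))
}

# igraph over skeleton voxels with physical step weights
.skeleton_igraph <- function(skeleton) {
  m <- materialMask(skeleton)
  n <- dim(m)
  d <- voxelDims(skeleton)
  lin <- which(m)
  coord <- which(m, arr.ind = TRUE)
  nv <- length(lin)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
                 (offs$dz == 0 & offs$dy == 0 & offs$dx > 0), ]
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    z2 <- coord[, 1] + offs$dz[r]
    y2 <- coord[, 2] + offs$dy[r]
    x2 <- coord[, 3] + offs$dx[r]
    ok <- z2 >= 1 & z2 <= n[1] & y2 >= 1 & y2 <= n[2] & x2 >= 1 & x2 <= n[3]
    lin2 <- z2 + n[1] * (y2 - 1) + n[1] * n[2] * (x2 - 1)
    j <- rep(NA_integer_, nv)
    j[ok] <- match(lin2[ok], lin)
    hit <- which(!is.na(j))
    if (length(hit)) {
      from <- c(from, hit); to <- c(to, j[hit])
      step <- sqrt((offs$dx[r] * d["dx"])^2 + (offs$dy[r] * d["dy"])^2 +
                     (offs$dz[r] * d["dz"])^2)
      w <- c(w, rep(step, length(hit)))
    }
  }
  g <- igraph::make_empty_graph(nv, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to), weight = w)
  list(g = g, coord = coord, centers = voxelCenters(
    {cc <- coord; colnames(cc) <- c("z", "y", "x"); cc}, geometry(skeleton)))
}

#' Network tortuosity
#'
#' For each Cartesian axis, identifies skeleton voxels intersecting the two
#' opposite box faces and, for every voxel A on the upper face, computes the
#' shortest along-skeleton path (physical step weights) to the set of
#' lower-face voxels. With lambda the path length and lambda_Euc the
#' Euclidean distance between A and the reached voxel B, each spanning path
#' contributes lambda / lambda_Euc; contributions are pooled over the three
#' axes. Axes without a spanning path contribute nothing; when no axis
#' spans, the result is flagged non-percolating.
#'
#' A voxel "intersects" a face when its centre lies within
#' \code{face_margin} of it; the default is one particle diameter when
#' \code{sigma} is supplied (the medial axis of a strand clipped at the face
#' ends about one particle radius inside the material, plus rendering
#' slack), and one voxel pitch otherwise.
#'
#' The trajectory length lambda is measured on the shortest path's voxel
#' sequence resampled as a polygonal line every \code{resample_step} voxels:
#' raw voxel-step sums overestimate the length of smooth curves by the
#' lattice staircase bias, while the coarse polyline is exact for straight
#' strands and unbiased for gently curved ones.
#'
#' @param graph a \code{NetworkGraph} (supplies sigma and the box), or
#'   \code{NULL}.
#' @param skeleton the \code{Skeleton} the graph was extracted from.
#' @param face_margin physical face tolerance (see above).
#' @param resample_step polyline resampling stride in voxels (default 5).
#' @return a list of class \code{netskel_tortuosity}: \code{xi_mean},
#'   \code{xi_std}, \code{n_paths}, \code{per_axis} (data.frame),
#'   \code{percolating}.
#' @export
tortuosity <- function(graph, skeleton, face_margin = NULL,
                       resample_step = 5L) {
  d <- voxelDims(skeleton)
  n <- stackDim(skeleton)
  sigma <- if (!is.null(graph)) particleSigma(graph) else NULL
  if (is.null(face_margin))
    face_margin <- if (!is.null(sigma)) max(sigma, max(d))
                   else max(d)
  box <- if (!is.null(graph)) boundingBox(graph) else
    rbind(min = c(x = 0, y = 0, z = 0),
          max = c(x = n[3] * d[["dx"]], y = n[2] * d[["dy"]],
                  z = n[1] * d[["dz"]]))
  sk <- .skeleton_igraph(skeleton)
  if (nrow(sk$coord) == 0) {
    out <- list(xi_mean = NA_real_, xi_std = NA_real_, n_paths = 0L,
                per_axis = NULL, percolating = FALSE)
    class(out) <- "netskel_tortuosity"
    return(out)
  }
  axes <- c("x", "y", "z")
  ratios <- numeric(0)
  per_axis <- data.frame(axis = axes, xi_mean = NA_real_, n_paths = 0L)
  # one intersection point per strand crossing a face: voxels inside the
  # face slab are grouped by 26-connectivity and each group is represented
  # by its voxel closest to the face (ties broken by lowest (z, y, x))
  face_reps <- function(slab, ax_col, toward_min) {
    if (length(slab) == 0) return(integer(0))
    sub <- igraph::induced_subgraph(sk$g, slab)
    memb <- igraph::components(sub)$membership
    reps <- integer(max(memb))
    for (cl in seq_len(max(memb))) {
      cand <- slab[memb == cl]
      ppos <- sk$centers[cand, ax_col]
      if (!toward_min) ppos <- -ppos
      o <- order(ppos, sk$coord[cand, 1], sk$coord[cand, 2],
                 sk$coord[cand, 3])
      reps[cl] <- cand[o[1]]
    }
    reps
  }
  for (ai in seq_along(axes)) {
    ax <- axes[ai]
    pos_ax <- sk$centers[, ax]
    top <- which(pos_ax <= box[1, ax] + face_margin)
    bot <- which(pos_ax >= box[2, ax] - face_margin)
    bot <- setdiff(bot, top)
    if (length(top) == 0 || length(bot) == 0) next
    top <- face_reps(top, ax, TRUE)
    bot <- face_reps(bot, ax, FALSE)
    dm <- igraph::distances(sk$g, v = top, to = bot,
                            weights = igraph::E(sk$g)$weight)
    rr <- numeric(0)
    for (i in seq_along(top)) {
      row <- dm[i, ]
      if (all(!is.finite(row))) next
      j <- which.min(row)
      vp <- igraph::shortest_paths(sk$g, from = top[i], to = bot[j],
                                   weights = igraph::E(sk$g)$weight,
                                   output = "vpath")$vpath[[1]]
      pts <- sk$centers[as.integer(vp), , drop = FALSE]
      lambda <- .polyline_length(pts, resample_step)
      a <- sk$centers[top[i], ]
      b <- sk$centers[bot[j], ]
      l_euc <- sqrt(sum((a - b)^2))
      if (l_euc < 0.5 * min(d)) next
      rr <- c(rr, max(1, lambda / l_euc))
    }
    if (length(rr)) {
      per_axis$xi_mean[ai] <- mean(rr)
      per_axis$n_paths[ai] <- length(rr)
      ratios <- c(ratios, rr)
    }
  }
  out <- list(
    xi_mean = if (length(ratios)) mean(ratios) else NA_real_,
    xi_std = if (length(ratios) > 1) stats::sd(ratios) else
      if (length(ratios) == 1) 0 else NA_real_,
    n_paths = length(ratios),
    per_axis = per_axis,
    percolating = length(ratios) > 0)
  class(out) <- "netskel_tortuosity"
  out
}

#' @export
print.netskel_tortuosity <- function(x, ...) {
  if (!x$percolating) cat("Tortuosity: non-percolating (no spanning path)\n")
  else cat(sprintf("Tortuosity: xi = %.3f +/- %.3f over %d spanning paths\n",
                   x$xi_mean, x$xi_std, x$n_paths))
  invisible(x)
}

#' Full quantitative analysis of a network
#'
#' Bundles the summary counts/densities, the normalized link-length
#' histogram and the tortuosity, pooled and per connected component of the
#' graph.
#'
#' @param graph a cleaned \code{NetworkGraph}.
#' @param skeleton the \code{Skeleton} the graph was rebuilt into (used for
#'   tortuosity); may be \code{NULL} to skip tortuosity.
#' @param margin physical edge-exclusion margin (default 1.5 sigma).
#' @param bins histogram bins (see \code{\link{linkLengthHistogram}}).
#' @return a list of class \code{netskel_report}: \code{summary},
#'   \code{histogram}, \code{tortuosity}, \code{components} (per-component
#'   N_N / N_L data.frame).
#' @export
analyzeNetwork <- function(graph, skeleton = NULL,
                           margin = 1.5 * particleSigma(graph), bins = 20) {
  s <- summarizeNetwork(graph, margin)
  h <- linkLengthHistogram(graph, bins = bins, margin = margin)
  tort <- if (!is.null(skeleton)) tortuosity(graph, skeleton) else NULL
  nodes <- networkNodes(graph)
  links <- networkLinks(graph)
  comp_df <- NULL
  if (nrow(nodes) > 0) {
    g <- igraph::make_empty_graph(nrow(nodes), directed = FALSE)
    if (nrow(links) > 0)
      g <- igraph::add_edges(g, rbind(match(links$node_a, nodes$id),
                                      match(links$node_b, nodes$id)))
    memb <- igraph::components(g)$membership
    comp_df <- data.frame(component = seq_len(max(memb)))
    comp_df$N_N <- as.integer(table(factor(memb, comp_df$component)))
    if (nrow(links) > 0) {
      lm <- memb[match(links$node_a, nodes$id)]
      comp_df$N_L <- as.integer(table(factor(lm, comp_df$component)))
    } else comp_df$N_L <- 0L
  }
  out <- list(summary = s, histogram = h, tortuosity = tort,
              components = comp_df)
  class(out) <- "netskel_report"
  out
}

#' @export
print.netskel_report <- function(x, ...) {
  print(x$summary)
  if (!is.null(x$tortuosity)) print(x$tortuosity)
  if (!is.null(x$components))
    cat(sprintf("  %d connected component(s)\n", nrow(x$components)))
  invisible(x)
}
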