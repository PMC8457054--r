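# Whole-volume topological measurements used to validate thinning and
# phantom ground truths. These are deliberately implemented as global,
# array-level computations in R, independent of the per-voxel lattice
# predicates in the compiled thinning code, so the two routes can check
# each other.

#' Euler characteristic of a binary volume
#'
#' Computes the 3D Euler characteristic (objects - tunnels + cavities) of the
#' foreground, treating voxels as closed unit cubes (the convention matching
#' 26-connected foreground). The value is obtained from the cubical complex
#' as vertices - edges + faces - cubes, where each cell shared between
#' neighbouring cubes is counted once.
#'
#' @param x a 3D logical array, or a \code{BinaryVolume}/\code{Skeleton}.
#' @return integer Euler characteristic.
#' @examples
#' a <- array(FALSE, c(3, 3, 3)); a[2, 2, 2] <- TRUE
#' eulerCharacteristic(a) # 1: a single solid cube
#' @export
eulerCharacteristic <- function(x) {
  m <- if (is.array(x) && is.logical(x)) x else materialMask(x)
  n <- dim(m)
  # Q: padded occupancy, one layer of background on every side
  q <- array(FALSE, n + 2L)
  q[2:(n[1] + 1), 2:(n[2] + 1), 2:(n[3] + 1)] <- m
  # S(dz, dy, dx): occupancy shifted onto the (n+1)^3 lattice of cell corners
  s <- function(dz, dy, dx)
    q[(1:(n[1] + 1)) + dz, (1:(n[2] + 1)) + dy, (1:(n[3] + 1)) + dx,
      drop = FALSE]
  cubes <- sum(m)
  # 2-cells perpendicular to each axis: OR of the two voxels sharing the
  # face, counted on a lattice of (n+1) positions along that axis and n
  # positions along the other two
  face_z <- sum(q[1:(n[1] + 1), 2:(n[2] + 1), 2:(n[3] + 1), drop = FALSE] |
                  q[2:(n[1] + 2), 2:(n[2] + 1), 2:(n[3] + 1), drop = FALSE])
  face_y <- sum(q[2:(n[1] + 1), 1:(n[2] + 1), 2:(n[3] + 1), drop = FALSE] |
                  q[2:(n[1] + 1), 2:(n[2] + 2), 2:(n[3] + 1), drop = FALSE])
  face_x <- sum(q[2:(n[1] + 1), 2:(n[2] + 1), 1:(n[3] + 1), drop = FALSE] |
                  q[2:(n[1] + 1), 2:(n[2] + 1), 2:(n[3] + 2), drop = FALSE])
  faces <- face_z + face_y + face_x
  # 1-cells parallel to each axis: OR of the four voxels sharing the edge
  or4 <- function(a, b, cc, d) a | b | cc | d
  # edges parallel to z: lattice in (y, x), voxel extent in z
  sz <- function(dy, dx)
    q[2:(n[1] + 1), (1:(n[2] + 1)) + dy, (1:(n[3] + 1)) + dx, drop = FALSE]
  edge_z <- sum(or4(sz(0, 0), sz(1, 0), sz(0, 1), sz(1, 1)))
  sy <- function(dz, dx)
    q[(1:(n[1] + 1)) + dz, 2:(n[2] + 1), (1:(n[3] + 1)) + dx, drop = FALSE]
  edge_y <- sum(or4(sy(0, 0), sy(1, 0), sy(0, 1), sy(1, 1)))
  sx <- function(dz, dy)
    q[(1:(n[1] + 1)) + dz, (1:(n[2] + 1)) + dy, 2:(n[3] + 1), drop = FALSE]
  edge_x <- sum(or4(sx(0, 0), sx(1, 0), sx(0, 1), sx(1, 1)))
  edges <- edge_z + edge_y + edge_x
  # 0-cells: OR of the eight voxels sharing the corner
  acc <- array(FALSE, n + 1L)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    acc <- acc | s(dz, dy, dx)
  verts <- sum(acc)
  as.integer(verts - edges + faces - cubes)
}

#' Count connected foreground components
#'
#' Counts connected components of the foreground using an adjacency-graph
#' construction (via \pkg{igraph}), independent of the compiled flood-fill
#' labelling used elsewhere in the package.
#'
#' @param x a 3D logical array, or a \code{BinaryVolume}/\code{Skeleton}.
#' @param connectivity 26 (default) or 6.
#' @return integer number of components.
#' @export
countComponents <- function(x, connectivity = 26) {
  m <- if (is.array(x) && is.logical(x)) x else materialMask(x)
  n <- dim(m)
  lin <- which(m)
  if (length(lin) == 0) return(0L)
  coord <- which(m, arr.ind = TRUE)
  key <- function(z, y, x) z + n[1] * (y - 1) + n[1] * n[2] * (x - 1)
  edges <- list()
  k <- 1
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  # only half the offsets to avoid duplicate edges
  offs <- offs[as.logical(offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
                            (offs$dz == 0 & offs$dy == 0 & offs$dx > 0)), ]
  for (r in seq_len(nrow(offs))) {
    z2 <- coord[, 1] + offs$dz[r]
    y2 <- coord[, 2] + offs$dy[r]
    x2 <- coord[, 3] + offs$dx[r]
    ok <- z2 >= 1 & z2 <= n[1] & y2 >= 1 & y2 <= n[2] & x2 >= 1 & x2 <= n[3]
    j <- rep(NA_integer_, length(lin))
    j[ok] <- match(key(z2[ok], y2[ok], x2[ok]), lin)
    hit <- which(!is.na(j))
    if (length(hit)) {
      edges[[k]] <- cbind(hit, j[hit])
      k <- k + 1
    }
  }
  if (length(edges) == 0) return(length(lin))
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(lin) - igraph::vcount(g)))
  igraph::count_components(g)
}
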