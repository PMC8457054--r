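# Skeleton -> graph conversion and graph cleaning.
#
# Voxel classification counts material voxels in the 3x3x3 cube around each
# skeleton voxel (centre included): exactly 2 -> end voxel, exactly 3 ->
# link voxel, more than 3 -> branch voxel. Adjacent branch voxels are
# clumped into a single node (26-connectivity); end voxels are singleton
# nodes; link voxels form chains traced into link paths. Physical link
# length is the sum of anisotropic step lengths along the path.

.path_length <- function(path, d) {
  if (is.null(path) || nrow(path) < 2) return(0)
  dz <- diff(path[, 1]) * d["dz"]
  dy <- diff(path[, 2]) * d["dy"]
  dx <- diff(path[, 3]) * d["dx"]
  sum(sqrt(dx^2 + dy^2 + dz^2))
}

.node_degrees <- function(nodes, links) {
  deg <- integer(nrow(nodes))
  names(deg) <- nodes$id
  if (nrow(links) > 0) {
    t1 <- table(factor(c(links$node_a, links$node_b), levels = nodes$id))
    deg <- as.integer(t1)
    names(deg) <- nodes$id
  }
  deg
}

.empty_nodes <- function() {
  data.frame(id = integer(0), kind = character(0), x = numeric(0),
             y = numeric(0), z = numeric(0), degree = integer(0),
             cycle_anchor = logical(0), stringsAsFactors = FALSE)
}

.empty_links <- function() {
  data.frame(id = integer(0), node_a = integer(0), node_b = integer(0),
             length = numeric(0), n_path = integer(0),
             stringsAsFactors = FALSE)
}

#' Classify skeleton voxels as end, link or branch voxels
#'
#' Counts material voxels in the 27-voxel cube centred on every skeleton
#' voxel (the centre included): a count of exactly 2 marks an end voxel,
#' exactly 3 a link voxel, and more than 3 a branch voxel. Isolated voxels
#' (count 1) are labelled \code{"end"} and flagged.
#'
#' @param skeleton a \code{Skeleton}.
#' @return data.frame with one row per skeleton voxel: \code{z, y, x,
#'   count, label, isolated}.
#' @export
classifyVoxels <- function(skeleton) {
  m <- materialMask(skeleton)
  counts <- cpp_neighbor_count(as.logical(m), dim(m))
  lin <- which(m)
  cnt <- counts[lin]
  coord <- which(m, arr.ind = TRUE)
  label <- ifelse(cnt <= 2L, "end", ifelse(cnt == 3L, "link", "branch"))
  data.frame(z = coord[, 1], y = coord[, 2], x = coord[, 3], count = cnt,
             label = label, isolated = cnt == 1L, stringsAsFactors = FALSE)
}

# 26-neighbour adjacency among a voxel set given by linear indices `lin`
# into an array of dim `n`. Returns a list: for voxel i (position in lin),
# the integer positions of its neighbours in lin.
.adjacency <- function(lin, coord, n) {
  nv <- length(lin)
  adj <- vector("list", nv)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    z2 <- coord[, 1] + offs$dz[r]
    y2 <- coord[, 2] + offs$dy[r]
    x2 <- coord[, 3] + offs$dx[r]
    ok <- z2 >= 1 & z2 <= n[1] & y2 >= 1 & y2 <= n[2] & x2 >= 1 & x2 <= n[3]
    lin2 <- z2 + n[1] * (y2 - 1) + n[1] * n[2] * (x2 - 1)
    j <- rep(NA_integer_, nv)
    j[ok] <- match(lin2[ok], lin)
    hit <- which(!is.na(j))
    from <- c(from, hit)
    to <- c(to, j[hit])
  }
  if (length(from)) {
    o <- order(from, to)
    split(to[o], factor(from[o], levels = seq_len(nv)))
  } else {
    rep(list(integer(0)), nv)
  }
}

#' Extract a node-link graph from a skeleton
#'
#' Branch voxels are grouped into nodes by 26-connectivity (one clump = one
#' node), end voxels become singleton nodes, and chains of link voxels are
#' traced into link paths between node attachment voxels. Closed cycles with
#' no node voxel are anchored at a synthetic degree-2 node flagged
#' \code{cycle_anchor}. Link length is the physical path length including
#' one attachment voxel of each endpoint node.
#'
#' @param skeleton a \code{Skeleton}.
#' @param sigma particle diameter in the geometry's units (stored on the
#'   graph; the cleaning defaults are expressed in sigma).
#' @param box optional 2 x 3 physical bounding box; defaults to the full
#'   grid extent.
#' @return a \code{NetworkGraph}.
#' @export
extractGraph <- function(skeleton, sigma, box = NULL) {
  m <- materialMask(skeleton)
  n <- dim(m)
  geom <- geometry(skeleton)
  d <- voxelDims(geom)
  if (is.null(box)) {
    box <- rbind(min = c(x = 0, y = 0, z = 0),
                 max = c(x = n[3] * d[["dx"]], y = n[2] * d[["dy"]],
                         z = n[1] * d[["dz"]]))
  }
  lin <- which(m)
  nv <- length(lin)
  if (nv == 0) {
    return(new("NetworkGraph", nodes = .empty_nodes(), nodeVoxels = list(),
               links = .empty_links(), paths = list(), geometry = geom,
               box = box, sigma = as.numeric(sigma)))
  }
  coord <- which(m, arr.ind = TRUE)
  counts <- cpp_neighbor_count(as.logical(m), n)[lin]
  lab <- ifelse(counts <= 2L, "end", ifelse(counts == 3L, "link", "branch"))
  adj <- .adjacency(lin, coord, n)

  # sanity: a link voxel must have exactly two skeleton neighbours
  nnb <- lengths(adj)
  if (any(lab == "link" & nnb != 2L))
    stop("integrity error: skeleton is not thin (link voxel with ",
         "neighbour count != 2)")

  node_of <- integer(nv) # 0 = not a node voxel
  node_kind <- character(0)
  node_anchor <- logical(0)
  node_members <- list()
  nid <- 0L

  # branch clumps
  br <- which(lab == "branch")
  if (length(br) > 0) {
    seen <- logical(nv)
    isbr <- lab == "branch"
    for (s in br) {
      if (seen[s]) next
      nid <- nid + 1L
      stack <- s
      seen[s] <- TRUE
      members <- integer(0)
      while (length(stack)) {
        v <- stack[length(stack)]
        stack <- stack[-length(stack)]
        members <- c(members, v)
        nb <- adj[[v]]
        nb <- nb[isbr[nb] & !seen[nb]]
        seen[nb] <- TRUE
        stack <- c(stack, nb)
      }
      node_of[members] <- nid
      node_members[[nid]] <- sort(members)
      node_kind[nid] <- "branching"
      node_anchor[nid] <- FALSE
    }
  }
  # end voxels
  for (s in which(lab == "end")) {
    nid <- nid + 1L
    node_of[s] <- nid
    node_members[[nid]] <- s
    node_kind[nid] <- "end"
    node_anchor[nid] <- FALSE
  }

  links <- list()
  paths <- list()
  lid <- 0L
  add_link <- function(a, b, path_rows) {
    lid <<- lid + 1L
    path <- coord[path_rows, , drop = FALSE]
    links[[lid]] <<- data.frame(id = lid, node_a = a, node_b = b,
                                length = .path_length(path, d),
                                n_path = nrow(path))
    paths[[lid]] <<- path
  }

  is_link <- lab == "link"
  visited <- logical(nv)
  link_nb <- lapply(seq_len(nv), function(i)
    if (is_link[i]) adj[[i]][is_link[adj[[i]]]] else integer(0))
  linkdeg <- lengths(link_nb)

  trace_chain <- function(start) {
    chain <- start
    visited[start] <<- TRUE
    cur <- start
    repeat {
      nxt <- link_nb[[cur]]
      nxt <- nxt[!visited[nxt]]
      if (length(nxt) == 0) break
      cur <- nxt[1]
      visited[cur] <<- TRUE
      chain <- c(chain, cur)
    }
    chain
  }

  # open chains: termini are link voxels with < 2 link neighbours
  for (s in which(is_link & linkdeg < 2L)) {
    if (visited[s]) next
    chain <- trace_chain(s)
    k <- length(chain)
    att_first <- adj[[chain[1]]][node_of[adj[[chain[1]]]] > 0L]
    att_last <- adj[[chain[k]]][node_of[adj[[chain[k]]]] > 0L]
    if (k == 1L) {
      att <- sort(att_first)
      if (length(att) < 2)
        stop("integrity error: dangling link voxel")
      a_vox <- att[1]; b_vox <- att[2]
    } else {
      if (length(att_first) < 1 || length(att_last) < 1)
        stop("integrity error: chain without node attachment")
      a_vox <- sort(att_first)[1]
      b_vox <- sort(att_last)[1]
    }
    add_link(node_of[a_vox], node_of[b_vox], c(a_vox, chain, b_vox))
  }

  # remaining link voxels form pure cycles: anchor each at its lowest voxel
  for (s in which(is_link)) {
    if (visited[s]) next
    chain <- trace_chain(s)
    nid <- nid + 1L
    node_of[chain[1]] <- nid
    node_members[[nid]] <- chain[1]
    node_kind[nid] <- "branching"
    node_anchor[nid] <- TRUE
    add_link(nid, nid, c(chain, chain[1]))
  }

  # direct node-node adjacencies (via end voxels, which have one neighbour)
  for (e in which(lab == "end" & nnb == 1L)) {
    nb <- adj[[e]][1]
    if (node_of[nb] > 0L) {
      if (lab[nb] == "end" && lin[e] > lin[nb]) next # dedupe end-end pairs
      add_link(node_of[e], node_of[nb], c(e, nb))
    }
  }

  nodes <- data.frame(id = seq_len(nid),
                      kind = node_kind,
                      x = NA_real_, y = NA_real_, z = NA_real_,
                      degree = 0L,
                      cycle_anchor = node_anchor,
                      stringsAsFactors = FALSE)
  node_vox <- vector("list", nid)
  for (i in seq_len(nid)) {
    vm <- coord[node_members[[i]], , drop = FALSE]
    colnames(vm) <- c("z", "y", "x")
    node_vox[[i]] <- vm
    ctr <- voxelCenters(vm, geom)
    nodes$x[i] <- mean(ctr[, "x"])
    nodes$y[i] <- mean(ctr[, "y"])
    nodes$z[i] <- mean(ctr[, "z"])
  }
  links_df <- if (lid > 0) do.call(rbind, links) else .empty_links()
  nodes$degree <- .node_degrees(nodes, links_df)
  paths <- lapply(paths, function(p) {
    colnames(p) <- c("z", "y", "x"); p
  })
  new("NetworkGraph", nodes = nodes, nodeVoxels = node_vox,
      links = links_df, paths = paths, geometry = geom, box = box,
      sigma = as.numeric(sigma))
}

.rebuild <- function(graph, nodes, node_vox, links, paths) {
  # renumber nodes and links consecutively, keeping referential integrity
  old_ids <- nodes$id
  nodes$id <- seq_len(nrow(nodes))
  if (nrow(links) > 0) {
    links$node_a <- match(links$node_a, old_ids)
    links$node_b <- match(links$node_b, old_ids)
    links$id <- seq_len(nrow(links))
  }
  nodes$degree <- .node_degrees(nodes, links)
  rownames(nodes) <- NULL
  rownames(links) <- NULL
  new("NetworkGraph", nodes = nodes, nodeVoxels = node_vox, links = links,
      paths = paths, geometry = graph@geometry, box = graph@box,
      sigma = graph@sigma)
}

#' Prune unphysically small side chains
#'
#' Repeatedly deletes every link that has at least one endpoint of degree 1
#' (an end node) and a path length strictly below \code{min_side_chain},
#' together with that end node. Node kinds are recomputed from final degrees
#' by \code{\link{cleanGraph}}; nodes orphaned by the pruning (degree drops
#' to 0) are removed as well.
#'
#' @param graph a \code{NetworkGraph}.
#' @param min_side_chain physical length threshold; the conventional default
#'   is 1.5 sigma (see \code{\link{cleaningParams}}).
#' @return a pruned \code{NetworkGraph}.
#' @export
pruneSideChains <- function(graph, min_side_chain) {
  nodes <- networkNodes(graph)
  links <- networkLinks(graph)
  node_vox <- graph@nodeVoxels
  paths <- graph@paths
  if (nrow(links) == 0) return(graph)
  had_links <- nodes$id %in% c(links$node_a, links$node_b)
  repeat {
    deg <- .node_degrees(nodes, links)
    end_node <- deg == 1L
    names(end_node) <- nodes$id
    if (nrow(links) == 0) break
    is_term <- (end_node[as.character(links$node_a)] |
                  end_node[as.character(links$node_b)]) &
      links$node_a != links$node_b
    short <- is_term & links$length < min_side_chain
    if (!any(short)) break
    links <- links[!short, , drop = FALSE]
    paths <- paths[!short]
    deg2 <- .node_degrees(nodes, links)
    drop <- deg2 == 0L & had_links
    if (any(drop)) {
      nodes <- nodes[!drop, , drop = FALSE]
      node_vox <- node_vox[!drop]
      had_links <- had_links[!drop]
    }
  }
  .rebuild(graph, nodes, node_vox, links, paths)
}

#' Merge canal nodes
#'
#' A canal node is connected to exactly two links; the node and its two
#' links are effectively one single link and are merged (the new length is
#' exactly the sum of the two). Applied repeatedly until no canal node
#' remains. Cycle-anchor nodes and nodes whose two link ends belong to a
#' single loop are left untouched.
#'
#' @param graph a \code{NetworkGraph}.
#' @return a \code{NetworkGraph} without canal nodes.
#' @export
mergeCanalNodes <- function(graph) {
  nodes <- networkNodes(graph)
  links <- networkLinks(graph)
  node_vox <- graph@nodeVoxels
  paths <- graph@paths
  repeat {
    if (nrow(links) == 0) break
    deg <- .node_degrees(nodes, links)
    cand <- NULL
    for (i in which(deg == 2L & !nodes$cycle_anchor)) {
      nidx <- nodes$id[i]
      at <- which(links$node_a == nidx | links$node_b == nidx)
      if (length(at) == 2L) { # two distinct links (not a single loop)
        cand <- i
        break
      }
    }
    if (is.null(cand)) break
    nidx <- nodes$id[cand]
    at <- which(links$node_a == nidx | links$node_b == nidx)
    l1 <- at[1]; l2 <- at[2]
    other <- function(l) if (links$node_a[l] == nidx) links$node_b[l]
                         else links$node_a[l]
    a <- other(l1); b <- other(l2)
    p1 <- paths[[l1]]
    if (links$node_a[l1] == nidx) p1 <- p1[rev(seq_len(nrow(p1))), ,
                                           drop = FALSE]
    p2 <- paths[[l2]]
    if (links$node_b[l2] == nidx) p2 <- p2[rev(seq_len(nrow(p2))), ,
                                           drop = FALSE]
    nv <- node_vox[[cand]]
    newpath <- rbind(p1, nv, p2)
    newpath <- newpath[!duplicated(newpath), , drop = FALSE]
    newlen <- links$length[l1] + links$length[l2]
    links$node_a[l1] <- a
    links$node_b[l1] <- b
    links$length[l1] <- newlen
    links$n_path[l1] <- nrow(newpath)
    paths[[l1]] <- newpath
    links <- links[-l2, , drop = FALSE]
    paths <- paths[-l2]
    nodes <- nodes[-cand, , drop = FALSE]
    node_vox <- node_vox[-cand]
  }
  .rebuild(graph, nodes, node_vox, links, paths)
}

#' Collect nodes in close proximity
#'
#' Single-linkage clustering of node positions at the given cutoff (a set to
#' be collected contains all nodes closer than the cutoff to another node of
#' the same set, i.e. transitive closure). Each cluster becomes one node
#' placed at the member voxel nearest the member-position centroid (ties
#' broken by lowest (z, y, x)). Links are re-attached; a link with both
#' endpoints inside one cluster is absorbed (deleted) when shorter than the
#' cutoff and becomes a loop otherwise.
#'
#' @param graph a \code{NetworkGraph}.
#' @param node_collect_dist physical distance cutoff (strict); conventional
#'   default 0.9 sigma.
#' @return a \code{NetworkGraph}.
#' @export
collectCloseNodes <- function(graph, node_collect_dist) {
  nodes <- networkNodes(graph)
  if (nrow(nodes) <= 1) return(graph)
  links <- networkLinks(graph)
  node_vox <- graph@nodeVoxels
  paths <- graph@paths
  geom <- graph@geometry
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  dmat <- as.matrix(stats::dist(pos))
  close <- dmat < node_collect_dist
  diag(close) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(close, mode = "undirected")
  comp <- igraph::components(g)$membership
  if (max(comp) == nrow(nodes)) return(graph) # no pair below cutoff

  rep_of <- integer(nrow(nodes))
  new_nodes <- list()
  new_vox <- list()
  for (cl in seq_len(max(comp))) {
    members <- which(comp == cl)
    keep <- members[1]
    rep_of[members] <- nodes$id[keep]
    if (length(members) == 1) {
      new_nodes[[cl]] <- nodes[keep, , drop = FALSE]
      new_vox[[cl]] <- node_vox[[keep]]
      next
    }
    vox <- unique(do.call(rbind, node_vox[members]))
    centroid <- colMeans(pos[members, , drop = FALSE])
    ctr <- voxelCenters(vox, geom)
    dd <- sqrt((ctr[, "x"] - centroid[1])^2 + (ctr[, "y"] - centroid[2])^2 +
                 (ctr[, "z"] - centroid[3])^2)
    best <- order(dd, vox[, "z"], vox[, "y"], vox[, "x"])[1]
    nd <- nodes[keep, , drop = FALSE]
    nd$x <- ctr[best, "x"]; nd$y <- ctr[best, "y"]; nd$z <- ctr[best, "z"]
    nd$cycle_anchor <- any(nodes$cycle_anchor[members])
    new_nodes[[cl]] <- nd
    new_vox[[cl]] <- vox
  }
  nodes2 <- do.call(rbind, new_nodes)
  if (nrow(links) > 0) {
    map <- stats::setNames(rep_of, nodes$id)
    links$node_a <- unname(map[as.character(links$node_a)])
    links$node_b <- unname(map[as.character(links$node_b)])
    absorb <- links$node_a == links$node_b &
      links$length < node_collect_dist
    links <- links[!absorb, , drop = FALSE]
    paths <- paths[!absorb]
  }
  .rebuild(graph, nodes2, new_vox, links, paths)
}

#' Default cleaning parameters
#'
#' @param sigma particle diameter in physical units.
#' @param min_side_chain side-chain pruning threshold; default 1.5 sigma.
#' @param node_collect_dist node collection distance; default 0.9 sigma.
#' @param max_iterations maximum cleaning iterations (default 10).
#' @return a named list of cleaning parameters (physical units).
#' @export
cleaningParams <- function(sigma, min_side_chain = 1.5 * sigma,
                           node_collect_dist = 0.9 * sigma,
                           max_iterations = 10L) {
  if (min_side_chain < 0 || node_collect_dist < 0)
    stop("cleaning lengths must be >= 0")
  list(min_side_chain = min_side_chain,
       node_collect_dist = node_collect_dist,
       max_iterations = as.integer(max_iterations))
}

.graph_signature <- function(graph) {
  l <- networkLinks(graph)
  c(nrow(networkNodes(graph)), nrow(l), round(sum(l$length), 9))
}

#' Clean a network graph
#'
#' Applies, in order: side-chain pruning, canal-node merging and close-node
#' collection, looping until a fixed point (or \code{max_iterations}). Node
#' kinds are then recomputed from final degrees: degree 1 = end node,
#' degree >= 3 = branching node.
#'
#' @param graph a \code{NetworkGraph}.
#' @param params list from \code{\link{cleaningParams}}; defaults to the
#'   conventional thresholds for the graph's sigma.
#' @return a cleaned \code{NetworkGraph}.
#' @export
cleanGraph <- function(graph, params = cleaningParams(particleSigma(graph))) {
  it <- 0L
  repeat {
    sig0 <- .graph_signature(graph)
    graph <- pruneSideChains(graph, params$min_side_chain)
    graph <- mergeCanalNodes(graph)
    graph <- collectCloseNodes(graph, params$node_collect_dist)
    it <- it + 1L
    if (identical(.graph_signature(graph), sig0)) break
    if (it >= params$max_iterations) {
      warning("cleaning stopped after ", it,
              " iterations without reaching a fixed point")
      break
    }
  }
  nodes <- networkNodes(graph)
  deg <- .node_degrees(nodes, networkLinks(graph))
  nodes$degree <- deg
  nodes$kind <- ifelse(deg >= 3L, "branching",
                       ifelse(deg == 1L, "end",
                              ifelse(nodes$cycle_anchor, "branching",
                                     "end")))
  graph@nodes <- nodes
  graph
}

#' Rebuild a skeleton from a graph
#'
#' The union of all node voxels and link path voxels as a binary skeleton
#' volume ("a new skeleton formed from the cleaned graph").
#'
#' @param graph a \code{NetworkGraph}.
#' @param shape grid dimensions (nz, ny, nx).
#' @return a \code{Skeleton}.
#' @export
graphToSkeleton <- function(graph, shape) {
  arr <- array(FALSE, shape)
  put <- function(vm) {
    if (is.null(vm) || nrow(vm) == 0) return()
    if (any(vm[, 1] < 1 | vm[, 1] > shape[1] | vm[, 2] < 1 |
              vm[, 2] > shape[2] | vm[, 3] < 1 | vm[, 3] > shape[3]))
      stop("graph voxels outside the requested shape")
    arr[vm] <<- TRUE
  }
  for (vm in graph@nodeVoxels) put(vm)
  for (vm in graph@paths) put(vm)
  Skeleton(arr, graph@geometry)
}
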