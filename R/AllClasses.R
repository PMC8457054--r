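#' @useDynLib netskel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# ---------------------------------------------------------------------------
# VoxelGeometry
# ---------------------------------------------------------------------------

#' Physical voxel geometry
#'
#' Holds the physical edge lengths of a voxel along x, y and z and the unit
#' they are expressed in. Anisotropy is permitted (confocal stacks commonly
#' have dz > dx = dy). All volumetric containers in the package carry a
#' \code{VoxelGeometry} so that lengths and densities can be reported in
#' physical units.
#'
#' Arrays are indexed slice-major as \code{[z, y, x]} throughout the package:
#' the first array index is the slice (z), matching the page order of a
#' multi-page TIFF. Voxel \code{(z, y, x)} (1-based) covers the half-open box
#' \code{[(x-1)*dx, x*dx) x [(y-1)*dy, y*dy) x [(z-1)*dz, z*dz)} with its
#' centre at the half-offsets.
#'
#' @slot dx,dy,dz positive physical edge lengths.
#' @slot unit unit label, one of \code{"um"} or \code{"sigma"}.
#' @export
setClass("VoxelGeometry",
  representation(dx = "numeric", dy = "numeric", dz = "numeric",
                 unit = "character"),
  validity = function(object) {
    msg <- NULL
    if (any(c(object@dx, object@dy, object@dz) <= 0) ||
        any(!is.finite(c(object@dx, object@dy, object@dz))))
      msg <- c(msg, "voxel edge lengths must be positive and finite")
    if (length(object@unit) != 1L || !object@unit %in% c("um", "sigma"))
      msg <- c(msg, "unit must be \"um\" or \"sigma\"")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a VoxelGeometry
#'
#' @param dx,dy,dz physical voxel edge lengths (positive).
#' @param unit unit label, \code{"um"} or \code{"sigma"}.
#' @return a \code{VoxelGeometry} object.
#' @examples
#' VoxelGeometry(0.061, 0.061, 0.12, "sigma")
#' @export
VoxelGeometry <- function(dx, dy, dz = dx, unit = "um") {
  new("VoxelGeometry", dx = as.numeric(dx), dy = as.numeric(dy),
      dz = as.numeric(dz), unit = unit)
}

#' Voxel edge lengths as a named vector
#' @param x a \code{VoxelGeometry} (or an object carrying one).
#' @return named numeric vector \code{c(dx, dy, dz)}.
#' @export
setGeneric("voxelDims", function(x) standardGeneric("voxelDims"))

#' @rdname voxelDims
#' @export
setMethod("voxelDims", "VoxelGeometry", function(x)
  c(dx = x@dx, dy = x@dy, dz = x@dz))

#' Unit label of a geometry
#' @param x a \code{VoxelGeometry} (or an object carrying one).
#' @return \code{"um"} or \code{"sigma"}.
#' @export
setGeneric("unitLabel", function(x) standardGeneric("unitLabel"))

#' @rdname unitLabel
#' @export
setMethod("unitLabel", "VoxelGeometry", function(x) x@unit)

setMethod("show", "VoxelGeometry", function(object) {
  cat(sprintf("VoxelGeometry: %g x %g x %g %s (dx x dy x dz)\n",
              object@dx, object@dy, object@dz, object@unit))
})

# ---------------------------------------------------------------------------
# Volumetric containers
# ---------------------------------------------------------------------------

.check_vol_array <- function(a, what) {
  msg <- NULL
  if (length(dim(a)) != 3L)
    msg <- c(msg, sprintf("%s must be a 3D array indexed (z, y, x)", what))
  else if (any(dim(a) < 3L))
    msg <- c(msg, sprintf("%s must have at least 3 voxels along every axis",
                          what))
  msg
}

#' 3D grayscale image stack
#'
#' A 3D grid of non-negative intensities with physical voxel geometry.
#' Indexed \code{[z, y, x]} (slice-major: z is the first index).
#'
#' @slot intensities 3D numeric array of non-negative intensities.
#' @slot geometry a \code{VoxelGeometry}.
#' @export
setClass("ImageStack",
  representation(intensities = "array", geometry = "VoxelGeometry"),
  validity = function(object) {
    msg <- .check_vol_array(object@intensities, "intensities")
    if (is.null(msg) && any(object@intensities < 0, na.rm = TRUE))
      msg <- c(msg, "intensities must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' Construct an ImageStack
#' @param intensities 3D numeric array indexed (z, y, x), non-negative.
#' @param geometry a \code{VoxelGeometry}.
#' @return an \code{ImageStack}.
#' @export
ImageStack <- function(intensities, geometry) {
  storage.mode(intensities) <- "double"
  new("ImageStack", intensities = intensities, geometry = geometry)
}

#' 3D binary volume of material voxels
#'
#' @slot material 3D logical array indexed (z, y, x); \code{TRUE} = material.
#' @slot geometry a \code{VoxelGeometry}.
#' @export
setClass("BinaryVolume",
  representation(material = "array", geometry = "VoxelGeometry"),
  validity = function(object) {
    msg <- .check_vol_array(object@material, "material")
    if (is.null(msg) && !is.logical(object@material))
      msg <- c(msg, "material must be a logical array")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a BinaryVolume
#' @param material 3D logical array indexed (z, y, x).
#' @param geometry a \code{VoxelGeometry}.
#' @return a \code{BinaryVolume}.
#' @export
BinaryVolume <- function(material, geometry) {
  storage.mode(material) <- "logical"
  new("BinaryVolume", material = material, geometry = geometry)
}

#' Single-voxel-thin skeleton
#'
#' The backbone produced by topology-preserving thinning: a set of material
#' voxels stored as a logical array of the same shape as the source volume.
#'
#' @slot voxels 3D logical array indexed (z, y, x).
#' @slot geometry a \code{VoxelGeometry}.
#' @export
setClass("Skeleton",
  representation(voxels = "array", geometry = "VoxelGeometry"),
  validity = function(object) {
    msg <- .check_vol_array(object@voxels, "voxels")
    if (is.null(msg) && !is.logical(object@voxels))
      msg <- c(msg, "voxels must be a logical array")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a Skeleton
#' @param voxels 3D logical array indexed (z, y, x).
#' @param geometry a \code{VoxelGeometry}.
#' @return a \code{Skeleton}.
#' @export
Skeleton <- function(voxels, geometry) {
  storage.mode(voxels) <- "logical"
  new("Skeleton", voxels = voxels, geometry = geometry)
}

#' Intensity array of a stack
#' @param x an \code{ImageStack}.
#' @return 3D numeric array indexed (z, y, x).
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname intensities
#' @export
setMethod("intensities", "ImageStack", function(x) x@intensities)

#' Material mask of a volumetric object
#' @param x a \code{BinaryVolume} or \code{Skeleton}.
#' @return 3D logical array indexed (z, y, x).
#' @export
setGeneric("materialMask", function(x) standardGeneric("materialMask"))
#' @rdname materialMask
#' @export
setMethod("materialMask", "BinaryVolume", function(x) x@material)
#' @rdname materialMask
#' @export
setMethod("materialMask", "Skeleton", function(x) x@voxels)

#' @rdname voxelDims
#' @export
setMethod("voxelDims", "ImageStack", function(x) voxelDims(x@geometry))
#' @rdname voxelDims
#' @export
setMethod("voxelDims", "BinaryVolume", function(x) voxelDims(x@geometry))
#' @rdname voxelDims
#' @export
setMethod("voxelDims", "Skeleton", function(x) voxelDims(x@geometry))

#' Geometry of a volumetric object
#' @param x an object carrying a \code{VoxelGeometry}.
#' @return the \code{VoxelGeometry}.
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname geometry
#' @export
setMethod("geometry", "ImageStack", function(x) x@geometry)
#' @rdname geometry
#' @export
setMethod("geometry", "BinaryVolume", function(x) x@geometry)
#' @rdname geometry
#' @export
setMethod("geometry", "Skeleton", function(x) x@geometry)

#' Grid dimensions of a volumetric object
#' @param x an \code{ImageStack}, \code{BinaryVolume} or \code{Skeleton}.
#' @return integer vector \code{c(nz, ny, nx)}.
#' @export
setGeneric("stackDim", function(x) standardGeneric("stackDim"))
#' @rdname stackDim
#' @export
setMethod("stackDim", "ImageStack", function(x) dim(x@intensities))
#' @rdname stackDim
#' @export
setMethod("stackDim", "BinaryVolume", function(x) dim(x@material))
#' @rdname stackDim
#' @export
setMethod("stackDim", "Skeleton", function(x) dim(x@voxels))

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("ImageStack: %d x %d x %d (z x y x x), range [%g, %g]\n",
              d[1], d[2], d[3], min(object@intensities),
              max(object@intensities)))
  show(object@geometry)
})

setMethod("show", "BinaryVolume", function(object) {
  d <- dim(object@material)
  cat(sprintf("BinaryVolume: %d x %d x %d (z x y x x), %d material voxels\n",
              d[1], d[2], d[3], sum(object@material)))
  show(object@geometry)
})

setMethod("show", "Skeleton", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("Skeleton: %d x %d x %d (z x y x x), %d skeleton voxels\n",
              d[1], d[2], d[3], sum(object@voxels)))
  show(object@geometry)
})

#' Skeleton voxel coordinates
#'
#' @param x a \code{Skeleton}.
#' @return integer matrix with columns \code{z, y, x} (1-based grid indices).
#' @export
setGeneric("skeletonVoxels", function(x) standardGeneric("skeletonVoxels"))
#' @rdname skeletonVoxels
#' @export
setMethod("skeletonVoxels", "Skeleton", function(x) {
  w <- which(x@voxels, arr.ind = TRUE)
  colnames(w) <- c("z", "y", "x")
  w
})

# ---------------------------------------------------------------------------
# ParticleSet and PSFKernel
# ---------------------------------------------------------------------------

#' Set of particle positions
#'
#' Particle centres in continuous physical coordinates, with a single global
#' particle diameter \code{sigma} and an axis-aligned bounding box.
#'
#' @slot positions numeric matrix with columns x, y, z (physical units).
#' @slot sigma particle diameter (same units).
#' @slot box 2 x 3 matrix: rows are (min, max), columns x, y, z.
#' @export
setClass("ParticleSet",
  representation(positions = "matrix", sigma = "numeric", box = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@positions) != 3L)
      msg <- c(msg, "positions must have 3 columns (x, y, z)")
    if (length(object@sigma) != 1L || object@sigma <= 0)
      msg <- c(msg, "sigma must be a single positive number")
    if (!all(dim(object@box) == c(2L, 3L)))
      msg <- c(msg, "box must be a 2 x 3 matrix (rows min, max)")
    else {
      eps <- 1e-9
      inside <- all(sweep(object@positions, 2, object@box[1, ], ">=") |
                      abs(sweep(object@positions, 2, object@box[1, ], "-")) < eps) &&
        all(sweep(object@positions, 2, object@box[2, ], "<=") |
              abs(sweep(object@positions, 2, object@box[2, ], "-")) < eps)
      if (nrow(object@positions) > 0 && !inside)
        msg <- c(msg, "all positions must lie inside the bounding box")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Construct a ParticleSet
#' @param positions numeric matrix (n x 3) of particle centres, columns x, y, z.
#' @param sigma particle diameter in the same units.
#' @param box optional 2 x 3 bounding box (rows min, max); defaults to the
#'   per-axis min/max of the positions.
#' @return a \code{ParticleSet}.
#' @export
ParticleSet <- function(positions, sigma, box = NULL) {
  positions <- as.matrix(positions)
  if (is.null(box)) {
    box <- rbind(apply(positions, 2, min), apply(positions, 2, max))
  }
  dimnames(positions) <- list(NULL, c("x", "y", "z"))
  dimnames(box) <- list(c("min", "max"), c("x", "y", "z"))
  new("ParticleSet", positions = positions, sigma = as.numeric(sigma),
      box = box)
}

#' Particle positions
#' @param x a \code{ParticleSet}.
#' @return numeric matrix with columns x, y, z.
#' @export
setGeneric("particlePositions", function(x) standardGeneric("particlePositions"))
#' @rdname particlePositions
#' @export
setMethod("particlePositions", "ParticleSet", function(x) x@positions)

#' Particle diameter
#' @param x a \code{ParticleSet}.
#' @return the particle diameter sigma.
#' @export
setGeneric("particleSigma", function(x) standardGeneric("particleSigma"))
#' @rdname particleSigma
#' @export
setMethod("particleSigma", "ParticleSet", function(x) x@sigma)

#' Bounding box
#' @param x a \code{ParticleSet}.
#' @return 2 x 3 matrix, rows (min, max), columns x, y, z.
#' @export
setGeneric("boundingBox", function(x) standardGeneric("boundingBox"))
#' @rdname boundingBox
#' @export
setMethod("boundingBox", "ParticleSet", function(x) x@box)

setMethod("show", "ParticleSet", function(object) {
  cat(sprintf("ParticleSet: %d particles, sigma = %g\n",
              nrow(object@positions), object@sigma))
})

#' Point-spread-function kernel
#'
#' A normalized convolution kernel sampled on the voxel grid, used to emulate
#' the blurring of a microscope when rendering particle coordinates.
#'
#' @slot weights 3D numeric array (z, y, x), non-negative, sums to 1,
#'   odd extent along every axis.
#' @slot geometry the \code{VoxelGeometry} the kernel was sampled on.
#' @export
setClass("PSFKernel",
  representation(weights = "array", geometry = "VoxelGeometry"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@weights)
    if (length(d) != 3L) msg <- c(msg, "weights must be a 3D array")
    else if (any(d %% 2L == 0L))
      msg <- c(msg, "kernel extent must be odd along every axis")
    if (any(object@weights < 0))
      msg <- c(msg, "weights must be non-negative")
    if (abs(sum(object@weights) - 1) > 1e-9)
      msg <- c(msg, "weights must sum to 1")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "PSFKernel", function(object) {
  d <- dim(object@weights)
  cat(sprintf("PSFKernel: %d x %d x %d (z x y x x)\n", d[1], d[2], d[3]))
})

# ---------------------------------------------------------------------------
# NetworkGraph
# ---------------------------------------------------------------------------

#' Node-link network graph
#'
#' The graph extracted from a skeleton. Nodes are end points or branching
#' clumps; links are voxel paths connecting node attachment voxels, with
#' physical path lengths.
#'
#' @slot nodes data.frame with columns \code{id, kind, x, y, z, degree,
#'   cycle_anchor} (positions are physical centroids of the node voxels).
#' @slot nodeVoxels list (by node) of integer matrices with columns z, y, x.
#' @slot links data.frame with columns \code{id, node_a, node_b, length,
#'   n_path}.
#' @slot paths list (by link) of integer matrices with columns z, y, x:
#'   the ordered voxel path including one attachment voxel of each endpoint
#'   node.
#' @slot geometry a \code{VoxelGeometry}.
#' @slot box 2 x 3 physical bounding box (rows min, max; columns x, y, z).
#' @slot sigma particle diameter in the geometry's units.
#' @export
setClass("NetworkGraph",
  representation(nodes = "data.frame", nodeVoxels = "list",
                 links = "data.frame", paths = "list",
                 geometry = "VoxelGeometry", box = "matrix",
                 sigma = "numeric"),
  validity = function(object) {
    msg <- NULL
    need_n <- c("id", "kind", "x", "y", "z", "degree", "cycle_anchor")
    if (!all(need_n %in% names(object@nodes)))
      msg <- c(msg, "nodes must have columns id, kind, x, y, z, degree, cycle_anchor")
    need_l <- c("id", "node_a", "node_b", "length", "n_path")
    if (!all(need_l %in% names(object@links)))
      msg <- c(msg, "links must have columns id, node_a, node_b, length, n_path")
    if (nrow(object@links) > 0 && nrow(object@nodes) > 0) {
      if (!all(c(object@links$node_a, object@links$node_b) %in%
                 object@nodes$id))
        msg <- c(msg, "every link endpoint must reference an existing node")
    } else if (nrow(object@links) > 0 && nrow(object@nodes) == 0) {
      msg <- c(msg, "links without nodes")
    }
    if (length(object@nodeVoxels) != nrow(object@nodes))
      msg <- c(msg, "nodeVoxels must have one entry per node")
    if (length(object@paths) != nrow(object@links))
      msg <- c(msg, "paths must have one entry per link")
    if (length(object@sigma) != 1L || object@sigma <= 0)
      msg <- c(msg, "sigma must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' Node table of a network graph
#' @param x a \code{NetworkGraph}.
#' @return data.frame of nodes (id, kind, x, y, z, degree, cycle_anchor).
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname networkNodes
#' @export
setMethod("networkNodes", "NetworkGraph", function(x) x@nodes)

#' Link table of a network graph
#' @param x a \code{NetworkGraph}.
#' @return data.frame of links (id, node_a, node_b, length, n_path).
#' @export
setGeneric("networkLinks", function(x) standardGeneric("networkLinks"))
#' @rdname networkLinks
#' @export
setMethod("networkLinks", "NetworkGraph", function(x) x@links)

#' Voxel paths of the links
#' @param x a \code{NetworkGraph}.
#' @return list of integer matrices (columns z, y, x), one per link.
#' @export
setGeneric("linkPaths", function(x) standardGeneric("linkPaths"))
#' @rdname linkPaths
#' @export
setMethod("linkPaths", "NetworkGraph", function(x) x@paths)

#' @rdname geometry
#' @export
setMethod("geometry", "NetworkGraph", function(x) x@geometry)

#' @rdname particleSigma
#' @export
setMethod("particleSigma", "NetworkGraph", function(x) x@sigma)

#' @rdname boundingBox
#' @export
setMethod("boundingBox", "NetworkGraph", function(x) x@box)

setMethod("show", "NetworkGraph", function(object) {
  cat(sprintf(
    "NetworkGraph: %d nodes (%d end, %d branching), %d links, sigma = %g %s\n",
    nrow(object@nodes), sum(object@nodes$kind == "end"),
    sum(object@nodes$kind == "branching"), nrow(object@links),
    object@sigma, object@geometry@unit))
})
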