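# Topology-preserving 3D thinning. The removal conditions follow the
# classical medial-axis thinning lineage: a border voxel may be deleted only
# if it is not an end point, its removal leaves the Euler characteristic
# unchanged, and it is a simple point (removal changes neither the local
# foreground connectivity nor the local background structure). Foreground
# connectivity is 26, background connectivity 6, and thinning operates on
# the voxel lattice, ignoring physical anisotropy; physical units re-enter
# only when link lengths are measured.

.as_nb27 <- function(neighborhood) {
  nb <- as.logical(neighborhood)
  if (length(nb) != 27)
    stop("neighborhood must be a 3x3x3 logical array or a 27-vector")
  nb
}

#' End-point test on a 3x3x3 neighbourhood
#'
#' A skeleton voxel is an end point when its 27-voxel neighbourhood (centre
#' included) contains exactly two material voxels: the voxel itself and one
#' neighbour.
#'
#' @param neighborhood 3x3x3 logical array indexed (z, y, x) (or a 27-vector
#'   in that order); the centre entry must be \code{TRUE}.
#' @return logical.
#' @export
isEndPoint <- function(neighborhood) {
  cpp_is_end_point(.as_nb27(neighborhood))
}

#' Euler-invariance test on a 3x3x3 neighbourhood
#'
#' \code{TRUE} when removing the centre voxel leaves the Euler characteristic
#' of the structure unchanged. The change is purely local, so it is evaluated
#' on the cubical complex of the 3x3x3 block with and without the centre.
#'
#' @inheritParams isEndPoint
#' @return logical.
#' @export
isEulerInvariant <- function(neighborhood) {
  cpp_is_euler_invariant(.as_nb27(neighborhood))
}

#' Simple-point test on a 3x3x3 neighbourhood
#'
#' \code{TRUE} when the removal of the centre voxel changes neither the
#' foreground connectivity nor the background structure of the
#' neighbourhood: the 26 neighbours must contain exactly one 26-connected
#' foreground component (paths not through the centre), and the background
#' within the 18 face-and-edge neighbours must form exactly one 6-connected
#' component touching the centre.
#'
#' @inheritParams isEndPoint
#' @return logical.
#' @export
isSimplePoint <- function(neighborhood) {
  cpp_is_simple_point(.as_nb27(neighborhood))
}

#' Thin a binary volume to a single-voxel skeleton
#'
#' Iteratively removes border material voxels that are not end points, are
#' Euler invariant and are simple points, until no voxel can be removed.
#' Each full pass visits the six border directions in the fixed order
#' (-z, +z, -y, +y, -x, +x); within a direction, candidates are collected
#' first and then re-checked sequentially in linear scan order (z fastest)
#' before actual removal, since a removal can invalidate a later candidate.
#' Voxels on the volume boundary treat out-of-bounds as background.
#'
#' The result preserves both the number of 26-connected foreground
#' components and the Euler characteristic of the input, is a subset of the
#' input material, and is a fixed point of the operation (thinning an
#' already-thin structure changes nothing).
#'
#' @param volume a \code{BinaryVolume} (or 3D logical array plus
#'   \code{geometry}).
#' @param geometry required if \code{volume} is a plain array.
#' @return a \code{Skeleton}.
#' @export
thinVolume <- function(volume, geometry = NULL) {
  if (is(volume, "BinaryVolume")) {
    m <- materialMask(volume)
    geometry <- geometry(volume)
  } else {
    m <- volume
    if (is.null(geometry)) stop("geometry required for a plain array")
  }
  out <- cpp_thin(as.logical(m), dim(m))
  dim(out) <- dim(m)
  Skeleton(out, geometry)
}
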