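# I/O for image stacks and particle coordinate tables, plus rendering of
# coordinate sets into image stacks with optional PSF convolution.

#' Physical positions of voxel centres
#'
#' @param idx integer matrix with columns z, y, x (1-based grid indices).
#' @param geom a \code{VoxelGeometry}.
#' @return numeric matrix with columns x, y, z (physical units).
#' @keywords internal
voxelCenters <- function(idx, geom) {
  d <- voxelDims(geom)
  cbind(x = (idx[, "x"] - 0.5) * d["dx"],
        y = (idx[, "y"] - 0.5) * d["dy"],
        z = (idx[, "z"] - 0.5) * d["dz"])
}

#' Read a multi-page grayscale TIFF into an ImageStack
#'
#' Reads an 8- or 16-bit grayscale multi-page TIFF. Slice count equals page
#' count and intensity values are preserved losslessly as reals. Any voxel
#' geometry stored in the TIFF metadata is ignored: physical voxel dimensions
#' always come from the supplied \code{geometry} (they are a required user
#' input, as microscope TIFF metadata is frequently wrong or absent).
#'
#' @param path path to the TIFF file.
#' @param geometry a \code{VoxelGeometry} giving the physical voxel size.
#' @param slices optional integer vector of z-slices to keep (default: all).
#' @return an \code{ImageStack} with dim (z, y, x) = (pages, rows, cols).
#' @export
readStack <- function(path, geometry, slices = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("cannot read TIFF '", path, "': ",
                           conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) != 2L)
      stop("unsupported format: page ", i, " of '", path,
           "' is not single-channel grayscale (RGB/multi-channel TIFF?)")
  }
  if (!is.null(slices)) pages <- pages[slices]
  nz <- length(pages)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
  ImageStack(arr, geometry)
}

#' Write an ImageStack or BinaryVolume as a multi-page TIFF
#'
#' Binary volumes are written as 8-bit \{0, 255\}. Grayscale stacks are
#' written as 8-bit when the maximum intensity fits, otherwise 16-bit;
#' intensities in [0, 1] are scaled to the full dynamic range. The result
#' round-trips through \code{\link{readStack}} up to this dtype scaling.
#'
#' @param x an \code{ImageStack} or \code{BinaryVolume}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeStack <- function(x, path) {
  if (is(x, "BinaryVolume") || is(x, "Skeleton")) {
    arr <- materialMask(x) * 255
    bits <- 8L
  } else if (is(x, "ImageStack")) {
    arr <- intensities(x)
    mx <- max(arr)
    if (mx <= 1) {
      bits <- 8L
      arr <- round(arr * 255)
    } else if (mx <= 255) {
      bits <- 8L
    } else if (mx <= 65535) {
      bits <- 16L
    } else {
      stop("intensities exceed the 16-bit range; rescale before writing")
    }
  } else stop("x must be an ImageStack, BinaryVolume or Skeleton")
  scale <- 2^bits - 1
  pages <- lapply(seq_len(dim(arr)[1]),
                  function(z) matrix(arr[z, , ] / scale,
                                     nrow = dim(arr)[2], ncol = dim(arr)[3]))
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = bits),
                 error = function(e)
                   stop("cannot write TIFF '", path, "': ",
                        conditionMessage(e)))
  invisible(path)
}

#' Read a particle coordinate table
#'
#' Reads a whitespace- or comma-delimited text file with at least three
#' numeric columns per row (x, y, z in physical units); additional columns
#' are ignored. Lines starting with \code{#} and blank lines are skipped.
#'
#' @param path path to the text file.
#' @param sigma particle diameter in the same units as the coordinates.
#' @param unit unit label, \code{"um"} or \code{"sigma"}.
#' @param box optional 2 x 3 bounding box; defaults to the per-axis min/max
#'   of the coordinates.
#' @return a \code{ParticleSet}.
#' @export
readCoordinates <- function(path, sigma, unit = "um", box = NULL) {
  if (!file.exists(path)) stop("cannot read coordinates: file not found: ",
                               path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("no particles in '", path, "'")
  pos <- matrix(NA_real_, nrow = length(lines), ncol = 3)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[,;[:space:]]+")[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) < 3)
      stop("parse error in '", path, "' line ", lineno[i],
           ": fewer than 3 columns")
    vals <- suppressWarnings(as.numeric(tok[1:3]))
    if (any(is.na(vals)))
      stop("parse error in '", path, "' line ", lineno[i],
           ": non-numeric coordinate")
    pos[i, ] <- vals
  }
  ParticleSet(pos, sigma = sigma, box = box)
}

#' Write a particle coordinate table
#'
#' @param particles a \code{ParticleSet}.
#' @param path output path; whitespace-delimited x y z with a \code{#} header.
#' @return invisibly, the path.
#' @export
writeCoordinates <- function(particles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# x y z", con)
  p <- particlePositions(particles)
  writeLines(sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]), con)
  invisible(path)
}

#' Default anisotropic Gaussian PSF
#'
#' Samples an anisotropic Gaussian point spread function on the voxel grid,
#' truncated at 3 standard deviations per axis and normalized to unit sum.
#' The default widths (lateral sd 0.21 sigma, axial sd 0.75 sigma in particle
#' diameters) reflect the typical lateral/axial asymmetry of a confocal
#' microscope.
#'
#' @param geometry a \code{VoxelGeometry}.
#' @param sigma_xy lateral Gaussian standard deviation (physical units).
#' @param sigma_z axial Gaussian standard deviation (physical units).
#' @return a \code{PSFKernel}.
#' @export
defaultPSF <- function(geometry, sigma_xy, sigma_z) {
  if (sigma_xy <= 0 || sigma_z <= 0) stop("PSF widths must be positive")
  d <- voxelDims(geometry)
  if (sigma_xy < d["dx"] / 2 || sigma_xy < d["dy"] / 2 ||
      sigma_z < d["dz"] / 2)
    warning("PSF width smaller than half a voxel: kernel degenerates ",
            "toward a delta")
  rx <- ceiling(3 * sigma_xy / d["dx"])
  ry <- ceiling(3 * sigma_xy / d["dy"])
  rz <- ceiling(3 * sigma_z / d["dz"])
  gx <- exp(-0.5 * ((-rx:rx) * d["dx"] / sigma_xy)^2)
  gy <- exp(-0.5 * ((-ry:ry) * d["dy"] / sigma_xy)^2)
  gz <- exp(-0.5 * ((-rz:rz) * d["dz"] / sigma_z)^2)
  w <- outer(outer(gz, gy), gx) # dim (z, y, x)
  w <- w / sum(w)
  new("PSFKernel", weights = w, geometry = geometry)
}

# Zero-padded FFT convolution of a 3D array with a centred odd-sized kernel.
fftConvolve3d <- function(arr, kernel) {
  da <- dim(arr)
  dk <- dim(kernel)
  dp <- da + dk - 1L
  pa <- array(0, dp)
  pa[seq_len(da[1]), seq_len(da[2]), seq_len(da[3])] <- arr
  pk <- array(0, dp)
  pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kernel
  conv <- Re(fft(fft(pa) * fft(pk), inverse = TRUE)) / prod(dp)
  off <- (dk - 1L) / 2L
  out <- conv[off[1] + seq_len(da[1]), off[2] + seq_len(da[2]),
              off[3] + seq_len(da[3]), drop = FALSE]
  out[out < 0] <- 0
  out
}

#' Render a particle set into an image stack
#'
#' Projects particle coordinates onto a voxel grid. In \code{"sphere"} mode
#' (default) every voxel whose centre lies within sigma/2 of any particle
#' centre receives intensity 1 (a union of solid spheres); in \code{"point"}
#' mode only the voxel containing each particle centre is lit. If a PSF
#' kernel is supplied, the binary render is convolved with it (zero-padded
#' boundaries) and rescaled to maximum 1.
#'
#' Coordinates are taken relative to the particle set's bounding-box minimum,
#' so the grid covers exactly the bounding box (expanded by half a particle
#' diameter on every side so spheres are not clipped).
#'
#' @param particles a \code{ParticleSet}.
#' @param geometry a \code{VoxelGeometry} (same units as the coordinates).
#' @param psf optional \code{PSFKernel}.
#' @param mode \code{"sphere"} or \code{"point"}.
#' @param pad extra physical padding added around the bounding box on every
#'   side (default sigma/2, so spheres at the box surface stay inside).
#' @return an \code{ImageStack} with intensities in [0, 1].
#' @export
projectParticles <- function(particles, geometry, psf = NULL,
                             mode = c("sphere", "point"), pad = NULL) {
  mode <- match.arg(mode)
  d <- voxelDims(geometry)
  sig <- particleSigma(particles)
  if (is.null(pad)) pad <- sig / 2
  if (sig < 3 * max(d["dx"], d["dy"]))
    warning("particle diameter spans fewer than 3 voxels laterally; ",
            "the rendered spheres will be heavily aliased")
  box <- boundingBox(particles)
  origin <- box[1, ] - pad
  extent <- (box[2, ] - box[1, ]) + 2 * pad
  n <- pmax(3L, as.integer(ceiling(extent / d - 1e-9)))
  names(n) <- c("x", "y", "z")
  arr <- array(FALSE, dim = c(n["z"], n["y"], n["x"]))
  pos <- sweep(particlePositions(particles), 2, origin, "-")
  r <- sig / 2

  bad <- which(pos[, 1] < 0 | pos[, 2] < 0 | pos[, 3] < 0 |
                 pos[, 1] > n["x"] * d["dx"] | pos[, 2] > n["y"] * d["dy"] |
                 pos[, 3] > n["z"] * d["dz"])
  if (length(bad) > 0)
    stop("particles outside the voxelized box: indices ",
         paste(utils::head(bad, 10), collapse = ", "))

  if (mode == "point") {
    iz <- pmin(pmax(1L, as.integer(ceiling(pos[, 3] / d["dz"]))), n["z"])
    iy <- pmin(pmax(1L, as.integer(ceiling(pos[, 2] / d["dy"]))), n["y"])
    ix <- pmin(pmax(1L, as.integer(ceiling(pos[, 1] / d["dx"]))), n["x"])
    arr[cbind(iz, iy, ix)] <- TRUE
  } else {
    for (p in seq_len(nrow(pos))) {
      px <- pos[p, 1]; py <- pos[p, 2]; pz <- pos[p, 3]
      ixr <- max(1L, floor((px - r) / d["dx"] + 0.5)):min(n["x"], ceiling((px + r) / d["dx"] + 0.5))
      iyr <- max(1L, floor((py - r) / d["dy"] + 0.5)):min(n["y"], ceiling((py + r) / d["dy"] + 0.5))
      izr <- max(1L, floor((pz - r) / d["dz"] + 0.5)):min(n["z"], ceiling((pz + r) / d["dz"] + 0.5))
      dx2 <- ((ixr - 0.5) * d["dx"] - px)^2
      dy2 <- ((iyr - 0.5) * d["dy"] - py)^2
      dz2 <- ((izr - 0.5) * d["dz"] - pz)^2
      inside <- outer(outer(dz2, dy2, "+"), dx2, "+") <= r^2
      arr[izr, iyr, ixr] <- arr[izr, iyr, ixr] | inside
    }
  }
  out <- array(as.numeric(arr), dim = dim(arr))
  if (!is.null(psf)) {
    out <- fftConvolve3d(out, psf@weights)
    mx <- max(out)
    if (mx > 0) out <- out / mx
  }
  ImageStack(out, geometry)
}
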