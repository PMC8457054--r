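# Preprocessing: Gaussian blur, per-slice binarization (percentile rule or
# Otsu), ellipsoidal morphological closing, small-cluster removal and
# 3D-enclosed hole filling. Foreground connectivity is 26 and background
# connectivity 6 throughout.

#' Separable Gaussian blur of an image stack
#'
#' Applies a separable Gaussian filter with reflective boundary handling.
#' Widths are standard deviations in voxel units per axis in (z, y, x) order
#' (a single value is recycled); a width of 0 along an axis leaves that axis
#' untouched. Blurring before binarization suppresses voxel-scale noise that
#' would otherwise seed spurious small side chains in the skeleton.
#'
#' @param stack an \code{ImageStack}.
#' @param width Gaussian standard deviation(s) in voxels, length 1 or 3
#'   (z, y, x).
#' @return a blurred \code{ImageStack}.
#' @export
gaussianBlur <- function(stack, width = 1) {
  if (length(width) == 1) width <- rep(width, 3)
  if (any(width < 0)) stop("blur widths must be >= 0")
  arr <- intensities(stack)
  for (axis in 1:3) {
    w <- width[axis]
    if (w == 0) next
    r <- max(1L, ceiling(3 * w))
    k <- exp(-0.5 * ((-r:r) / w)^2)
    k <- k / sum(k)
    arr <- cpp_convolve_axis(as.numeric(arr), dim(arr), k, axis)
    dim(arr) <- stackDim(stack)
  }
  ImageStack(arr, geometry(stack))
}

#' Percentile threshold of a single slice
#'
#' Computes the manual threshold rule I_T = I_10 + V_u (I_90 - I_10), where
#' I_10 and I_90 are the pixel intensities below which 10\% and 90\% of the
#' slice's pixel intensities fall (linear-interpolation quantiles), and V_u
#' in [0, 1] is the user control.
#'
#' @param slice 2D numeric matrix of pixel intensities.
#' @param v_u numeric in [0, 1].
#' @return a one-row data.frame with columns \code{I_10, I_90, I_T,
#'   degenerate}.
#' @export
sliceThresholdPercentile <- function(slice, v_u) {
  if (length(slice) == 0) stop("empty slice")
  if (v_u < 0 || v_u > 1) stop("v_u must lie in [0, 1]")
  qs <- stats::quantile(as.numeric(slice), c(0.1, 0.9), names = FALSE,
                        type = 7)
  i10 <- qs[1]; i90 <- qs[2]
  data.frame(I_10 = i10, I_90 = i90, I_T = i10 + v_u * (i90 - i10),
             degenerate = i10 == i90)
}

#' Otsu threshold of a single slice
#'
#' Maximizes the between-class variance over a 256-bin histogram spanning the
#' slice's intensity range; the threshold is the bin boundary with the
#' largest between-class variance (ties broken toward the lowest threshold).
#'
#' A constant slice is flagged degenerate and classifies as all background.
#' The same applies to slices whose histogram is effectively unimodal:
#' Otsu's effectiveness measure eta (the maximized between-class variance
#' over the total variance) is about 0.64 for a single Gaussian mode -- a
#' signal-free noise slice -- but close to 1 when distinct background and
#' material modes exist, so slices with eta below \code{min_eta} are
#' classified as all background rather than having their noise split in two.
#'
#' @param slice 2D numeric matrix of pixel intensities.
#' @param nbins number of histogram bins (default 256).
#' @param min_eta minimal Otsu effectiveness (default 0.75); set to 0 to
#'   disable the unimodality guard.
#' @return a one-row data.frame with columns \code{I_10, I_90, I_T,
#'   degenerate} (the percentile intensities are recorded for diagnostics).
#' @export
sliceThresholdOtsu <- function(slice, nbins = 256L, min_eta = 0.75) {
  if (length(slice) == 0) stop("empty slice")
  v <- as.numeric(slice)
  qs <- stats::quantile(v, c(0.1, 0.9), names = FALSE, type = 7)
  lo <- min(v); hi <- max(v)
  if (lo == hi) {
    return(data.frame(I_10 = qs[1], I_90 = qs[2], I_T = hi,
                      degenerate = TRUE))
  }
  edges <- seq(lo, hi, length.out = nbins + 1L)
  h <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE),
                          1L), nbins), nbins)
  w <- cumsum(h)
  n <- w[nbins]
  mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  msum <- cumsum(h * mids)
  mtot <- msum[nbins]
  # between-class variance for a split after bin k (k = 1..nbins-1)
  k <- seq_len(nbins - 1L)
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins - 1L)
  mu0 <- msum[k][valid] / w0[valid]
  mu1 <- (mtot - msum[k][valid]) / w1[valid]
  bcv[valid] <- w0[valid] * w1[valid] * (mu0 - mu1)^2
  kbest <- which.max(bcv)
  tot_var <- sum(h * (mids - mtot / n)^2)
  eta <- if (tot_var > 0) bcv[kbest] / (n * tot_var) else 0
  if (eta < min_eta) {
    # effectively unimodal: no material/background separation in this slice
    return(data.frame(I_10 = qs[1], I_90 = qs[2], I_T = hi,
                      degenerate = TRUE))
  }
  data.frame(I_10 = qs[1], I_90 = qs[2], I_T = edges[kbest + 1L],
             degenerate = FALSE)
}

#' Per-slice binarization of an image stack
#'
#' For each z-slice independently, computes a threshold (Otsu or percentile
#' rule) and classifies a voxel as material iff its intensity is strictly
#' greater than the slice threshold. Thresholding per slice compensates for
#' depth-dependent intensity drift (scattering mismatch, bleaching). A
#' degenerate (constant) slice contributes no material voxels.
#'
#' @param stack an \code{ImageStack}.
#' @param method \code{"otsu"} (default) or \code{"percentile"}.
#' @param v_u percentile-rule control in [0, 1] (percentile method only).
#' @return a list with elements \code{volume} (a \code{BinaryVolume}) and
#'   \code{thresholds} (data.frame with one row per slice: \code{slice, I_10,
#'   I_90, I_T, degenerate}).
#' @export
binarize <- function(stack, method = c("otsu", "percentile"), v_u = 0.5) {
  method <- match.arg(method)
  arr <- intensities(stack)
  nz <- dim(arr)[1]
  mat <- array(FALSE, dim(arr))
  recs <- vector("list", nz)
  for (z in seq_len(nz)) {
    slice <- arr[z, , ]
    rec <- if (method == "percentile") sliceThresholdPercentile(slice, v_u)
           else sliceThresholdOtsu(slice)
    if (!(method == "otsu" && rec$degenerate))
      mat[z, , ] <- slice > rec$I_T
    recs[[z]] <- cbind(slice = z, rec)
  }
  list(volume = BinaryVolume(mat, geometry(stack)),
       thresholds = do.call(rbind, recs))
}

# Integer offsets of a digital ellipsoid structuring element with semi-axes
# given in voxels (z, y, x order). Offsets (oz, oy, ox) are included when
# (ox/ax)^2 + (oy/ay)^2 + (oz/az)^2 <= 1. A semi-axis below 1 voxel admits
# no off-centre offset along that axis.
.ellipsoid_offsets <- function(semi_vox) {
  r <- floor(semi_vox + 1e-9)
  g <- expand.grid(dz = -r[1]:r[1], dy = -r[2]:r[2], dx = -r[3]:r[3])
  a <- pmax(semi_vox, 1e-12)
  keep <- (g$dx / a[3])^2 + (g$dy / a[2])^2 + (g$dz / a[1])^2 <= 1 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

.shift_or <- function(m, offsets, op = `|`) {
  n <- dim(m)
  r <- apply(abs(offsets), 2, max)
  p <- array(FALSE, n + 2L * r)
  iz <- r[1] + seq_len(n[1]); iy <- r[2] + seq_len(n[2])
  ix <- r[3] + seq_len(n[3])
  p[iz, iy, ix] <- m
  acc <- NULL
  for (k in seq_len(nrow(offsets))) {
    sh <- p[iz + offsets[k, 1], iy + offsets[k, 2], ix + offsets[k, 3],
            drop = FALSE]
    acc <- if (is.null(acc)) sh else op(acc, sh)
  }
  dim(acc) <- n
  acc
}

#' Morphological closing with a digital ellipsoid
#'
#' Dilation followed by erosion with an ellipsoidal structuring element whose
#' semi-axes are given in physical units and converted to voxels per axis, so
#' anisotropic voxels yield an anisotropic digital element. Two structures
#' merge when their binarized shapes are closer than twice the element
#' radius. Radii of 0 (or below one voxel on every axis) leave the volume
#' unchanged. The operation is extensive (never removes material) and
#' idempotent.
#'
#' The volume is padded with background by the element radius before the
#' dilation so that material at the volume face is not eroded away.
#'
#' @param volume a \code{BinaryVolume}.
#' @param radii physical semi-axes, length 1 or 3 in (x, y, z) order.
#' @return a closed \code{BinaryVolume}.
#' @export
morphologicalClose <- function(volume, radii) {
  if (length(radii) == 1) radii <- rep(radii, 3)
  if (any(radii < 0)) stop("closing radii must be >= 0")
  d <- voxelDims(volume)
  semi_vox <- c(radii[3] / d["dz"], radii[2] / d["dy"], radii[1] / d["dx"])
  offs <- .ellipsoid_offsets(semi_vox)
  if (nrow(offs) <= 1) return(volume)
  m <- materialMask(volume)
  n <- dim(m)
  r <- apply(abs(offs), 2, max)
  # work in a frame padded by the element radius so closing stays extensive
  big <- array(FALSE, n + 2L * r)
  iz <- r[1] + seq_len(n[1]); iy <- r[2] + seq_len(n[2])
  ix <- r[3] + seq_len(n[3])
  big[iz, iy, ix] <- m
  dil <- .shift_or(big, offs, `|`)
  ero <- .shift_or(dil, offs, `&`)
  out <- ero[iz, iy, ix, drop = FALSE]
  dim(out) <- n
  BinaryVolume(out | m, geometry(volume))
}

#' Remove small unconnected clusters
#'
#' Labels 26-connected material components and deletes every component whose
#' voxel count is strictly below \code{min_fraction} times the total material
#' voxel count. Surviving components keep distinct labels so they can be
#' analyzed as separate network structures.
#'
#' @param volume a \code{BinaryVolume}.
#' @param min_fraction numeric in [0, 1].
#' @return list with \code{volume} (cleaned \code{BinaryVolume}),
#'   \code{cluster_sizes} (sizes of all input components, decreasing),
#'   \code{labels} (integer array labelling surviving components, 0 =
#'   background).
#' @export
removeSmallClusters <- function(volume, min_fraction = 0.01) {
  if (min_fraction < 0 || min_fraction > 1)
    stop("min_fraction must lie in [0, 1]")
  m <- materialMask(volume)
  lab <- cpp_label_components(as.logical(m), dim(m), 26L)
  dim(lab) <- dim(m)
  sizes <- tabulate(lab[lab > 0])
  total <- sum(sizes)
  if (total == 0)
    return(list(volume = volume, cluster_sizes = integer(0), labels = lab))
  keep <- which(sizes >= min_fraction * total)
  if (length(keep) == 0)
    stop("no structure survives cluster removal; cluster sizes: ",
         paste(sort(sizes, decreasing = TRUE), collapse = ", "))
  out <- array(lab %in% keep, dim(m))
  newlab <- array(0L, dim(m))
  for (i in seq_along(keep)) newlab[lab == keep[i]] <- i
  list(volume = BinaryVolume(out, geometry(volume)),
       cluster_sizes = sort(sizes, decreasing = TRUE),
       labels = newlab)
}

#' Fill 3D-enclosed holes
#'
#' Background components (6-connected) that touch no face of the volume and
#' contain at most \code{max_hole_voxels} voxels are set to material. Larger
#' or face-touching background (e.g. the lumen of a tube open at both ends)
#' is left untouched.
#'
#' @param volume a \code{BinaryVolume}.
#' @param max_hole_voxels maximum hole size in voxels (>= 0).
#' @return a \code{BinaryVolume}.
#' @export
fillHoles <- function(volume, max_hole_voxels) {
  if (max_hole_voxels < 0) stop("max_hole_voxels must be >= 0")
  m <- materialMask(volume)
  n <- dim(m)
  lab <- cpp_label_components(as.logical(!m), n, 6L)
  dim(lab) <- n
  if (max(lab) == 0) return(volume)
  face <- unique(c(lab[1, , ], lab[n[1], , ], lab[, 1, ], lab[, n[2], ],
                   lab[, , 1], lab[, , n[3]]))
  sizes <- tabulate(lab[lab > 0])
  fill <- setdiff(which(sizes <= max_hole_voxels), face)
  if (length(fill) == 0) return(volume)
  out <- m | array(lab %in% fill, n)
  BinaryVolume(out, geometry(volume))
}

#' Full preprocessing of an image stack
#'
#' Runs the standard chain: Gaussian blur, per-slice binarization,
#' morphological closing, small-cluster removal and enclosed-hole filling,
#' and reconciles the input and output volumes in a report. Thresholds are
#' computed on the blurred stack.
#'
#' @param stack an \code{ImageStack}.
#' @param sigma particle diameter in the geometry's physical units; supplies
#'   the defaults for closing radii (0.25 sigma) and the maximum hole size
#'   (the voxel volume of one particle).
#' @param blur_width Gaussian widths in voxels (see
#'   \code{\link{gaussianBlur}}).
#' @param method,v_u binarization settings (see \code{\link{binarize}}).
#' @param closing_radii physical semi-axes of the closing element; default
#'   0.25 sigma on every axis.
#' @param min_fraction small-cluster threshold fraction of total material.
#' @param max_hole_voxels maximum enclosed-hole size in voxels; default the
#'   voxel volume of a ball of diameter sigma.
#' @return list with \code{volume} (final \code{BinaryVolume}),
#'   \code{binarized} (\code{BinaryVolume} straight after thresholding),
#'   \code{labels}, and \code{report} (list: \code{thresholds} data.frame,
#'   \code{added}/\code{removed} voxel-count and index sets,
#'   \code{cluster_sizes}).
#' @export
preprocessVolume <- function(stack, sigma, blur_width = 1,
                             method = c("otsu", "percentile"), v_u = 0.5,
                             closing_radii = NULL, min_fraction = 0.01,
                             max_hole_voxels = NULL) {
  method <- match.arg(method)
  d <- voxelDims(stack)
  if (is.null(closing_radii)) closing_radii <- rep(0.25 * sigma, 3)
  if (is.null(max_hole_voxels))
    max_hole_voxels <- ceiling(pi / 6 * sigma^3 / prod(d))
  blurred <- gaussianBlur(stack, blur_width)
  b <- binarize(blurred, method = method, v_u = v_u)
  closed <- morphologicalClose(b$volume, closing_radii)
  rc <- removeSmallClusters(closed, min_fraction)
  filled <- fillHoles(rc$volume, max_hole_voxels)
  m0 <- materialMask(b$volume)
  m1 <- materialMask(filled)
  report <- list(thresholds = b$thresholds,
                 added = which(m1 & !m0),
                 removed = which(m0 & !m1),
                 cluster_sizes = rc$cluster_sizes)
  list(volume = filled, binarized = b$volume, labels = rc$labels,
       report = report)
}

# ---------------------------------------------------------------------------
# Diagnostic overlays
# ---------------------------------------------------------------------------

.norm01 <- function(a) {
  mx <- max(a)
  if (mx > 0) a / mx else a
}

#' Binarization overlay (green = material, red = non-material)
#'
#' Reproduces the binarization diagnostic: the raw image rendered with the
#' material voxels in the green channel and non-material voxels in the red
#' channel, each scaled by the local intensity (voxels with little intensity
#' stay dark).
#'
#' @param stack the raw \code{ImageStack}.
#' @param volume the \code{BinaryVolume} from binarization.
#' @return a 4D numeric array (z, y, x, channel) with values in [0, 1].
#' @export
binarizationOverlay <- function(stack, volume) {
  a <- .norm01(intensities(stack))
  m <- materialMask(volume)
  out <- array(0, c(dim(a), 3))
  out[, , , 1] <- a * !m
  out[, , , 2] <- a * m
  out
}

#' Preprocessing difference overlay
#'
#' White = material unaltered by preprocessing, green = material added
#' (closing, hole filling), red = material removed (cluster removal).
#'
#' @param before \code{BinaryVolume} straight after binarization.
#' @param after final preprocessed \code{BinaryVolume}.
#' @return a 4D numeric array (z, y, x, channel) with values in [0, 1].
#' @export
preprocessDiffOverlay <- function(before, after) {
  b <- materialMask(before)
  a <- materialMask(after)
  out <- array(0, c(dim(a), 3))
  unchanged <- a & b
  added <- a & !b
  removed <- b & !a
  out[, , , 1] <- unchanged + removed
  out[, , , 2] <- unchanged + added
  out[, , , 3] <- unchanged * 1
  out
}

#' Write an RGB stack as a multi-page TIFF
#'
#' @param rgb 4D numeric array (z, y, x, channel), values in [0, 1].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeRGBStack <- function(rgb, path) {
  pages <- lapply(seq_len(dim(rgb)[1]), function(z) rgb[z, , , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
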