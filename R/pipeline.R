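# End-to-end orchestration: configuration handling, the full
# preprocess -> skeletonize -> graph -> clean -> analyze pipeline, artifact
# export and visualization overlays.

#' Default run configuration
#'
#' Builds the full configuration for \code{\link{runPipeline}} with every
#' default documented. Length thresholds are expressed in multiples of the
#' particle diameter sigma and converted to physical units at run time.
#'
#' @param input input file path(s) (TIFF stack or coordinate table).
#' @param input_kind \code{"tiff"} or \code{"coordinates"}.
#' @param voxel physical voxel dimensions c(dx, dy, dz).
#' @param unit \code{"um"} or \code{"sigma"}.
#' @param sigma particle diameter in the same physical units.
#' @param slices optional z-slice range (integer vector) for TIFF input.
#' @param method binarization method, \code{"otsu"} or \code{"percentile"}.
#' @param v_u percentile-rule control in [0, 1].
#' @param blur_width Gaussian blur standard deviation(s), voxels.
#' @param closing_radii closing element semi-axes in sigma (default 0.25).
#' @param min_fraction small-cluster threshold fraction (default 0.01).
#' @param max_hole_voxels max enclosed-hole size in voxels (default: the
#'   voxel volume of one particle, computed at run time).
#' @param min_side_chain side-chain pruning threshold in sigma (default 1.5).
#' @param node_collect_dist node collection distance in sigma (default 0.9).
#' @param max_iterations cleaning iteration cap (default 10).
#' @param margin edge-exclusion margin in sigma (default 1.5).
#' @param bins link-length histogram bins (default 20).
#' @param psf_enabled render coordinates through a PSF (default FALSE).
#' @param psf_sigma_xy,psf_sigma_z PSF widths in sigma (defaults 0.21, 0.75).
#' @param render_mode \code{"sphere"} or \code{"point"} for coordinates.
#' @param out_dir output directory (default \code{"netskel_out"}).
#' @param overlays write diagnostic overlay TIFFs (default TRUE).
#' @param seed integer seed recorded with the run.
#' @return a named list (class \code{netskel_config}).
#' @export
runConfig <- function(input = NULL, input_kind = c("tiff", "coordinates"),
                      voxel = c(1, 1, 1), unit = "um", sigma = 1,
                      slices = NULL,
                      method = c("otsu", "percentile"), v_u = 0.5,
                      blur_width = 1, closing_radii = 0.25,
                      min_fraction = 0.01, max_hole_voxels = NULL,
                      min_side_chain = 1.5, node_collect_dist = 0.9,
                      max_iterations = 10L, margin = 1.5, bins = 20,
                      psf_enabled = FALSE, psf_sigma_xy = 0.21,
                      psf_sigma_z = 0.75,
                      render_mode = c("sphere", "point"),
                      out_dir = "netskel_out", overlays = TRUE, seed = 1L) {
  cfg <- list(input = input, input_kind = match.arg(input_kind),
              voxel = as.numeric(voxel), unit = unit,
              sigma = as.numeric(sigma), slices = slices,
              method = match.arg(method), v_u = v_u,
              blur_width = blur_width, closing_radii = closing_radii,
              min_fraction = min_fraction,
              max_hole_voxels = max_hole_voxels,
              min_side_chain = min_side_chain,
              node_collect_dist = node_collect_dist,
              max_iterations = as.integer(max_iterations),
              margin = margin, bins = bins,
              psf_enabled = isTRUE(psf_enabled),
              psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
              render_mode = match.arg(render_mode),
              out_dir = out_dir, overlays = isTRUE(overlays),
              seed = as.integer(seed))
  if (length(cfg$voxel) == 1) cfg$voxel <- rep(cfg$voxel, 3)
  if (length(cfg$voxel) != 3) stop("invalid config field 'voxel': need 1 or 3 values")
  if (cfg$sigma <= 0) stop("invalid config field 'sigma': must be > 0")
  if (cfg$v_u < 0 || cfg$v_u > 1) stop("invalid config field 'v_u': must lie in [0, 1]")
  if (cfg$margin < 0) stop("invalid config field 'margin': must be >= 0")
  class(cfg) <- "netskel_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' The file holds one key per \code{\link{runConfig}} field; unknown keys are
#' an error. The configuration round-trips losslessly through
#' \code{\link{writeRunConfig}}.
#'
#' @param path YAML file path.
#' @return a \code{netskel_config}.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("invalid config field(s): ", paste(bad, collapse = ", "))
  do.call(runConfig, raw)
}

#' Write a run configuration to a YAML file
#'
#' @param config a \code{netskel_config}.
#' @param path output YAML path.
#' @return invisibly, the path.
#' @export
writeRunConfig <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, TRUE)]
  yaml::write_yaml(x, path)
  invisible(path)
}

.log_line <- function(log, ...) c(log, paste0(...))

#' Run the full analysis pipeline
#'
#' Executes, per input file: input loading (TIFF stack or coordinate table
#' rendered to a stack), preprocessing (blur, per-slice binarization,
#' closing, cluster removal, hole filling), skeletonization, graph
#' extraction and cleaning, skeleton rebuild, and quantitative analysis.
#' Writes node/link tables, a JSON report, the histogram CSV, the cleaned
#' skeleton TIFF, diagnostic overlays and a log recording every parameter
#' the run actually used and per-stage voxel/node/link counts. With several
#' inputs, per-file outputs go to numbered subdirectories and pooled
#' statistics (mean over files) are written at the top level.
#'
#' @param config a \code{netskel_config} from \code{\link{runConfig}} or
#'   \code{\link{readRunConfig}}.
#' @return invisibly, a list of per-file results (each with \code{graph},
#'   \code{skeleton}, \code{report}, \code{paths} of artifacts).
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "netskel_config")) config <- do.call(runConfig, config)
  if (is.null(config$input)) stop("invalid config field 'input': missing")
  inputs <- config$input
  multi <- length(inputs) > 1
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    outdir <- if (multi) file.path(config$out_dir, sprintf("input_%02d", i))
              else config$out_dir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    results[[i]] <- .run_single(inputs[i], config, outdir)
  }
  if (multi) {
    pool <- list(
      n_inputs = length(inputs),
      rho_N_sigma = mean(vapply(results, function(r)
        r$report$summary$rho_N_sigma, 0)),
      rho_L_sigma = mean(vapply(results, function(r)
        r$report$summary$rho_L_sigma, 0)),
      links_per_node = mean(vapply(results, function(r)
        r$report$summary$links_per_node, 0)),
      xi_mean = mean(vapply(results, function(r)
        if (is.null(r$report$tortuosity)) NA_real_
        else r$report$tortuosity$xi_mean, 0), na.rm = TRUE),
      xi_std_over_inputs = stats::sd(vapply(results, function(r)
        if (is.null(r$report$tortuosity)) NA_real_
        else r$report$tortuosity$xi_mean, 0), na.rm = TRUE))
    jsonlite::write_json(pool, file.path(config$out_dir, "pooled.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(results)
}

.run_single <- function(input, config, outdir) {
  log <- character(0)
  log <- .log_line(log, "input: ", input, " (", config$input_kind, ")")
  geom <- VoxelGeometry(config$voxel[1], config$voxel[2], config$voxel[3],
                        config$unit)
  sigma <- config$sigma
  log <- .log_line(log, "voxel: ", paste(config$voxel, collapse = " x "),
                   " ", config$unit, "; sigma: ", sigma)

  if (config$input_kind == "tiff") {
    stack <- readStack(input, geom, slices = config$slices)
  } else {
    particles <- readCoordinates(input, sigma = sigma, unit = config$unit)
    psf <- if (config$psf_enabled)
      defaultPSF(geom, config$psf_sigma_xy * sigma,
                 config$psf_sigma_z * sigma) else NULL
    stack <- projectParticles(particles, geom, psf = psf,
                              mode = config$render_mode, pad = 0)
    log <- .log_line(log, "rendered ", nrow(particlePositions(particles)),
                     " particles; psf: ", config$psf_enabled)
  }
  log <- .log_line(log, "stack: ", paste(stackDim(stack), collapse = " x "),
                   " (z y x)")

  pre <- preprocessVolume(stack, sigma = sigma,
                          blur_width = config$blur_width,
                          method = config$method, v_u = config$v_u,
                          closing_radii = rep(config$closing_radii * sigma, 3),
                          min_fraction = config$min_fraction,
                          max_hole_voxels = config$max_hole_voxels)
  log <- .log_line(log, "binarization method: ", config$method,
                   "; v_u: ", config$v_u,
                   "; blur_width: ", paste(config$blur_width, collapse = " "),
                   " voxels")
  log <- .log_line(log, "closing radii: ", config$closing_radii,
                   " sigma; min_fraction: ", config$min_fraction,
                   "; max_hole_voxels: ",
                   if (is.null(config$max_hole_voxels)) "auto (1 particle)"
                   else config$max_hole_voxels)
  log <- .log_line(log, "material voxels after preprocessing: ",
                   sum(materialMask(pre$volume)),
                   " (added ", length(pre$report$added), ", removed ",
                   length(pre$report$removed), "); clusters: ",
                   paste(pre$report$cluster_sizes, collapse = ", "))

  skel <- thinVolume(pre$volume)
  log <- .log_line(log, "skeleton voxels: ", sum(materialMask(skel)))

  graph <- extractGraph(skel, sigma = sigma)
  log <- .log_line(log, "raw graph: ", nrow(networkNodes(graph)), " nodes, ",
                   nrow(networkLinks(graph)), " links")
  params <- cleaningParams(sigma,
                           min_side_chain = config$min_side_chain * sigma,
                           node_collect_dist = config$node_collect_dist * sigma,
                           max_iterations = config$max_iterations)
  graph <- cleanGraph(graph, params)
  log <- .log_line(log, "cleaning: min_side_chain ", config$min_side_chain,
                   " sigma, node_collect_dist ", config$node_collect_dist,
                   " sigma, max_iterations ", config$max_iterations)
  log <- .log_line(log, "cleaned graph: ", nrow(networkNodes(graph)),
                   " nodes, ", nrow(networkLinks(graph)), " links")

  cleaned_skel <- graphToSkeleton(graph, stackDim(skel))
  report <- analyzeNetwork(graph, cleaned_skel,
                           margin = config$margin * sigma,
                           bins = config$bins)
  log <- .log_line(log, "margin: ", config$margin, " sigma; N_N = ",
                   report$summary$N_N, ", N_L = ", report$summary$N_L)

  paths <- .write_artifacts(stack, pre, cleaned_skel, graph, report, config,
                            outdir)
  writeLines(log, file.path(outdir, "log.txt"))
  list(graph = graph, skeleton = cleaned_skel, report = report,
       preprocess = pre, paths = paths)
}

.report_json <- function(report) {
  s <- report$summary
  out <- list(
    N_N = s$N_N, N_L = s$N_L, links_per_node = s$links_per_node,
    rho_N = s$rho_N, rho_L = s$rho_L,
    rho_N_sigma = s$rho_N_sigma, rho_L_sigma = s$rho_L_sigma,
    analysis_volume = s$analysis_volume, unit = s$unit, margin = s$margin,
    histogram = list(bin_edges = report$histogram$bin_edges,
                     counts = report$histogram$counts,
                     normalized = report$histogram$normalized))
  if (!is.null(report$tortuosity)) {
    out$tortuosity <- list(xi_mean = report$tortuosity$xi_mean,
                           xi_std = report$tortuosity$xi_std,
                           n_paths = report$tortuosity$n_paths,
                           percolating = report$tortuosity$percolating)
  }
  if (!is.null(report$components)) out$components <- report$components
  out
}

.write_artifacts <- function(stack, pre, skel, graph, report, config,
                             outdir) {
  p <- list()
  nodes <- networkNodes(graph)
  links <- networkLinks(graph)
  p$nodes <- file.path(outdir, "nodes.csv")
  utils::write.csv(nodes[, c("id", "kind", "x", "y", "z", "degree")],
                   p$nodes, row.names = FALSE)
  p$links <- file.path(outdir, "links.csv")
  utils::write.csv(links, p$links, row.names = FALSE)
  p$report <- file.path(outdir, "report.json")
  jsonlite::write_json(.report_json(report), p$report, auto_unbox = TRUE,
                       digits = NA)
  h <- report$histogram
  p$histogram <- file.path(outdir, "histogram.csv")
  if (!h$empty) {
    centers <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
    utils::write.csv(data.frame(bin_center = centers, count = h$counts,
                                normalized = h$normalized),
                     p$histogram, row.names = FALSE)
  } else {
    utils::write.csv(data.frame(bin_center = numeric(0), count = integer(0),
                                normalized = numeric(0)),
                     p$histogram, row.names = FALSE)
  }
  p$skeleton <- file.path(outdir, "skeleton.tif")
  writeStack(skel, p$skeleton)
  if (config$overlays) {
    p$binarization_overlay <- file.path(outdir, "binarization_overlay.tif")
    writeRGBStack(binarizationOverlay(stack, pre$binarized),
                  p$binarization_overlay)
    p$preprocess_diff <- file.path(outdir, "preprocess_diff.tif")
    writeRGBStack(preprocessDiffOverlay(pre$binarized, pre$volume),
                  p$preprocess_diff)
    ov <- renderOverlays(stack, skel, graph, outdir)
    p <- c(p, ov)
  }
  p
}

#' Skeleton and node overlays plus projections
#'
#' Writes (i) a per-slice RGB TIFF with the raw grayscale image as
#' background, skeleton voxels in green and branching-node voxels in blue,
#' and (ii) three maximum-intensity projections of the skeleton as static
#' renderings.
#'
#' @param stack the raw \code{ImageStack}.
#' @param skeleton the cleaned \code{Skeleton} (same shape).
#' @param graph the cleaned \code{NetworkGraph} (branching-node voxels are
#'   taken from it).
#' @param outdir output directory.
#' @return named list of written file paths.
#' @export
renderOverlays <- function(stack, skeleton, graph, outdir) {
  if (!all(stackDim(stack) == stackDim(skeleton)))
    stop("stack and skeleton shapes differ")
  a <- .norm01(intensities(stack))
  m <- materialMask(skeleton)
  d <- dim(a)
  rgb <- array(0, c(d, 3))
  bg <- a * (1 - m) # grayscale background outside the skeleton
  rgb[, , , 1] <- bg
  rgb[, , , 2] <- pmin(1, bg + m)
  rgb[, , , 3] <- bg
  nodes <- networkNodes(graph)
  bidx <- which(nodes$kind == "branching")
  if (length(bidx)) {
    vm <- do.call(rbind, graph@nodeVoxels[bidx])
    vm <- vm[vm[, 1] <= d[1] & vm[, 2] <= d[2] & vm[, 3] <= d[3], ,
             drop = FALSE]
    n3 <- prod(d)
    lin <- vm[, 1] + d[1] * (vm[, 2] - 1) + d[1] * d[2] * (vm[, 3] - 1)
    for (ch in 1:3) {
      plane <- rgb[, , , ch]
      plane[lin] <- if (ch == 3) 1 else 0
      rgb[, , , ch] <- plane
    }
  }
  p <- list()
  p$skeleton_overlay <- file.path(outdir, "skeleton_overlay.tif")
  writeRGBStack(rgb, p$skeleton_overlay)
  # maximum-intensity projections of the skeleton along each axis
  for (ax in 1:3) {
    mip <- apply(m, setdiff(1:3, ax), max)
    nm <- c("z", "y", "x")[ax]
    p[[paste0("mip_", nm)]] <- file.path(outdir,
                                         sprintf("skeleton_mip_%s.tif", nm))
    tiff::writeTIFF(mip * 1.0, p[[paste0("mip_", nm)]],
                    bits.per.sample = 8L)
  }
  p
}
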