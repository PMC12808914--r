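#' @include AllClasses.R
NULL

#' Construct a grayscale stack / voxel volume
#'
#' @param data 3D array (intensities in 0-255 for the stack; 0/1 labels for
#'   the volume).
#' @param voxelSize numeric(3), physical voxel edges (nm at FIB/SEM scale).
#' @param origin numeric(3), physical coordinate of the first voxel corner.
#' @return a [GrayscaleStack-class] or [VoxelVolume-class].
#' @export
grayscaleStack <- function(data, voxelSize = c(1, 1, 1)) {
  new("GrayscaleStack", data = data, voxelSize = as.numeric(voxelSize))
}

#' @rdname grayscaleStack
#' @export
voxelVolume <- function(data, voxelSize = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(data) <- "integer"
  new("VoxelVolume", data = data, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' Threshold a grayscale stack into pore/solid labels
#'
#' Voxels with intensity <= threshold become pore (or >= threshold with
#' `poreBelow = FALSE`). An optional Gaussian pre-blur (sigma in voxels)
#' stands in for the instrument software's noise filtering.
#'
#' @param stack a [GrayscaleStack-class].
#' @param threshold intensity threshold in [0, 255].
#' @param poreBelow logical: pore phase is the darker one (default).
#' @param blurSigma Gaussian blur sigma in voxels applied before
#'   thresholding; 0 disables.
#' @return a [VoxelVolume-class] carrying the stack's voxel size.
#' @export
binarize <- function(stack, threshold, poreBelow = TRUE, blurSigma = 0) {
  stopifnot(is(stack, "GrayscaleStack"))
  if (threshold < 0 || threshold > 255) stop("threshold must be in [0, 255]")
  x <- stack@data
  if (blurSigma > 0) x <- gaussianBlur3d(x, blurSigma)
  lab <- if (poreBelow) (x <= threshold) else (x >= threshold)
  voxelVolume(lab + 0L, voxelSize = stack@voxelSize)
}

# separable FFT-free Gaussian blur along each axis (reflected edges)
gaussianBlur3d <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  blur_axis <- function(a, axis) {
    a <- aperm(a, switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3),
                         `3` = c(3, 2, 1)))
    d <- dim(a)
    m <- matrix(a, nrow = d[1])
    idx <- c(rev(seq_len(r)), seq_len(d[1]), d[1] - seq_len(r) + 1L)
    padded <- m[idx, , drop = FALSE]
    out <- matrix(0, nrow = d[1], ncol = ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * padded[(j - 1L) + seq_len(d[1]), , drop = FALSE]
    a <- array(out, d)
    aperm(a, switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3),
                    `3` = c(3, 2, 1)))
  }
  for (ax in 1:3) x <- blur_axis(x, ax)
  x
}

#' Porosity fraction of a labeled volume
#'
#' @param vox a [VoxelVolume-class].
#' @return pore voxels / total voxels * 100 (percent).
#' @export
porosityFraction <- function(vox) {
  stopifnot(is(vox, "VoxelVolume"))
  mean(vox@data == 1L) * 100
}

#' Pore-network connectivity
#'
#' Connected-component labeling of the pore phase (26-connectivity by
#' default, the common percolation choice). Reports the number of
#' components, the fraction of pore voxels in the largest component, and
#' whether that component spans two opposite volume faces. With
#' `faceSpanningRule = TRUE` the "connected network" is instead taken as
#' the union of components touching at least two opposite faces.
#'
#' @param vox a [VoxelVolume-class] with at least one pore voxel.
#' @param connectivity 26 or 6.
#' @param faceSpanningRule alternative operationalization of "part of a
#'   connected network" (see Details).
#' @return list with `nComponents`, `largestComponentFraction` (percent),
#'   `faceSpanning` (logical) and, when `faceSpanningRule`,
#'   `spanningFraction` (percent of pore voxels in face-spanning
#'   components).
#' @export
connectivity <- function(vox, connectivity = 26, faceSpanningRule = FALSE) {
  stopifnot(is(vox, "VoxelVolume"), connectivity %in% c(6, 26))
  mask <- vox@data == 1L
  if (!any(mask)) stop("no pore voxels")
  lab <- .label3d(as.logical(mask), dim(mask), as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  big <- which.max(sizes)
  d <- dim(mask)
  touches <- function(lb) {
    c(any(lab[1, , ] == lb), any(lab[d[1], , ] == lb),
      any(lab[, 1, ] == lb), any(lab[, d[2], ] == lb),
      any(lab[, , 1] == lb), any(lab[, , d[3]] == lb))
  }
  tb <- touches(big)
  spanning <- (tb[1] && tb[2]) || (tb[3] && tb[4]) || (tb[5] && tb[6])
  out <- list(nComponents = length(sizes),
              largestComponentFraction = sizes[big] / sum(sizes) * 100,
              faceSpanning = spanning)
  if (faceSpanningRule) {
    span_ids <- which(vapply(seq_along(sizes), function(lb) {
      tt <- touches(lb)
      (tt[1] && tt[2]) || (tt[3] && tt[4]) || (tt[5] && tt[6])
    }, logical(1)))
    out$spanningFraction <- sum(sizes[span_ids]) / sum(sizes) * 100
  }
  out
}

#' Local thickness (largest inscribed sphere) of a phase
#'
#' For every voxel of the phase, thickness is the diameter of the largest
#' sphere fully contained in the phase that covers the voxel, computed via a
#' Euclidean distance transform followed by sphere propagation. The sphere
#' radius at a center voxel is its distance to the near face of the nearest
#' background voxel (sqrt(EDT^2) - 0.5 voxels); the volume boundary counts
#' as background, so spheres must fit inside the grid. Anisotropic voxels
#' are first resampled to the smallest spacing by nearest neighbor, since
#' inscribed-sphere semantics require isotropy.
#'
#' The histogram is volume-weighted with a fixed bin width of 2 voxels.
#'
#' @param vox a [VoxelVolume-class].
#' @param phase "pore" or "solid".
#' @return a [ThicknessMap-class]; thickness values carry the physical unit
#'   of `voxelSize`.
#' @export
localThickness <- function(vox, phase = c("pore", "solid")) {
  stopifnot(is(vox, "VoxelVolume"))
  phase <- match.arg(phase)
  arr <- vox@data
  vs <- vox@voxelSize
  iso <- min(vs)
  if (max(abs(vs - iso)) > 1e-12 * iso) {
    d <- dim(arr)
    newd <- pmax(1L, as.integer(round(d * vs / iso)))
    ix <- pmin(d[1], pmax(1L, as.integer(ceiling((seq_len(newd[1]) - 0.5) *
                                                   d[1] / newd[1]))))
    iy <- pmin(d[2], pmax(1L, as.integer(ceiling((seq_len(newd[2]) - 0.5) *
                                                   d[2] / newd[2]))))
    iz <- pmin(d[3], pmax(1L, as.integer(ceiling((seq_len(newd[3]) - 0.5) *
                                                   d[3] / newd[3]))))
    arr <- arr[ix, iy, iz]
  }
  mask <- if (phase == "pore") arr == 1L else arr == 0L
  if (!any(mask)) stop("phase is empty")
  edt2 <- .edt3d(as.logical(mask), dim(mask))
  th_vox <- .localThickness3d(as.logical(mask), edt2, dim(mask))
  th <- th_vox * iso
  vals <- th[mask]
  bw <- 2 * iso
  breaks <- seq(0, max(vals) + bw, by = bw)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  hist_df <- data.frame(mid = h$mids, fraction = h$counts / length(vals))
  new("ThicknessMap", thickness = th, phase = phase, voxelSize = iso,
      histogram = hist_df,
      meanThickness = mean(vals), maxThickness = max(vals))
}

#' Compare two thickness maps
#'
#' @param mapA,mapB [ThicknessMap-class] objects for the same phase.
#' @return list with mean/median thickness per map, their differences, and
#'   an overlay data.frame of both histograms.
#' @export
compareStructures <- function(mapA, mapB) {
  stopifnot(is(mapA, "ThicknessMap"), is(mapB, "ThicknessMap"))
  if (mapA@phase != mapB@phase)
    stop("thickness maps are for different phases")
  va <- mapA@thickness[mapA@thickness > 0]
  vb <- mapB@thickness[mapB@thickness > 0]
  ha <- mapA@histogram; ha$map <- "A"
  hb <- mapB@histogram; hb$map <- "B"
  list(meanA = mean(va), meanB = mean(vb),
       medianA = stats::median(va), medianB = stats::median(vb),
       meanDifference = mean(va) - mean(vb),
       medianDifference = stats::median(va) - stats::median(vb),
       histograms = rbind(ha, hb))
}

#' TIFF stack I/O for voxel data
#'
#' Multi-page 8-bit grayscale TIFF, one page per z-slice, plus a JSON
#' sidecar recording dims, dtype, voxel size and axis order. `readVoxelTiff`
#' reconstructs a [GrayscaleStack-class] (or a [VoxelVolume-class] when the
#' sidecar marks the data as labels).
#'
#' @param x a [GrayscaleStack-class] or [VoxelVolume-class].
#' @param path TIFF file path; the sidecar is `<path>.json`.
#' @return writer: `path`, invisibly; reader: the reconstructed object.
#' @export
writeVoxelTiff <- function(x, path) {
  arr <- voxelData(x)
  is_label <- is(x, "VoxelVolume")
  scale <- if (is_label) 255 else 1
  pages <- lapply(seq_len(dim(arr)[3]),
                  function(k) arr[, , k] * scale / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  side <- list(dims = dim(arr), dtype = "uint8",
               voxel_size = voxelSize(x), axis_order = "xyz",
               labels = is_label)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeVoxelTiff
#' @export
readVoxelTiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, side$dims)
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * 255
  if (isTRUE(side$labels))
    voxelVolume(as.integer(round(arr / 255)) |> array(side$dims),
                voxelSize = side$voxel_size)
  else grayscaleStack(round(arr), voxelSize = side$voxel_size)
}
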