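#' @include AllClasses.R
NULL

#' Construct a lattice-cube specification
#'
#' Reproduces the two printed lattice designs literally. Both are a centered
#' cube of edge `a` minus three orthogonal families of square-section beams
#' (section `window` x `window`, length `a`) at offsets t*c with
#' t = window + wall:
#' * S1 (fine): a = 9.5, window = 0.76, wall = 0.38 mm and
#'   z = -0.5 + round(0.5*a/t), so c runs over half-integers
#'   {-3.5, ..., 3.5} and there are 8 beams per family per axis
#'   (8 x 8 windows per face).
#' * S2 (coarse): a = 9.0, window = 1.5, wall = 1.5 mm and
#'   z = floor((a - t)/(2*t)), so c is integer {-1, 0, 1} (3 x 3 windows).
#'
#' For S1 the identity 8*window + 9*wall = a is asserted at construction.
#'
#' @param shape "S1", "S2" or "custom".
#' @param a cube edge (mm); defaulted per shape.
#' @param window lattice spacing / window edge (mm).
#' @param wall lattice wall (mm).
#' @param zRule offset rule for custom shapes: "half" (S1-style, with
#'   correction value b = 0.5) or "integer" (S2-style).
#' @return a [LatticeSpec-class].
#' @export
latticeSpec <- function(shape = c("S1", "S2", "custom"), a = NULL,
                        window = NULL, wall = NULL,
                        zRule = c("half", "integer")) {
  shape <- match.arg(shape)
  if (shape == "S1") {
    if (is.null(a)) a <- 9.5
    if (is.null(window)) window <- 0.76
    if (is.null(wall)) wall <- 0.38
    zRule <- "half"
  } else if (shape == "S2") {
    if (is.null(a)) a <- 9.0
    if (is.null(window)) window <- 1.5
    if (is.null(wall)) wall <- 1.5
    zRule <- "integer"
  } else {
    zRule <- match.arg(zRule)
    stopifnot(!is.null(a), !is.null(window), !is.null(wall))
  }
  t <- window + wall
  z <- if (zRule == "half") -0.5 + round(0.5 * a / t) else
    floor((a - t) / (2 * t))
  if (z < 0) stop("degenerate lattice: z < 0 (cube too small for one beam)")
  offsets <- t * seq(-z, z, by = 1)
  if (shape == "S1" &&
      abs(8 * window + 9 * wall - a) > 1e-9)
    stop("S1 dimensional identity 8*window + 9*wall = a violated")
  new("LatticeSpec", shape = shape, a = a, window = window, wall = wall,
      z = z, offsets = offsets)
}

#' Build the constructive solid for a lattice spec
#'
#' Returns a membership closure evaluating the solid: a point is solid when
#' it lies inside the centered cube and inside none of the subtracted beams.
#' The three beam families run along y (offsets in x, z), x (offsets in
#' y, z) and z (offsets in x, y), exactly as the nested script modules
#' replicate them.
#'
#' @param spec a [LatticeSpec-class].
#' @return list with `spec` and `isSolid(x, y, z)` (vectorized over equal-
#'   length coordinate vectors, mm, cube centered at origin).
#' @export
buildLattice <- function(spec) {
  stopifnot(is(spec, "LatticeSpec"))
  validObject(spec)
  half_w <- spec@window / 2
  offs <- spec@offsets
  # half-open bands [o - w/2, o + w/2) so grid-aligned voxel centers are
  # counted exactly once
  in_band <- function(u) {
    hit <- rep(FALSE, length(u))
    for (o in offs) hit <- hit | (u >= o - half_w & u < o + half_w)
    hit
  }
  a2 <- spec@a / 2
  isSolid <- function(x, y, z) {
    inside <- abs(x) <= a2 & abs(y) <= a2 & abs(z) <= a2
    bx <- in_band(x); by <- in_band(y); bz <- in_band(z)
    beam <- (bx & bz) | (by & bz) | (bx & by)
    inside & !beam
  }
  list(spec = spec, isSolid = isSolid, inBand = in_band)
}

#' Voxelize a lattice solid
#'
#' Uniform grid over the cube bounding box; a voxel is labeled pore (1) when
#' its center lies inside a subtracted beam or outside the cube, solid (0)
#' otherwise.
#'
#' @param solid result of [buildLattice()].
#' @param resolution voxel edge (mm), > 0. A warning is issued above
#'   wall/4, where run-length metrics become unreliable.
#' @return a [VoxelVolume-class] (voxel sizes in mm).
#' @export
voxelize <- function(solid, resolution) {
  if (resolution <= 0) stop("resolution must be > 0")
  spec <- solid$spec
  if (resolution > spec@wall / 4)
    warning("resolution coarser than wall/4: lattice metrics unreliable")
  n <- ceiling(spec@a / resolution)
  centers <- (seq_len(n) - 0.5) * resolution - spec@a / 2
  bx <- solid$inBand(centers)
  inside <- abs(centers) <= spec@a / 2
  # separable construction: beam = (bx&bz)|(by&bz)|(bx&by), identical bands
  # on all three axes
  arr <- array(FALSE, c(n, n, n))
  bxy <- outer(bx, bx, "&")
  # beam membership in slice z = k: (bx_i & bz_k) | (by_j & bz_k) | (bx_i & by_j)
  sl_in_band <- outer(bx, rep(TRUE, n), "&")      # bx_i over columns
  sl_in_band <- sl_in_band | t(sl_in_band) | bxy  # bx_i | by_j, plus bxy
  for (k in seq_len(n)) arr[, , k] <- if (bx[k]) sl_in_band else bxy
  # outside the cube counts as pore
  out <- !inside
  if (any(out)) {
    arr[out, , ] <- TRUE; arr[, out, ] <- TRUE; arr[, , out] <- TRUE
  }
  new("VoxelVolume", data = arr + 0L,
      voxelSize = rep(resolution, 3), origin = rep(-spec@a / 2, 3))
}

#' Measure macrogeometry metrics on a voxelized lattice
#'
#' Windows are counted as 4-connected open regions on a boundary face
#' slice; window edge and wall thickness are modal run lengths along the
#' face line with the most pore voxels (interior and edge wall runs are
#' reported separately, since the coarse script geometry leaves thinner
#' walls at the cube edges). The characteristic diffusion half-thickness is
#' wall_thickness/2.
#'
#' @param vox a [VoxelVolume-class] from [voxelize()].
#' @return list with `windowsPerFace`, `windowEdge` (mm), `wallThickness`
#'   (mm, modal interior run), `edgeWallThickness` (mm), `macroVoidFraction`
#'   (0-1, within the cube bounding box), `surfaceAreaPerVolume` (1/mm) and
#'   `characteristicHalfThickness` (mm).
#' @export
measureLattice <- function(vox) {
  stopifnot(is(vox, "VoxelVolume"))
  arr <- vox@data
  d <- dim(arr)
  if (any(d < 2L)) stop("empty or degenerate grid")
  res <- vox@voxelSize[1]
  face <- arr[1, , ]                     # boundary slice, x- face
  lab <- EBImage::bwlabel(face == 1)
  nwin <- max(lab)
  # line with the most pore voxels across the face
  line_i <- which.max(rowSums(face == 1))
  line <- face[line_i, ]
  r <- rle(line == 1)
  pore_runs <- r$lengths[r$values]
  solid_runs <- r$lengths[!r$values]
  interior_solid <- solid_runs
  edge_solid <- numeric(0)
  if (length(solid_runs)) {
    first_is_solid <- !r$values[1]
    last_is_solid <- !r$values[length(r$values)]
    keep <- rep(TRUE, length(solid_runs))
    if (first_is_solid) { edge_solid <- c(edge_solid, solid_runs[1]); keep[1] <- FALSE }
    if (last_is_solid) { edge_solid <- c(edge_solid, solid_runs[length(solid_runs)]); keep[length(solid_runs)] <- FALSE }
    interior_solid <- solid_runs[keep]
  }
  modal <- function(v) if (length(v)) as.numeric(names(sort(table(v), decreasing = TRUE))[1]) else NA_real_
  window_edge <- modal(pore_runs) * res
  wall_thick <- modal(interior_solid) * res
  edge_wall <- if (length(edge_solid)) modal(edge_solid) * res else NA_real_
  void_frac <- mean(arr == 1)
  # exposed solid faces (6-neighborhood, grid boundary faces count)
  solid <- arr == 0
  exposed <- 0
  exposed <- exposed + sum(solid[1, , ]) + sum(solid[d[1], , ]) +
    sum(solid[, 1, ]) + sum(solid[, d[2], ]) +
    sum(solid[, , 1]) + sum(solid[, , d[3]])
  exposed <- exposed +
    sum(solid[-1, , ] != solid[-d[1], , ]) +
    sum(solid[, -1, ] != solid[, -d[2], ]) +
    sum(solid[, , -1] != solid[, , -d[3]])
  sa <- exposed * res^2
  vol_solid <- sum(solid) * res^3
  list(windowsPerFace = nwin,
       windowEdge = window_edge,
       wallThickness = wall_thick,
       edgeWallThickness = edge_wall,
       macroVoidFraction = void_frac,
       surfaceAreaPerVolume = if (vol_solid > 0) sa / vol_solid else NA_real_,
       characteristicHalfThickness = wall_thick / 2)
}

#' Export a voxel volume's solid phase as binary STL
#'
#' Writes a watertight triangle mesh of all exposed solid-voxel faces (two
#' triangles per face) in standard little-endian binary STL (80-byte header,
#' 50-byte facet records). Triangle winding is outward so the signed mesh
#' volume equals the voxel-counted solid volume.
#'
#' @param vox a [VoxelVolume-class] with at least one solid voxel.
#' @param path output file path.
#' @return invisibly, the number of triangles written.
#' @export
exportStl <- function(vox, path) {
  stopifnot(is(vox, "VoxelVolume"))
  solid <- vox@data == 0
  if (!any(solid)) stop("no solid voxels to export")
  d <- dim(solid)
  vs <- vox@voxelSize
  org <- vox@origin
  tris <- stl_faces(solid, d, vs, org)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(nrow(tris) / 3L), con, size = 4, endian = "little")
  for (f in seq_len(nrow(tris) / 3L)) {
    v <- tris[(3 * f - 2):(3 * f), ]
    nrm <- cross3(v[2, ] - v[1, ], v[3, ] - v[1, ])
    nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
    writeBin(as.numeric(c(nrm, t(v))), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(nrow(tris) / 3L)
}

cross3 <- function(u, v)
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])

# enumerate exposed faces -> matrix of triangle vertices (3 rows per tri)
stl_faces <- function(solid, d, vs, org) {
  verts <- list()
  idx <- which(solid, arr.ind = TRUE)
  get <- function(i, j, k) {
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    out <- rep(FALSE, length(i))
    out[ok] <- solid[cbind(i[ok], j[ok], k[ok])]
    out
  }
  # corner coordinates of voxel (i,j,k): org + (i-1..i)*vs etc.
  add_face <- function(ii, jj, kk, axis, positive) {
    if (!length(ii)) return(NULL)
    x0 <- org[1] + (ii - 1) * vs[1]; x1 <- x0 + vs[1]
    y0 <- org[2] + (jj - 1) * vs[2]; y1 <- y0 + vs[2]
    z0 <- org[3] + (kk - 1) * vs[3]; z1 <- z0 + vs[3]
    n <- length(ii)
    tri <- matrix(0, nrow = 6 * n, ncol = 3)
    for (q in seq_len(n)) {
      c000 <- c(x0[q], y0[q], z0[q]); c100 <- c(x1[q], y0[q], z0[q])
      c010 <- c(x0[q], y1[q], z0[q]); c110 <- c(x1[q], y1[q], z0[q])
      c001 <- c(x0[q], y0[q], z1[q]); c101 <- c(x1[q], y0[q], z1[q])
      c011 <- c(x0[q], y1[q], z1[q]); c111 <- c(x1[q], y1[q], z1[q])
      quad <- switch(axis,
        x = if (positive) rbind(c100, c110, c111, c101)
            else rbind(c000, c001, c011, c010),
        y = if (positive) rbind(c010, c011, c111, c110)
            else rbind(c000, c100, c101, c001),
        z = if (positive) rbind(c001, c101, c111, c011)
            else rbind(c000, c010, c110, c100))
      tri[(6 * q - 5):(6 * q), ] <- rbind(quad[1, ], quad[2, ], quad[3, ],
                                          quad[1, ], quad[3, ], quad[4, ])
    }
    tri
  }
  i <- idx[, 1]; j <- idx[, 2]; k <- idx[, 3]
  out <- list(
    add_face(i[!get(i + 1, j, k)], j[!get(i + 1, j, k)], k[!get(i + 1, j, k)], "x", TRUE),
    add_face(i[!get(i - 1, j, k)], j[!get(i - 1, j, k)], k[!get(i - 1, j, k)], "x", FALSE),
    add_face(i[!get(i, j + 1, k)], j[!get(i, j + 1, k)], k[!get(i, j + 1, k)], "y", TRUE),
    add_face(i[!get(i, j - 1, k)], j[!get(i, j - 1, k)], k[!get(i, j - 1, k)], "y", FALSE),
    add_face(i[!get(i, j, k + 1)], j[!get(i, j, k + 1)], k[!get(i, j, k + 1)], "z", TRUE),
    add_face(i[!get(i, j, k - 1)], j[!get(i, j, k - 1)], k[!get(i, j, k - 1)], "z", FALSE))
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Read a binary STL file
#'
#' Minimal reader for the 80-byte-header/50-byte-facet binary layout; used
#' for round-trip verification of [exportStl()] output.
#'
#' @param path STL file path.
#' @return list with `nTriangles` and `vertices` (3 rows per triangle) and
#'   `volume` (signed mesh volume via the divergence theorem).
#' @export
readStl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  verts <- matrix(0, nrow = 3 * nt, ncol = 3)
  vol <- 0
  for (f in seq_len(nt)) {
    vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "raw", n = 2)
    v <- matrix(vals[4:12], nrow = 3, byrow = TRUE)
    verts[(3 * f - 2):(3 * f), ] <- v
    vol <- vol + sum(v[1, ] * cross3(v[2, ], v[3, ])) / 6
  }
  list(nTriangles = nt, vertices = verts, volume = vol)
}
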