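#' Density map container
#'
#' A `dr_map` is a real 3D grid with orthogonal axes: `grid[i, j, k]` is the
#' density at Cartesian position `origin + (i-1, j-1, k-1) * voxel`.
#' Only orthorhombic cells (all angles 90 degrees) are supported.
#'
#' @param grid 3D numeric array (all dims >= 2).
#' @param voxel voxel size in Angstrom, length 1 or 3.
#' @param origin Cartesian position of grid index (1,1,1), Angstrom.
#' @param resolution_hint optional nominal resolution, Angstrom.
#' @return An object of class `dr_map`.
#' @export
map_new <- function(grid, voxel = 1, origin = c(0, 0, 0), resolution_hint = NULL) {
  stopifnot(length(dim(grid)) == 3L, all(dim(grid) >= 2L))
  voxel <- rep(as.numeric(voxel), length.out = 3L)
  if (any(voxel <= 0)) stop("voxel sizes must be positive")
  if (!all(is.finite(grid))) stop("map values must be finite")
  structure(list(grid = grid, voxel = voxel, origin = as.numeric(origin),
                 resolution_hint = resolution_hint), class = "dr_map")
}

#' @export
print.dr_map <- function(x, ...) {
  cat(sprintf("<dr_map> %d x %d x %d grid, voxel (%.3f, %.3f, %.3f) A, origin (%.2f, %.2f, %.2f) A\n",
              dim(x$grid)[1], dim(x$grid)[2], dim(x$grid)[3],
              x$voxel[1], x$voxel[2], x$voxel[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Read an MRC/CCP4 density map
#'
#' Axis order is normalized to (x, y, z) regardless of the MAPC/MAPR/MAPS
#' permutation in the header. The origin is taken from the ORIGIN header
#' record when any component is nonzero, otherwise from NXSTART/NYSTART/
#' NZSTART times the voxel size (both conventions occur in EMDB-derived
#' files). Non-orthogonal cells are rejected.
#'
#' @param path MRC/CCP4 file path.
#' @return A `dr_map`.
#' @export
load_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  nxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!mode %in% c(0, 1, 2))
    stop("unsupported MRC mode ", mode, " in ", path)
  nstart <- readBin(con, "integer", 3, size = 4, endian = "little")
  mxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  angles <- readBin(con, "numeric", 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")   # dmin dmax dmean
  readBin(con, "integer", 1, size = 4, endian = "little")   # ispg
  nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 25, size = 4, endian = "little")  # extra
  hdr_origin <- readBin(con, "numeric", 3, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  n <- prod(nxyz)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"))
  if (length(vals) != n) stop("truncated MRC data block in ", path)
  if (any(abs(angles - 90) > 1e-3))
    stop("unsupported cell: non-orthogonal angles (",
         paste(sprintf("%.2f", angles), collapse = ", "), ") in ", path)
  raw <- array(vals, dim = nxyz)
  if (any(mapcrs < 1) || any(mapcrs > 3) || anyDuplicated(mapcrs))
    stop("invalid MAPC/MAPR/MAPS axis codes in ", path)
  perm <- order(mapcrs)           # file axis order -> (x, y, z)
  grid <- aperm(raw, perm)
  voxel <- cella / mxyz           # A per grid step along each cell axis
  nstart_xyz <- nstart[perm]
  origin <- if (any(hdr_origin != 0)) hdr_origin else nstart_xyz * voxel
  map_new(grid, voxel = voxel, origin = origin)
}

#' Write a density map as MRC/CCP4 mode 2
#'
#' Values are stored as 32-bit floats in (x fastest) axis order; the origin
#' is written to the ORIGIN header record (the convention applied on read).
#'
#' @param map A `dr_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_map <- function(map, path) {
  stopifnot(inherits(map, "dr_map"))
  d <- dim(map$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d); wi(2); wi(c(0, 0, 0)); wi(d)
  wf(d * map$voxel); wf(c(90, 90, 90))
  wi(c(1, 2, 3))
  g <- map$grid
  wf(c(min(g), max(g), mean(g)))
  wi(1); wi(0)                       # ISPG volume, NSYMBT 0
  wi(rep(0, 25))
  wf(map$origin)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)
  wf(stats::sd(as.numeric(g)))
  wi(0)                              # NLABL
  writeBin(raw(800), con)            # label block
  wf(as.numeric(g))
  invisible(path)
}

# Cartesian coordinates of every voxel along one axis
map_axis_coords <- function(map, axis)
  map$origin[axis] + (seq_len(dim(map$grid)[axis]) - 1) * map$voxel[axis]

# fractional (1-based, continuous) grid index of Cartesian points
map_frac_index <- function(map, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, 1, 3)
  cbind((xyz[, 1] - map$origin[1]) / map$voxel[1] + 1,
        (xyz[, 2] - map$origin[2]) / map$voxel[2] + 1,
        (xyz[, 3] - map$origin[3]) / map$voxel[3] + 1)
}

# Cartesian coordinates of integer grid indices (n x 3)
map_index_coords <- function(map, ijk) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, 1, 3)
  cbind(map$origin[1] + (ijk[, 1] - 1) * map$voxel[1],
        map$origin[2] + (ijk[, 2] - 1) * map$voxel[2],
        map$origin[3] + (ijk[, 3] - 1) * map$voxel[3])
}
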