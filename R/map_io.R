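#' Density map
#'
#' A 3D scalar grid with cubic voxels. World coordinates of grid point
#' `(i, j, k)` (1-based) are `origin + (c(i, j, k) - 1) * voxel_size`, with
#' the first array index the fastest (x) axis as in the MRC convention.
#'
#' @param grid 3D numeric array (each dimension >= 2).
#' @param voxel_size voxel edge in Angstrom (> 0).
#' @param origin world coordinate of the first grid point, Angstrom.
#' @return An object of class `density_map`.
#' @export
density_map <- function(grid, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(is.array(grid), length(dim(grid)) == 3)
  if (any(dim(grid) < 2)) stop("grid dimensions must be >= 2 in each axis")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<density_map> %d x %d x %d voxels @ %.3f A, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_size, min(x$grid), max(x$grid)))
  invisible(x)
}

# world coordinates of all grid points along each axis
map_axes <- function(map) {
  lapply(1:3, function(k) {
    map$origin[k] + (seq_len(dim(map$grid)[k]) - 1) * map$voxel_size
  })
}

#' Read an MRC2014 density map
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32) with the standard
#' column axis order (MAPC,MAPR,MAPS = 1,2,3) and cubic voxels. The origin is
#' taken from the ORIGIN header words plus any NXSTART offset.
#'
#' @param path file path.
#' @return A [density_map()].
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 1024)
  parse_hdr <- function(endian) {
    list(
      nxyz = readBin(hdr_raw[1:12], "integer", 3, 4, endian = endian),
      mode = readBin(hdr_raw[13:16], "integer", 1, 4, endian = endian),
      nstart = readBin(hdr_raw[17:28], "integer", 3, 4, endian = endian),
      mxyz = readBin(hdr_raw[29:40], "integer", 3, 4, endian = endian),
      cella = readBin(hdr_raw[41:52], "double", 3, 4, endian = endian),
      mapcrs = readBin(hdr_raw[65:76], "integer", 3, 4, endian = endian),
      nsymbt = readBin(hdr_raw[93:96], "integer", 1, 4, endian = endian),
      origin = readBin(hdr_raw[197:208], "double", 3, 4, endian = endian)
    )
  }
  h <- parse_hdr("little")
  endian <- "little"
  if (any(h$nxyz <= 0) || any(h$nxyz > 100000)) {
    h <- parse_hdr("big")
    endian <- "big"
    if (any(h$nxyz <= 0) || any(h$nxyz > 100000)) stop("not a readable MRC file")
  }
  if (!h$mode %in% c(0L, 1L, 2L)) {
    stop(sprintf("unsupported MRC mode %d (modes 0, 1, 2 supported)", h$mode))
  }
  if (!identical(h$mapcrs, c(1L, 2L, 3L))) {
    stop("unsupported MRC axis order (MAPC,MAPR,MAPS must be 1,2,3)")
  }
  vx <- h$cella / h$mxyz
  if (max(vx) - min(vx) > 1e-4 * max(vx)) {
    stop("anisotropic voxels are unsupported (cell/grid ratios differ)")
  }
  if (h$nsymbt > 0) readBin(con, "raw", h$nsymbt)
  nvox <- prod(h$nxyz)
  vals <- switch(as.character(h$mode),
    "0" = as.numeric(readBin(con, "integer", nvox, 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", nvox, 2, signed = TRUE,
                             endian = endian)),
    "2" = readBin(con, "double", nvox, 4, endian = endian))
  if (length(vals) < nvox) stop("truncated MRC data section")
  origin <- h$origin + h$nstart * vx[1]
  density_map(array(vals, dim = h$nxyz), vx[1], origin)
}

#' Write a density map as MRC2014 (mode 2, float32)
#'
#' Values are stored as 32-bit floats (the MRC mode 2 representation), so a
#' write/read cycle is exact at float32 precision and is a fixed point: a
#' second round-trip reproduces the first bit-identically.
#'
#' @param map a [density_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- dim(map$grid)
  wi <- function(x) writeBin(as.integer(x), con, 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, 4, endian = "little")
  wi(n)                        # NX NY NZ
  wi(2L)                       # MODE 2 = float32
  wi(c(0L, 0L, 0L))            # NXSTART..
  wi(n)                        # MX MY MZ
  wf(n * map$voxel_size)       # CELLA
  wf(c(90, 90, 90))            # CELLB
  wi(c(1L, 2L, 3L))            # MAPC MAPR MAPS
  wf(c(min(map$grid), max(map$grid), mean(map$grid)))  # DMIN DMAX DMEAN
  wi(1L)                       # ISPG
  wi(0L)                       # NSYMBT
  writeBin(raw(12), con)       # EXTRA (words 25-26) + EXTTYP (word 27)
  wi(20140L)                   # NVERSION (MRC2014, word 28)
  writeBin(raw(84), con)       # EXTRA (words 29-49)
  wf(map$origin)               # ORIGIN
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(map$grid))      # RMS
  wi(0L)                       # NLABL
  writeBin(raw(800), con)      # labels
  writeBin(as.numeric(map$grid), con, 4, endian = "little")
  invisible(path)
}
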