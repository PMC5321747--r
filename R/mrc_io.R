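# MRC/CCP4 volume input and output.
#
# Implements the MRC2014 subset used by EMDB depositions: mode 2 (32-bit
# float) volumes, little-endian, with the voxel size taken as cell length /
# grid sampling and the MRC2014 origin record.  Data are stored x fastest,
# z slowest, which maps directly onto an R array dim = c(nx, ny, nz).
# Gzipped files are read transparently.

MRC_HEADER_BYTES <- 1024L

#' Read an MRC/CCP4 density map
#'
#' Reads a 32-bit float (mode 2) MRC/CCP4 volume, the format used by EMDB
#' depositions.  The voxel size is derived from the header as cell length
#' divided by grid sampling; the MRC2014 origin fields populate the map
#' origin.  Gzipped files (`.mrc.gz`, `.map.gz`) are handled transparently.
#'
#' @param path file path.
#' @return a [density_map()].
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)

  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  if (length(ints) < 10) stop("MRC format error: truncated header")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  mx <- ints[8]; my <- ints[9]; mz <- ints[10]
  if (any(c(nx, ny, nz) <= 0) || any(c(nx, ny, nz) > 100000L))
    stop("MRC format error: implausible grid dimensions (nx/ny/nz)")
  if (mode != 2L)
    stop("MRC format error: unsupported mode ", mode,
         " (only mode 2, 32-bit float, is supported)")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")     # cellb
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("MRC format error: non-standard axis order (mapc/mapr/maps = ",
         paste(mapcrs, collapse = ","), "); only 1,2,3 is supported")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")     # dmin/max/mean
  readBin(con, "integer", n = 1, size = 4, endian = "little")     # ispg
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  readBin(con, "integer", n = 25, size = 4, endian = "little")    # extra
  origin <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "integer", n = 3, size = 4, endian = "little")     # MAP/machst/rms
  readBin(con, "integer", n = 1, size = 4, endian = "little")     # nlabl
  lab <- readBin(con, "raw", n = 800)
  if (length(lab) < 800) stop("MRC format error: truncated header labels")
  if (!is.na(nsymbt) && nsymbt > 0)
    readBin(con, "raw", n = nsymbt)

  nvox <- as.double(nx) * ny * nz
  vals <- readBin(con, "numeric", n = nvox, size = 4, endian = "little")
  if (length(vals) < nvox)
    stop("MRC format error: truncated data section (expected ", nvox,
         " voxels, got ", length(vals), ")")
  if (any(!is.finite(vals)))
    stop("MRC format error: non-finite voxel values in data section")

  vs <- if (!is.na(mx) && mx > 0 && is.finite(cella[1]) && cella[1] > 0)
    cella[1] / mx else 1
  label <- rawToChar(lab[lab != as.raw(0)])
  density_map(array(vals, dim = c(nx, ny, nz)), voxel_size = vs,
              origin = origin, label = trimws(substr(label, 1, 80)))
}

#' Write a density map as MRC
#'
#' Writes a mode 2 (32-bit float) MRC2014 volume, little-endian.  Values
#' are truncated to float32 precision on disk; a write/read cycle is exact
#' at that precision.
#'
#' @param m a [density_map()] or [volume_mask()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(m, path) {
  vals <- map_values(m)
  vs <- if (inherits(m, "density_map") || inherits(m, "volume_mask"))
    m$voxel_size else 1
  org <- if (inherits(m, "density_map")) m$origin else c(0, 0, 0)
  d <- dim(vals)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # nx ny nz
  wi(2L)                     # mode 2: float32
  wi(c(0L, 0L, 0L))          # nxstart
  wi(d)                      # mx my mz
  wf(d * vs)                 # cella
  wf(c(90, 90, 90))          # cellb
  wi(c(1L, 2L, 3L))          # mapc mapr maps
  wf(c(min(vals), max(vals), mean(vals)))
  wi(1L)                     # ispg: volume
  wi(0L)                     # nsymbt
  wi(integer(25))            # extra
  wf(org)                    # MRC2014 origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # machst: little endian
  wf(stats::sd(vals))        # rms
  wi(1L)                     # nlabl
  lab <- charToRaw(formatC("tomowedge", width = -80))
  writeBin(c(lab, raw(800 - length(lab))), con)
  writeBin(as.numeric(vals), con, size = 4, endian = "little")
  invisible(path)
}
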