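# MRC2014 (MRCS multi-section, mode-2 float32) writer and reader, built
# directly on writeBin/readBin. Only the fields a particle stack needs are
# populated; the 1024-byte header follows the MRC2014 word layout.

#' Write an image stack as an MRCS file (MRC2014, mode 2)
#'
#' Sections are written in particle order with the x (column) axis fastest,
#' little-endian float32. Header carries nx = ny = image size, nz = number
#' of particles, mode = 2, cell dimensions from `pixel_size`, and the
#' min/max/mean/rms statistics of the (float32-quantized) data.
#'
#' @param images `D x D x n` array.
#' @param path output path.
#' @param pixel_size physical pixel size in Angstrom (header cell field).
#' @return `path`, invisibly.
#' @export
write_mrcs <- function(images, path, pixel_size = 1.0) {
  stopifnot(is.array(images), length(dim(images)) == 3)
  d <- dim(images)
  nx <- d[2]
  ny <- d[1]
  nz <- d[3]
  # x fastest within each section
  dat <- as.numeric(vapply(
    seq_len(nz), function(i) as.vector(t(images[, , i])), numeric(nx * ny)
  ))
  # statistics on the float32 values actually stored
  dat32 <- readBin(writeBin(dat, raw(), size = 4, endian = "little"),
    numeric(), n = length(dat), size = 4, endian = "little"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(nx, ny, nz)) # 1-3 dimensions
  wi(2L) # 4 mode 2 = float32
  wi(c(0L, 0L, 0L)) # 5-7 nstart
  wi(c(nx, ny, nz)) # 8-10 sampling grid
  wf(pixel_size * c(nx, ny, nz)) # 11-13 cell dimensions (A)
  wf(c(90, 90, 90)) # 14-16 cell angles
  wi(c(1L, 2L, 3L)) # 17-19 axis correspondence
  wf(c(min(dat32), max(dat32), mean(dat32))) # 20-22
  wi(0L) # 23 ispg: image stack
  wi(0L) # 24 nsymbt
  wi(rep(0L, 25)) # 25-49 extra
  wf(c(0, 0, 0)) # 50-52 origin
  writeBin(charToRaw("MAP "), con) # 53 format id
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # 54 machine stamp (LE)
  wf(stats::sd(dat32)) # 55 rms
  wi(0L) # 56 nlabl
  writeBin(raw(800), con) # labels
  writeBin(dat, con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRCS image stack
#'
#' @param path MRCS/MRC file (mode 2, as written by [write_mrcs()]).
#' @return list with `images` (`D x D x n` array), `pixel_size`, and the
#'   parsed `header` fields.
#' @export
read_mrcs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, integer(), n = n, size = 4, endian = "little")
  rf <- function(n) readBin(con, numeric(), n = n, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  if (mode != 2L) stop("unsupported MRC mode ", mode, " (only mode 2 float32)")
  ri(3) # nstart
  grid <- ri(3)
  cell <- rf(3)
  rf(3) # angles
  ri(3) # axes
  stats3 <- rf(3)
  ri(2) # ispg, nsymbt
  ri(25) # extra
  rf(3) # origin
  map_id <- rawToChar(readBin(con, raw(), 4))
  readBin(con, raw(), 4) # machine stamp
  rms <- rf(1)
  ri(1) # nlabl
  readBin(con, raw(), 800)
  nx <- dims[1]
  ny <- dims[2]
  nz <- dims[3]
  if (map_id != "MAP ") warning("missing 'MAP ' id; not a canonical MRC2014 file")
  npix <- as.double(nx) * ny * nz
  dat <- readBin(con, numeric(), n = npix, size = 4, endian = "little")
  if (length(dat) < npix) {
    stop(
      "truncated MRCS: header promises ", nz, " sections (",
      npix, " pixels) but only ", length(dat), " pixels are present"
    )
  }
  images <- array(0, dim = c(ny, nx, nz))
  per <- nx * ny
  for (i in seq_len(nz)) {
    images[, , i] <- t(matrix(dat[((i - 1) * per + 1):(i * per)], nx, ny))
  }
  list(
    images = images,
    pixel_size = if (grid[1] > 0) cell[1] / grid[1] else 1,
    header = list(
      nx = nx, ny = ny, nz = nz, mode = mode,
      dmin = stats3[1], dmax = stats3[2], dmean = stats3[3], rms = rms
    )
  )
}
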