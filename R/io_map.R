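#' CCP4/MRC map input and output
#'
#' Mode-2 (32-bit float) CCP4/MRC files with axis order X, Y, Z and the
#' unit cell and sampling recorded in the header. Enough of the format
#' for exchange with standard viewers; symmetry records are not
#' written.
#'
#' @param map A `map_grid`.
#' @param path File path.
#' @return `read_ccp4()` returns a `map_grid`; `write_ccp4()` returns
#'   `path` invisibly.
#' @export
write_ccp4 <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  dims <- as.integer(map$dims)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dims)                      # NC NR NS
  wi(2L)                        # MODE 2 = float32
  wi(c(0L, 0L, 0L))             # start
  wi(dims)                      # intervals
  wf(c(map$cell$a, map$cell$b, map$cell$c,
       map$cell$alpha, map$cell$beta, map$cell$gamma))
  wi(c(1L, 2L, 3L))             # MAPC MAPR MAPS
  wf(c(min(map$values), max(map$values), map$mean))
  wi(1L)                        # ISPG (P1)
  wi(0L)                        # NSYMBT
  wi(rep(0L, 25))               # extra
  wf(c(0, 0, 0))                # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wf(map$sigma)                 # RMS
  wi(0L)                        # NLABL
  writeBin(raw(800), con)       # labels
  wf(as.vector(map$values))
  invisible(path)
}

#' @rdname write_ccp4
#' @export
read_ccp4 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  if (mode != 2L) stop("only mode-2 (float32) CCP4 maps are supported")
  ri(3)        # start
  ri(3)        # intervals
  cellp <- rf(6)
  ri(3)        # axis order
  rf(3)        # min max mean
  ri(2)        # ispg nsymbt
  ri(25); rf(3)
  readChar(con, 4, useBytes = TRUE)
  readBin(con, "raw", 4)
  rf(1)
  ri(1)
  readBin(con, "raw", 800)
  vals <- rf(prod(dims))
  cell <- unit_cell(cellp[1], cellp[2], cellp[3], cellp[4], cellp[5], cellp[6])
  new_map_grid(array(vals, dims), cell, d_min = NA_real_)
}
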