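#' Read a multi-channel 3D image stack from TIFF
#'
#' Reads either one multi-page TIFF holding all channels (pages ordered
#' channel-major: all z-slices of channel 1, then all z-slices of channel 2,
#' ...) or one single-channel multi-page TIFF per channel (pass a character
#' vector of paths, one per channel, in channel order). Intensities are
#' preserved bit-exactly (16-bit container).
#'
#' @param path path to a multi-page TIFF, or a character vector of per-channel
#'   TIFF paths.
#' @param channelMap named integer vector mapping channel names to channel
#'   indices, e.g. \code{c(DAPI = 1, MeC = 2)}. Must cover \code{"DAPI"} and
#'   \code{"MeC"}.
#' @param voxelSize physical voxel edge lengths in nm, \code{c(x, y, z)}.
#'   When \code{NULL} the acquisition default \code{c(120, 120, 250)} is used
#'   with a warning.
#' @param bitDepth dynamic range in bits (default 12).
#' @return An \linkS4class{ImageStack}.
#' @seealso [writeStack()]
#' @export
readStack <- function(path, channelMap = c(DAPI = 1, MeC = 2),
                      voxelSize = NULL, bitDepth = 12L) {
  if (!all(c("DAPI", "MeC") %in% names(channelMap)))
    stop("channelMap must cover channels 'DAPI' and 'MeC'")
  nCh <- max(channelMap)

  readPages <- function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    pages <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    shapes <- vapply(pages, function(m) dim(m)[1:2], integer(2))
    if (any(shapes[1L, ] != shapes[1L, 1L]) ||
        any(shapes[2L, ] != shapes[2L, 1L]))
      stop("format error: non-uniform slice shapes in ", p)
    pages
  }

  if (length(path) > 1L) {
    if (length(path) != nCh)
      stop("expected ", nCh, " per-channel files, got ", length(path))
    byCh <- lapply(path, readPages)
    nz <- length(byCh[[1L]])
    if (any(vapply(byCh, length, 1L) != nz))
      stop("format error: channels differ in slice count")
    pages <- do.call(c, byCh)
  } else {
    pages <- readPages(path)
    if (length(pages) %% nCh != 0L)
      stop("page count ", length(pages),
           " is not a multiple of the channel count ", nCh)
    nz <- length(pages) %/% nCh
  }

  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  data <- array(0L, dim = c(nCh, nz, ny, nx))
  for (c in seq_len(nCh))
    for (z in seq_len(nz))
      data[c, z, , ] <- pages[[(c - 1L) * nz + z]]

  chn <- character(nCh)
  chn[channelMap] <- names(channelMap)
  chn[chn == ""] <- paste0("ch", which(chn == ""))
  ImageStack(data, voxelSize = voxelSize, channelNames = chn,
             bitDepth = bitDepth)
}

#' Write an ImageStack to a multi-page TIFF
#'
#' Pages are written channel-major (all z of channel 1, then channel 2, ...)
#' in a 16-bit container; integer intensities round-trip bit-exactly through
#' [readStack()].
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  d <- imgData(stack)
  dm <- dim(d)
  pages <- vector("list", dm[1L] * dm[2L])
  k <- 1L
  for (c in seq_len(dm[1L]))
    for (z in seq_len(dm[2L])) {
      pages[[k]] <- matrix(d[c, z, , ], nrow = dm[3L]) / 65535
      k <- k + 1L
    }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a 3D label volume as an integer multi-page TIFF
#'
#' @param labels integer \code{(z, y, x)} array of nucleus labels
#'   (0 = background).
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeLabelVolume <- function(labels, path) {
  dm <- dim(labels)
  pages <- lapply(seq_len(dm[1L]), function(z)
    matrix(labels[z, , ], nrow = dm[2L]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read back a label volume written by [writeLabelVolume()]
#'
#' @param path TIFF path.
#' @return integer \code{(z, y, x)} array.
#' @export
readLabelVolume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, dim = c(length(pages), nrow(pages[[1L]]),
                           ncol(pages[[1L]])))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  arr
}

#' Write the per-nucleus feature table as CSV
#'
#' One row per nucleus; floats carry full precision (>= 6 significant
#' digits), so a write/read round trip reproduces values to 1e-6.
#'
#' @param records a data.frame of per-nucleus features and metadata (or an
#'   empty data.frame with the schema columns for a header-only file).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeCellTable <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(format(records, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a per-nucleus feature table written by [writeCellTable()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readCellTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
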