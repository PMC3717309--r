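#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib qdmi3d, .registration = TRUE
NULL

#' ImageStack: a multi-channel 3D intensity volume with physical metadata
#'
#' Container for one confocal field of view. Intensities are stored as a 4D
#' integer-valued array in \code{(channel, z, y, x)} order; the physical
#' voxel pitch is carried in nanometres and propagates to every downstream
#' record. Channels are named; \code{"DAPI"} (gDNA counterstain) and
#' \code{"MeC"} (anti-5-methylcytosine immunofluorescence) are mandatory for
#' the analysis functions, a third channel (e.g. \code{"Ki67"}) is carried
#' through untouched as a qualitative annotation.
#'
#' All array coordinates in this package are 1-based and bounding boxes are
#' closed intervals, following base R and Bioconductor (IRanges) convention.
#'
#' @slot data 4D array, \code{dim = c(channel, z, y, x)}; integer-valued,
#'   non-negative, at most \code{2^bitDepth - 1}.
#' @slot voxelSize named numeric of physical edge lengths in nm,
#'   \code{c(x=, y=, z=)}; strictly positive. The acquisition default is
#'   \code{c(120, 120, 250)}.
#' @slot channelNames character, one per channel.
#' @slot bitDepth integer scalar; dynamic range is \code{2^bitDepth - 1}
#'   (12 by default, max intensity 4095).
#' @export
setClass("ImageStack",
  representation(
    data = "array",
    voxelSize = "numeric",
    channelNames = "character",
    bitDepth = "integer"
  ),
  prototype(
    voxelSize = c(x = 120, y = 120, z = 250),
    bitDepth = 12L
  )
)

setValidity("ImageStack", function(object) {
  d <- object@data
  if (length(dim(d)) != 4L)
    return("data must be a 4D (channel, z, y, x) array")
  if (length(object@channelNames) != dim(d)[1L])
    return("channelNames length must equal the number of channels")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 strictly positive nm values (x, y, z)")
  if (anyNA(d))
    return("intensities must not contain NA")
  rng <- range(d)
  if (rng[1L] < 0 || rng[2L] > 2^object@bitDepth - 1)
    return(sprintf("intensities must lie in [0, %d]", 2^object@bitDepth - 1))
  TRUE
})

#' Construct an ImageStack
#'
#' @param data 4D array in \code{(channel, z, y, x)} order.
#' @param voxelSize physical voxel edge lengths in nm as \code{c(x, y, z)}.
#'   Defaults to the acquisition constants \code{c(120, 120, 250)} with a
#'   warning when left unspecified.
#' @param channelNames character vector naming the channels.
#' @param bitDepth dynamic range in bits per pixel (default 12).
#' @return An \linkS4class{ImageStack}.
#' @examples
#' a <- array(0L, c(2, 4, 8, 8))
#' s <- ImageStack(a, voxelSize = c(120, 120, 250),
#'                 channelNames = c("DAPI", "MeC"))
#' dim(imgData(s))
#' @export
ImageStack <- function(data, voxelSize = NULL,
                       channelNames = c("DAPI", "MeC"),
                       bitDepth = 12L) {
  if (is.null(voxelSize)) {
    warning("no voxel size supplied; assuming 120 x 120 x 250 nm")
    voxelSize <- c(x = 120, y = 120, z = 250)
  }
  voxelSize <- as.numeric(voxelSize)
  names(voxelSize) <- c("x", "y", "z")
  new("ImageStack", data = data, voxelSize = voxelSize,
      channelNames = channelNames, bitDepth = as.integer(bitDepth))
}

#' NucleusROI: one segmented nucleus
#'
#' @slot label positive integer label, unique within a stack.
#' @slot pixels integer vector of 1-based linear indices into the 3D
#'   \code{(z, y, x)} volume of one channel.
#' @slot volumePx pixel count (\code{length(pixels)}).
#' @slot centroid numeric \code{(z, y, x)} centroid in pixel coordinates.
#' @slot bbox 2 x 3 matrix, rows \code{min}/\code{max}, columns
#'   \code{(z, y, x)}; closed interval.
#' @slot borderTouching does the ROI touch any face of the stack?
#' @export
setClass("NucleusROI",
  representation(
    label = "integer",
    pixels = "integer",
    volumePx = "integer",
    centroid = "numeric",
    bbox = "matrix",
    borderTouching = "logical"
  )
)

setValidity("NucleusROI", function(object) {
  if (object@volumePx != length(object@pixels))
    return("volumePx must equal the number of pixels")
  if (object@volumePx < 1L)
    return("an ROI must contain at least one pixel")
  bb <- object@bbox
  cz <- object@centroid
  if (any(cz < bb[1L, ] - 1e-9) || any(cz > bb[2L, ] + 1e-9))
    return("centroid must lie inside the bounding box")
  TRUE
})

#' Codistribution: the MeC/DAPI joint intensity histogram of one nucleus
#'
#' A normalised 2D probability table over (DAPI bin, MeC bin), built on
#' population-level bin edges shared by all nuclei of a stack, with an
#' optional Kullback-Leibler divergence score against the population
#' reference (in bits; \code{NA} until scored).
#'
#' @slot hist numeric matrix (DAPI bins x MeC bins), entries >= 0 summing
#'   to 1.
#' @slot binEdges list with numeric elements \code{dapi} and \code{mec}.
#' @slot kld K-L divergence vs the population reference (bits), or NA.
#' @export
setClass("Codistribution",
  representation(
    hist = "matrix",
    binEdges = "list",
    kld = "numeric"
  ),
  prototype(kld = NA_real_)
)

setValidity("Codistribution", function(object) {
  h <- object@hist
  if (any(h < 0))
    return("histogram entries must be non-negative")
  if (abs(sum(h) - 1) > 1e-9)
    return("histogram must sum to 1")
  if (!all(c("dapi", "mec") %in% names(object@binEdges)))
    return("binEdges must contain 'dapi' and 'mec'")
  if (length(object@binEdges$dapi) != nrow(h) + 1L ||
      length(object@binEdges$mec) != ncol(h) + 1L)
    return("binEdges must match the histogram dimensions")
  if (!is.na(object@kld) && object@kld < -1e-12)
    return("kld must be non-negative when set")
  TRUE
})
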