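#' @rdname ImageStack-accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname ImageStack-accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname ImageStack-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname ImageStack-accessors
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))

#' Accessors for ImageStack
#'
#' \code{imgData} returns the raw 4D array, \code{voxelSize} the physical
#' pitch in nm (\code{c(x, y, z)}), \code{channelNames} the channel labels,
#' and \code{getChannel} one channel as a 3D \code{(z, y, x)} array.
#'
#' @param x an \linkS4class{ImageStack}.
#' @param channel channel name (e.g. \code{"DAPI"}) or index.
#' @return See description.
#' @name ImageStack-accessors
#' @aliases imgData voxelSize channelNames getChannel
NULL

#' @rdname ImageStack-accessors
setMethod("imgData", "ImageStack", function(x) x@data)

#' @rdname ImageStack-accessors
setMethod("voxelSize", "ImageStack", function(x) x@voxelSize)

#' @rdname ImageStack-accessors
setMethod("channelNames", "ImageStack", function(x) x@channelNames)

#' @rdname ImageStack-accessors
setMethod("getChannel", "ImageStack", function(x, channel) {
  if (is.character(channel)) {
    idx <- match(channel, x@channelNames)
    if (is.na(idx))
      stop("channel '", channel, "' not present (have: ",
           paste(x@channelNames, collapse = ", "), ")")
  } else idx <- as.integer(channel)
  d <- x@data
  ch <- d[idx, , , , drop = FALSE]
  dim(ch) <- dim(d)[-1L]
  ch
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat("ImageStack:", paste(d, collapse = " x "),
      "(channel, z, y, x)\n")
  cat("  channels :", paste(object@channelNames, collapse = ", "), "\n")
  cat("  voxel    :", paste(object@voxelSize, collapse = " x "), "nm (x,y,z)\n")
  cat("  bit depth:", object@bitDepth, "bits (max",
      2^object@bitDepth - 1, ")\n")
})

setMethod("show", "NucleusROI", function(object) {
  cat(sprintf("NucleusROI #%d: %d px, centroid (z,y,x) = (%.1f, %.1f, %.1f)%s\n",
              object@label, object@volumePx, object@centroid[1L],
              object@centroid[2L], object@centroid[3L],
              if (object@borderTouching) " [border]" else ""))
})

setMethod("show", "Codistribution", function(object) {
  cat(sprintf("Codistribution: %d x %d bins (DAPI x MeC), kld = %s bits\n",
              nrow(object@hist), ncol(object@hist),
              ifelse(is.na(object@kld), "unscored",
                     format(object@kld, digits = 4))))
})

#' @rdname NucleusROI-accessors
#' @export
setGeneric("roiLabel", function(x) standardGeneric("roiLabel"))

#' @rdname NucleusROI-accessors
#' @export
setGeneric("roiVolume", function(x) standardGeneric("roiVolume"))

#' @rdname NucleusROI-accessors
#' @export
setGeneric("roiPixels", function(x) standardGeneric("roiPixels"))

#' @rdname NucleusROI-accessors
#' @export
setGeneric("roiCentroid", function(x) standardGeneric("roiCentroid"))

#' Accessors for NucleusROI
#'
#' @param x a \linkS4class{NucleusROI}.
#' @return label, pixel count, linear pixel indices, or centroid.
#' @name NucleusROI-accessors
NULL

#' @rdname NucleusROI-accessors
setMethod("roiLabel", "NucleusROI", function(x) x@label)
#' @rdname NucleusROI-accessors
setMethod("roiVolume", "NucleusROI", function(x) x@volumePx)
#' @rdname NucleusROI-accessors
setMethod("roiPixels", "NucleusROI", function(x) x@pixels)
#' @rdname NucleusROI-accessors
setMethod("roiCentroid", "NucleusROI", function(x) x@centroid)

#' @rdname Codistribution-accessors
#' @export
setGeneric("codHist", function(x) standardGeneric("codHist"))

#' @rdname Codistribution-accessors
#' @export
setGeneric("codKLD", function(x) standardGeneric("codKLD"))

#' Accessors for Codistribution
#'
#' @param x a \linkS4class{Codistribution}.
#' @return \code{codHist}: the normalised joint histogram matrix;
#'   \code{codKLD}: the K-L divergence score (bits) or NA if unscored.
#' @name Codistribution-accessors
NULL

#' @rdname Codistribution-accessors
setMethod("codHist", "Codistribution", function(x) x@hist)
#' @rdname Codistribution-accessors
setMethod("codKLD", "Codistribution", function(x) x@kld)
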