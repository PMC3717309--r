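#' Image-inherent global threshold of the DAPI channel
#'
#' Binarises foreground (nuclei) from background using a threshold derived
#' from the image itself. \code{"otsu"} is the canonical parameter-free
#' histogram split. \code{"envelope"} refines it for volume fidelity:
#' Otsu first separates the two classes, then the threshold is placed at
#' the midpoint between the background mean and the lower-quartile nuclear
#' intensity -- the crossing point of the blur-smeared nuclear envelope.
#' A plain Otsu cut sits well above that midpoint when background
#' dominates the field, which systematically erodes measured nuclear
#' volumes by ~10-15% at confocal-like blur; the envelope method removes
#' that bias. Both are deterministic.
#'
#' @param vol 3D \code{(z, y, x)} intensity array (typically the DAPI
#'   channel of an \linkS4class{ImageStack}).
#' @param method \code{"otsu"} or \code{"envelope"}.
#' @param maxLevel top of the intensity scale (4095 for 12-bit data).
#' @return Scalar threshold, strictly between \code{min(vol)} and
#'   \code{max(vol)}; foreground is \code{vol > threshold}.
#' @export
globalThreshold <- function(vol, method = c("otsu", "envelope"),
                            maxLevel = 4095L) {
  method <- match.arg(method)
  t1 <- .otsu(vol, maxLevel = maxLevel)
  if (method == "otsu") return(t1)
  bg <- vol[vol <= t1]
  fg <- vol[vol > t1]
  max((mean(bg) + stats::quantile(fg, 0.25, names = FALSE)) / 2,
      min(vol) + .Machine$double.eps)
}

#' Extract watershed seeds from a binary nucleus mask
#'
#' Seeds are local maxima of the anisotropic (physical-unit) Euclidean
#' distance transform of the mask. The raw discrete transform carries
#' ridge artefacts, so it is lightly smoothed (1 px isotropic Gaussian)
#' before maxima detection; shallow maxima below \code{prominence} times
#' the global peak are discarded, and the rest are thinned by a greedy
#' minimum-separation rule: candidates are visited in decreasing distance
#' order (ties by scan order) and accepted if at least
#' \code{minSeparationNm} away from every accepted seed. The default
#' separation is 0.7 times the expected nuclear radius. Holes inside
#' nuclei (nucleoli) are filled per z-slice before the transform so the
#' distance peaks at the true nuclear centre.
#'
#' @param mask logical \code{(z, y, x)} foreground mask.
#' @param voxelSize physical pitch in nm, \code{c(x, y, z)}.
#' @param expectedRadiusNm expected nuclear radius (nm); sets the default
#'   seed separation.
#' @param minSeparationNm minimum physical distance between seeds.
#' @param prominence fraction of the global distance peak below which
#'   candidate maxima are discarded (suppresses neck/ridge artefacts).
#' @return data.frame with columns \code{z, y, x} (pixel coordinates),
#'   \code{idx} (linear index) and \code{dist} (distance-transform value,
#'   nm); zero rows for an empty mask.
#' @export
extractSeeds <- function(mask, voxelSize, expectedRadiusNm = 5000,
                         minSeparationNm = 0.7 * expectedRadiusNm,
                         prominence = 0.3) {
  empty <- data.frame(z = integer(), y = integer(), x = integer(),
                      idx = integer(), dist = numeric())
  if (!any(mask)) return(empty)
  mask <- .fillHolesSlices(mask)
  d <- .edt3d(mask, voxelSize)
  ds <- array(.gauss_blur3d_cpp(as.numeric(d), dim(d), c(1, 1, 1)), dim(d))
  cand <- .localmax3d_cpp(as.numeric(ds), as.logical(mask), dim(mask))
  if (length(cand) == 0L) return(empty)
  cand <- cand[ds[cand] >= prominence * max(ds[cand])]
  ord <- order(-ds[cand], cand)
  cand <- cand[ord]
  zyx <- .idx2zyx(cand, dim(mask))
  # physical coordinates (nm) for the separation rule
  phys <- cbind(zyx[, "x"] * voxelSize[1L], zyx[, "y"] * voxelSize[2L],
                zyx[, "z"] * voxelSize[3L])
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    if (!any(keep)) {
      keep[i] <- TRUE
      next
    }
    dd <- sqrt(colSums((t(phys[keep, , drop = FALSE]) - phys[i, ])^2))
    if (all(dd >= minSeparationNm)) keep[i] <- TRUE
  }
  sel <- which(keep)
  data.frame(z = zyx[sel, "z"], y = zyx[sel, "y"], x = zyx[sel, "x"],
             idx = cand[sel], dist = d[cand[sel]])
}

# fill holes slice-by-slice (EBImage fillHull works per 2D frame)
.fillHolesSlices <- function(mask) {
  dm <- dim(mask)
  # EBImage frames are the 3rd dimension: permute (z,y,x) -> (y,x,z)
  m <- aperm(array(as.numeric(mask), dm), c(2L, 3L, 1L))
  filled <- EBImage::fillHull(EBImage::Image(m))
  aperm(EBImage::imageData(filled), c(3L, 1L, 2L)) > 0
}

#' 3D seeded watershed segmentation
#'
#' Partitions the foreground mask into one region per seed by priority
#' flooding of the inverted (negated) anisotropic distance transform,
#' 6-connected, with deterministic FIFO tie-breaking: identical inputs give
#' identical labelings.
#'
#' @param dapi 3D \code{(z, y, x)} intensity array (used only for its
#'   geometry; the flooding relief is the inverted distance transform of
#'   \code{mask}).
#' @param seeds seed table from [extractSeeds()] (needs columns \code{idx};
#'   labels are assigned 1..nrow in seed order).
#' @param mask logical foreground mask; every seed must lie inside it.
#' @param voxelSize physical pitch in nm, \code{c(x, y, z)}.
#' @return integer \code{(z, y, x)} label volume; every foreground pixel
#'   carries exactly one seed label, background is 0.
#' @export
watershed3D <- function(dapi, seeds, mask, voxelSize) {
  stopifnot(nrow(seeds) >= 1L)
  if (any(!mask[seeds$idx]))
    stop("seed outside the foreground mask")
  mask <- .fillHolesSlices(mask)
  d <- .edt3d(mask, voxelSize)
  labels <- .watershed3d_cpp(as.numeric(-d), as.logical(mask), dim(mask),
                             as.numeric(seeds$idx),
                             seq_len(nrow(seeds)))
  array(labels, dim(mask))
}

#' Collect nucleus ROIs from a label volume
#'
#' Builds one \linkS4class{NucleusROI} per label and applies the ROI
#' filters: minimum volume and (optionally) removal of nuclei touching any
#' stack face, whose volumes are unreliable. Removal counts are reported as
#' an attribute.
#'
#' @param labels integer \code{(z, y, x)} label volume (0 = background).
#' @param minVolumePx drop ROIs smaller than this many pixels.
#' @param excludeBorder drop ROIs touching the stack border?
#' @return list of \linkS4class{NucleusROI}, with attribute
#'   \code{"excluded"} = \code{c(small = , border = )}.
#' @export
collectRois <- function(labels, minVolumePx = 0L, excludeBorder = TRUE) {
  dims <- dim(labels)
  idx <- which(labels > 0L)
  rois <- list()
  nSmall <- 0L
  nBorder <- 0L
  if (length(idx)) {
    labs <- labels[idx]
    zyx <- .idx2zyx(idx, dims)
    ord <- order(labs)
    idx <- idx[ord]
    labs <- labs[ord]
    zyx <- zyx[ord, , drop = FALSE]
    splits <- split(seq_along(idx), labs)
    for (ln in names(splits)) {
      sel <- splits[[ln]]
      pz <- zyx[sel, , drop = FALSE]
      border <- any(pz[, "z"] == 1L | pz[, "z"] == dims[1L] |
                    pz[, "y"] == 1L | pz[, "y"] == dims[2L] |
                    pz[, "x"] == 1L | pz[, "x"] == dims[3L])
      vol <- length(sel)
      if (vol < minVolumePx) {
        nSmall <- nSmall + 1L
        next
      }
      if (excludeBorder && border) {
        nBorder <- nBorder + 1L
        next
      }
      roi <- new("NucleusROI",
                 label = as.integer(ln),
                 pixels = as.integer(idx[sel]),
                 volumePx = vol,
                 centroid = c(z = mean(pz[, "z"]), y = mean(pz[, "y"]),
                              x = mean(pz[, "x"])),
                 bbox = rbind(min = apply(pz, 2, min),
                              max = apply(pz, 2, max)),
                 borderTouching = border)
      rois[[length(rois) + 1L]] <- roi
    }
  }
  attr(rois, "excluded") <- c(small = nSmall, border = nBorder)
  rois
}

#' Segment nuclei from an ImageStack (threshold + seeds + watershed)
#'
#' Convenience wrapper running the full DAPI-channel segmentation:
#' image-inherent global threshold, per-slice hole filling, distance
#' transform seeding, 3D seeded watershed, and ROI collection.
#'
#' @param stack an \linkS4class{ImageStack} with a \code{"DAPI"} channel.
#' @param expectedRadiusNm expected nuclear radius (nm), used for the seed
#'   separation default.
#' @param minVolumePx minimum ROI volume in pixels.
#' @param excludeBorder drop border-touching nuclei?
#' @param thresholdMethod see [globalThreshold()]; the volume-unbiased
#'   \code{"envelope"} refinement by default.
#' @return list with \code{rois} (list of \linkS4class{NucleusROI}),
#'   \code{labels} (label volume), \code{threshold}, \code{seeds}, and
#'   \code{excluded} counts.
#' @export
segmentNuclei <- function(stack, expectedRadiusNm = 5000,
                          minVolumePx = 50L, excludeBorder = TRUE,
                          thresholdMethod = "envelope") {
  dapi <- getChannel(stack, "DAPI")
  thr <- globalThreshold(dapi, method = thresholdMethod,
                         maxLevel = 2^stack@bitDepth - 1L)
  mask <- dapi > thr
  mask <- .fillHolesSlices(mask)
  seeds <- extractSeeds(mask, voxelSize(stack),
                        expectedRadiusNm = expectedRadiusNm)
  if (nrow(seeds) == 0L)
    return(list(rois = list(), labels = array(0L, dim(mask)),
                threshold = thr, seeds = seeds,
                excluded = c(small = 0L, border = 0L)))
  labels <- watershed3D(dapi, seeds, mask, voxelSize(stack))
  rois <- collectRois(labels, minVolumePx = minVolumePx,
                      excludeBorder = excludeBorder)
  list(rois = rois, labels = labels, threshold = thr, seeds = seeds,
       excluded = attr(rois, "excluded"))
}
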