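#' Image-inherent low-intensity threshold for one channel
#'
#' Otsu threshold on the pooled within-ROI intensity histogram of a
#' channel, computed once per stack so that all its nuclei share the same
#' low/high cut. Pixels strictly below the threshold count as
#' "low-intensity" for LID%/LIM% and for the voxel agreement feature.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param rois list of \linkS4class{NucleusROI} whose pixels are pooled;
#'   \code{NULL} pools the whole stack.
#' @param channel \code{"DAPI"} or \code{"MeC"}.
#' @return scalar threshold on the raw intensity scale.
#' @export
lowIntensityThreshold <- function(stack, rois = NULL, channel) {
  v <- getChannel(stack, channel)
  if (!is.null(rois)) v <- v[unlist(lapply(rois, roiPixels))]
  .otsu(v, maxLevel = 2^stack@bitDepth - 1L)
}

#' Low/high thresholds and robust intensity scales for a stack
#'
#' Convenience bundle: per-channel Otsu low-intensity thresholds and the
#' robust intensity scale (99.5th percentile of pooled ROI pixels by
#' default; the maximum is fragile to hot pixels at 12 bits) used to
#' normalise \code{cond} and \code{meth} into [0, 1].
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param rois list of \linkS4class{NucleusROI}.
#' @param scalePercentile percentile defining the intensity scale.
#' @return list with \code{tDapi, tMec, scaleDapi, scaleMec}.
#' @export
channelCalibration <- function(stack, rois, scalePercentile = 0.995) {
  idx <- unlist(lapply(rois, roiPixels))
  .calibrate(getChannel(stack, "DAPI")[idx], getChannel(stack, "MeC")[idx],
             2^stack@bitDepth - 1L, scalePercentile)
}

.calibrate <- function(d, m, maxL, scalePercentile) {
  list(
    tDapi = .otsu(d, maxLevel = maxL),
    tMec = .otsu(m, maxLevel = maxL),
    scaleDapi = stats::quantile(d, scalePercentile, names = FALSE),
    scaleMec = stats::quantile(m, scalePercentile, names = FALSE)
  )
}

#' Percentages of low-intensity DAPI and MeC pixels in an ROI
#'
#' \code{LID\%} is the percentage of ROI pixels whose DAPI intensity lies
#' below the image-inherent low-intensity threshold; \code{LIM\%} is the
#' MeC analogue.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param roi a \linkS4class{NucleusROI}.
#' @param calib calibration from [channelCalibration()] (needs
#'   \code{tDapi}, \code{tMec}).
#' @return named numeric \code{c(lid_pct, lim_pct)} in [0, 100].
#' @export
lidLimPercent <- function(stack, roi, calib) {
  idx <- roiPixels(roi)
  if (length(idx) == 0L) stop("empty ROI")
  c(lid_pct = 100 * mean(getChannel(stack, "DAPI")[idx] < calib$tDapi),
    lim_pct = 100 * mean(getChannel(stack, "MeC")[idx] < calib$tMec))
}

#' Partition a nucleus into 500 nm analysis cubes
#'
#' Lays a cube lattice of physical edge \code{cubeSizeNm} over the ROI,
#' anchored at the ROI bounding-box corner (so features are
#' translation-invariant for identical nuclei). At the 120 x 120 x 250 nm
#' pitch a cube spans ceil(500/120) = 5 x 5 pixels laterally and 2 axially.
#' Partial cubes at the ROI boundary are retained with their occupancy.
#' Every ROI pixel belongs to exactly one cube, so occupancies sum to the
#' ROI volume.
#'
#' Each cube gets a normalised radial position \eqn{r \in [0, 1]}: the
#' physical distance from the ROI centroid to the cube centre, divided by
#' the centroid-to-surface distance along that direction (found by ray
#' marching on the ROI mask), clipped to [0, 1]. The direction-dependent
#' denominator keeps \eqn{r} comparable across ellipsoidal nuclei.
#'
#' @param roi a \linkS4class{NucleusROI}.
#' @param stack an \linkS4class{ImageStack} (supplies voxel metadata and
#'   the stack geometry).
#' @param cubeSizeNm physical cube edge, default 500 nm; must be at least
#'   the largest pixel pitch.
#' @return list (class \code{"VoxelGrid"}) with \code{cubeSizeNm} and a
#'   data.frame \code{cells} (one row per cube: \code{cube}, occupancy
#'   \code{occ}, \code{meanDapi}, \code{meanMec}, counts of low pixels per
#'   channel \code{nLowD}/\code{nLowM} filled later, cube centre physical
#'   coords, \code{r}), plus \code{pixelCube}: the cube id of every ROI
#'   pixel in ROI-pixel order.
#' @export
voxelize <- function(roi, stack, cubeSizeNm = 500) {
  vs <- voxelSize(stack)
  if (is.null(vs) || any(is.na(vs)))
    stop("missing physical voxel-size metadata")
  if (cubeSizeNm < max(vs))
    stop("cube size must be at least the largest pixel pitch (",
         max(vs), " nm)")
  dims <- dim(imgData(stack))[-1L]
  idx <- roiPixels(roi)
  zyx <- .idx2zyx(idx, dims)
  # cube extent in pixels per axis
  ext <- c(z = ceiling(cubeSizeNm / unname(vs[3L])),
           y = ceiling(cubeSizeNm / unname(vs[2L])),
           x = ceiling(cubeSizeNm / unname(vs[1L])))
  bb0 <- c(min(zyx[, "z"]), min(zyx[, "y"]), min(zyx[, "x"]))
  ci <- cbind(
    (zyx[, "z"] - bb0[1L]) %/% ext["z"],
    (zyx[, "y"] - bb0[2L]) %/% ext["y"],
    (zyx[, "x"] - bb0[3L]) %/% ext["x"]
  )
  nCub <- apply(ci, 2L, max) + 1L
  cubeId <- ci[, 1L] + nCub[1L] * (ci[, 2L] + nCub[2L] * ci[, 3L]) + 1L

  cent <- roiCentroid(roi)  # (z, y, x) in px
  centNm <- c(cent[1L] * vs[3L], cent[2L] * vs[2L], cent[3L] * vs[1L])

  uc <- sort(unique(cubeId))
  occ <- tabulate(match(cubeId, uc), nbins = length(uc))
  # cube centres: physical centre of the cube's pixel block
  ucId <- uc - 1L
  czc <- ucId %% nCub[1L]
  rr <- ucId %/% nCub[1L]
  cyc <- rr %% nCub[2L]
  cxc <- rr %/% nCub[2L]
  cubeCentrePx <- cbind(
    z = bb0[1L] + czc * ext["z"] + (ext["z"] - 1) / 2,
    y = bb0[2L] + cyc * ext["y"] + (ext["y"] - 1) / 2,
    x = bb0[3L] + cxc * ext["x"] + (ext["x"] - 1) / 2
  )
  cubeCentreNm <- cbind(
    z = cubeCentrePx[, "z"] * vs[3L],
    y = cubeCentrePx[, "y"] * vs[2L],
    x = cubeCentrePx[, "x"] * vs[1L]
  )

  r <- .radialPositions(cubeCentreNm, centNm, idx, dims, vs)

  cells <- data.frame(
    cube = uc, occ = occ,
    cz = cubeCentrePx[, "z"], cy = cubeCentrePx[, "y"],
    cx = cubeCentrePx[, "x"], r = r
  )
  structure(list(cubeSizeNm = cubeSizeNm, cells = cells,
                 pixelCube = match(cubeId, uc), roi = roi),
            class = "VoxelGrid")
}

# normalised radial position of cube centres: |c - centroid| divided by the
# centroid-to-surface distance along the same ray, found by marching on the
# ROI pixel set; clipped to [0, 1]
.radialPositions <- function(cubeCentreNm, centNm, roiIdx, dims, vs) {
  inRoi <- logical(prod(dims))
  inRoi[roiIdx] <- TRUE
  step <- min(vs) / 2
  maxNm <- sqrt(sum((dims * c(vs[3L], vs[2L], vs[1L]))^2))
  vapply(seq_len(nrow(cubeCentreNm)), function(i) {
    dvec <- cubeCentreNm[i, ] - centNm  # (z, y, x) nm
    dist <- sqrt(sum(dvec^2))
    if (dist < 1e-9) return(0)
    u <- dvec / dist
    t <- dist
    repeat {
      t <- t + step
      if (t > maxNm) break
      p <- centNm + t * u
      pz <- round(p[1L] / vs[3L])
      py <- round(p[2L] / vs[2L])
      px <- round(p[3L] / vs[1L])
      if (pz < 1 || pz > dims[1L] || py < 1 || py > dims[2L] ||
          px < 1 || px > dims[3L]) break
      if (!inRoi[pz + dims[1L] * ((py - 1) + dims[2L] * (px - 1))]) break
    }
    bound <- t - step / 2
    min(max(dist / bound, 0), 1)
  }, numeric(1))
}

#' Per-cube texture features cond, meth and assoc
#'
#' For each occupied cube: \code{cond} is the mean DAPI intensity over the
#' cube's ROI pixels divided by the robust image scale (chromatin
#' condensation, clipped to [0, 1]); \code{meth} is the MeC analogue
#' (relative methylation); \code{assoc} is the fraction of the cube's
#' pixels whose two channels agree in thresholded state (both low or both
#' high) -- 1 when either agreement class fills the cube (degenerate
#' agreement), 0 for a perfectly anti-correlated cube.
#'
#' @param grid a \code{VoxelGrid} from [voxelize()].
#' @param stack an \linkS4class{ImageStack}.
#' @param calib calibration from [channelCalibration()].
#' @return \code{grid} with \code{cond}, \code{meth}, \code{assoc},
#'   \code{meanDapi}, \code{meanMec} columns added to \code{grid$cells}.
#' @export
voxelFeatures <- function(grid, stack, calib) {
  idx <- roiPixels(grid$roi)
  .voxelFeaturesVec(grid, getChannel(stack, "DAPI")[idx],
                    getChannel(stack, "MeC")[idx], calib)
}

# d, m: per-pixel intensities in ROI-pixel order
.voxelFeaturesVec <- function(grid, d, m, calib) {
  g <- grid$pixelCube
  n <- nrow(grid$cells)
  occ <- grid$cells$occ
  sumD <- vapply(split(d, g), sum, numeric(1))
  sumM <- vapply(split(m, g), sum, numeric(1))
  agree <- (d < calib$tDapi) == (m < calib$tMec)
  nAgree <- vapply(split(agree, g), sum, numeric(1))
  ordKey <- as.integer(names(sumD))
  meanD <- numeric(n)
  meanM <- numeric(n)
  assoc <- numeric(n)
  meanD[ordKey] <- sumD / occ[ordKey]
  meanM[ordKey] <- sumM / occ[ordKey]
  assoc[ordKey] <- nAgree / occ[ordKey]
  grid$cells$meanDapi <- meanD
  grid$cells$meanMec <- meanM
  grid$cells$cond <- pmin(pmax(meanD / calib$scaleDapi, 0), 1)
  grid$cells$meth <- pmin(pmax(meanM / calib$scaleMec, 0), 1)
  grid$cells$assoc <- assoc
  grid
}

#' Volume-weighted aggregation of voxel features to one nucleus
#'
#' Each whole-ROI scalar is the occupancy-weighted mean of the per-cube
#' values, \eqn{\sum_v occ_v f_v / \sum_v occ_v}; at full occupancy this
#' equals the arithmetic mean. LID%/LIM%, raw channel means and the ROI
#' volume are attached alongside.
#'
#' @param grid a \code{VoxelGrid} with features (see [voxelFeatures()]).
#' @param stack an \linkS4class{ImageStack}.
#' @param calib calibration from [channelCalibration()].
#' @return one-row data.frame: \code{label, volume_px, mean_dapi,
#'   mean_mec, lid_pct, lim_pct, cond, meth, assoc}.
#' @export
aggregateVoxels <- function(grid, stack, calib) {
  idx <- roiPixels(grid$roi)
  .aggregateVec(grid, getChannel(stack, "DAPI")[idx],
                getChannel(stack, "MeC")[idx], calib)
}

.aggregateVec <- function(grid, d, m, calib) {
  cells <- grid$cells
  w <- cells$occ
  wm <- function(v) sum(w * v) / sum(w)
  data.frame(
    label = roiLabel(grid$roi),
    volume_px = roiVolume(grid$roi),
    mean_dapi = mean(d),
    mean_mec = mean(m),
    lid_pct = 100 * mean(d < calib$tDapi),
    lim_pct = 100 * mean(m < calib$tMec),
    cond = wm(cells$cond),
    meth = wm(cells$meth),
    assoc = wm(cells$assoc)
  )
}

#' Normalised centre-to-periphery radial profile of one nucleus
#'
#' Cubes are binned by their normalised radial position \eqn{r} into
#' \code{nShells} equal-width shells; each feature is averaged per shell
#' with occupancy weights. Empty shells are \code{NA}.
#'
#' @param grid a \code{VoxelGrid} with features.
#' @param nShells number of shells (>= 1; with 1 shell the profile equals
#'   the whole-ROI aggregate).
#' @return data.frame with \code{shell}, shell mid-position \code{rMid},
#'   \code{occ}, and weighted mean \code{cond}, \code{meth}, \code{assoc}.
#' @export
radialProfile <- function(grid, nShells = 5L) {
  stopifnot(nShells >= 1L)
  cells <- grid$cells
  br <- seq(0, 1, length.out = nShells + 1L)
  shell <- pmin(pmax(findInterval(cells$r, br, rightmost.closed = TRUE),
                     1L), nShells)
  out <- data.frame(shell = seq_len(nShells),
                    rMid = (br[-1L] + br[-length(br)]) / 2,
                    occ = 0, cond = NA_real_, meth = NA_real_,
                    assoc = NA_real_)
  for (s in seq_len(nShells)) {
    sel <- shell == s
    if (!any(sel)) next
    w <- cells$occ[sel]
    out$occ[s] <- sum(w)
    out$cond[s] <- sum(w * cells$cond[sel]) / sum(w)
    out$meth[s] <- sum(w * cells$meth[sel]) / sum(w)
    out$assoc[s] <- sum(w * cells$assoc[sel]) / sum(w)
  }
  out
}

#' Per-shell dispersion of radial profiles across a population
#'
#' For each shell and feature: mean, sample standard deviation (n-1) and
#' coefficient of variation across nuclei, ignoring missing shells.
#'
#' @param profiles list of radial profiles (same \code{nShells}; see
#'   [radialProfile()]).
#' @return data.frame with one row per shell x feature:
#'   \code{shell, feature, n, mean, sd, cv}.
#' @export
profileDispersion <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  nS <- nrow(profiles[[1L]])
  if (any(vapply(profiles, nrow, 1L) != nS))
    stop("profiles must share the same number of shells")
  feats <- c("cond", "meth", "assoc")
  rows <- list()
  for (s in seq_len(nS)) {
    for (f in feats) {
      v <- vapply(profiles, function(p) p[[f]][s], numeric(1))
      v <- v[!is.na(v)]
      mu <- if (length(v)) mean(v) else NA_real_
      sdv <- if (length(v) > 1L) stats::sd(v) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        shell = s, feature = f, n = length(v), mean = mu, sd = sdv,
        cv = ifelse(!is.na(mu) && abs(mu) > 0, sdv / mu, NA_real_))
    }
  }
  do.call(rbind, rows)
}

#' All TVA features for one nucleus
#'
#' Convenience wrapper: voxelise, compute per-cube features, aggregate, and
#' (optionally) attach the radial profile.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param roi a \linkS4class{NucleusROI}.
#' @param calib calibration from [channelCalibration()].
#' @param cubeSizeNm physical cube edge (default 500 nm).
#' @param nShells shells for the radial profile; \code{NULL} skips it.
#' @return one-row data.frame of features; when \code{nShells} is given the
#'   profile data.frame is attached as attribute \code{"profile"}.
#' @export
nucleusFeatures <- function(stack, roi, calib, cubeSizeNm = 500,
                            nShells = NULL) {
  idx <- roiPixels(roi)
  .nucleusFeaturesVec(roi, stack, getChannel(stack, "DAPI")[idx],
                      getChannel(stack, "MeC")[idx], calib, cubeSizeNm,
                      nShells)
}

.nucleusFeaturesVec <- function(roi, stack, d, m, calib, cubeSizeNm,
                                nShells) {
  grid <- voxelize(roi, stack, cubeSizeNm = cubeSizeNm)
  grid <- .voxelFeaturesVec(grid, d, m, calib)
  row <- .aggregateVec(grid, d, m, calib)
  if (!is.null(nShells))
    attr(row, "profile") <- radialProfile(grid, nShells = nShells)
  row
}
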