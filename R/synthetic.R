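#' Phenotype specification for the phantom generator
#'
#' Describes one growth-behaviour phenotype as generator parameters: nuclear
#' size, the target fraction of high-MeC (methylated) and high-DAPI
#' (condensed) chromatin, heterochromatin focus count, and the confocal-like
#' degradation (anisotropic blur, Poisson-Gaussian noise, 12-bit
#' quantisation).
#'
#' The three presets encode the growth-behaviour scheme the analysis is
#' meant to recover: global methylation and condensation ordered
#' \emph{senescent < cancer < proliferating}, and senescent nuclei enlarged
#' relative to proliferating ones (population volume ratio about 1.6). The
#' preset nuclear radii correspond to interphase nuclei of roughly 150-250
#' thousand pixels at the default 120 x 120 x 250 nm pitch.
#'
#' Both channels derive their texture from one shared focus field, so
#' high-MeC chromatin colocalises with condensed (high-DAPI) chromatin; the
#' per-channel high fraction is set by \code{mecLevel} / \code{condLevel}.
#'
#' @param name preset name (\code{"proliferating"}, \code{"cancer"},
#'   \code{"senescent"}) or a custom label (then give all parameters).
#' @param radiusNm,radiusSdNm mean and spread of the ellipsoid semi-axes, nm.
#' @param mecLevel target fraction of high-MeC chromatin, in [0, 1].
#' @param condLevel target fraction of high-DAPI chromatin, in [0, 1].
#' @param nFoci number of dense heterochromatin blobs per nucleus.
#' @param fociSigmaNm Gaussian radius of one blob, nm.
#' @param zFlatten axial flattening factor of adherent nuclei (z semi-axis =
#'   \code{zFlatten} times the lateral one).
#' @param blurSigmaNm anisotropic blur sigma, nm, as \code{c(x, y, z)}
#'   (point-spread-function stand-in); 0 disables.
#' @param noiseGaussSd Gaussian read-noise sigma (intensity counts).
#' @param noisePhotonScale intensity units per photon for Poisson shot
#'   noise; 0 disables.
#' @param baseDapi,highDapi,baseMec,highMec chromatin intensity levels
#'   (12-bit counts) for the low/high texture states.
#' @param background extranuclear background level (counts).
#' @return A \code{PhenotypeSpec} (validated list).
#' @examples
#' phenotypeSpec("senescent")
#' @export
phenotypeSpec <- function(name = c("proliferating", "cancer", "senescent"),
                          radiusNm = NULL, radiusSdNm = NULL,
                          mecLevel = NULL, condLevel = NULL, nFoci = NULL,
                          fociSigmaNm = 450, zFlatten = 0.7,
                          blurSigmaNm = c(120, 120, 300),
                          noiseGaussSd = 25, noisePhotonScale = 4,
                          baseDapi = 1300, highDapi = 2500,
                          baseMec = 250, highMec = 3000,
                          background = 60) {
  name <- if (length(name) > 1L) name[1L] else name
  presets <- list(
    proliferating = list(radiusNm = 5000, radiusSdNm = 300,
                         mecLevel = 0.50, condLevel = 0.50, nFoci = 40L),
    cancer = list(radiusNm = 4800, radiusSdNm = 300,
                  mecLevel = 0.30, condLevel = 0.35, nFoci = 30L),
    senescent = list(radiusNm = 5900, radiusSdNm = 400,
                     mecLevel = 0.12, condLevel = 0.25, nFoci = 15L)
  )
  p <- presets[[name]]
  spec <- list(
    name = name,
    radiusNm = radiusNm %||% p$radiusNm,
    radiusSdNm = radiusSdNm %||% p$radiusSdNm,
    mecLevel = mecLevel %||% p$mecLevel,
    condLevel = condLevel %||% p$condLevel,
    nFoci = as.integer(nFoci %||% p$nFoci),
    fociSigmaNm = fociSigmaNm, zFlatten = zFlatten,
    blurSigmaNm = as.numeric(blurSigmaNm),
    noiseGaussSd = noiseGaussSd, noisePhotonScale = noisePhotonScale,
    baseDapi = baseDapi, highDapi = highDapi,
    baseMec = baseMec, highMec = highMec, background = background
  )
  if (is.null(spec$radiusNm))
    stop("custom phenotype '", name, "' needs explicit parameters")
  stopifnot(spec$mecLevel >= 0, spec$mecLevel <= 1,
            spec$condLevel >= 0, spec$condLevel <= 1,
            spec$radiusNm > 0, spec$nFoci >= 0L)
  class(spec) <- "PhenotypeSpec"
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# outer product of three axis vectors -> (z, y, x) array
.outer3 <- function(a, b, c) outer(outer(a, b), c)

# render one ellipsoidal nucleus into the (z,y,x) canvases; returns truth row
.renderNucleus <- function(canvas, geom, spec, voxelSize, label) {
  vs <- voxelSize  # c(x, y, z) nm
  zz <- geom$zr[1L]:geom$zr[2L]
  yy <- geom$yr[1L]:geom$yr[2L]
  xx <- geom$xr[1L]:geom$xr[2L]
  A <- (((zz - geom$cz) * vs[3L]) / geom$azNm)^2
  B <- (((yy - geom$cy) * vs[2L]) / geom$ayNm)^2
  C <- (((xx - geom$cx) * vs[1L]) / geom$axNm)^2
  e2 <- .outer3(A, rep(1, length(B)), rep(1, length(C))) +
        .outer3(rep(1, length(A)), B, rep(1, length(C))) +
        .outer3(rep(1, length(A)), rep(1, length(B)), C)
  inside <- e2 <= 1

  # shared focus field drives both channels (condensed chromatin is
  # preferentially methylated)
  FF <- array(0, dim(e2))
  if (spec$nFoci > 0L) {
    s2 <- spec$fociSigmaNm^2
    for (k in seq_len(spec$nFoci)) {
      # focus centre uniform in the 0.85-scaled ellipsoid
      repeat {
        u <- stats::runif(3, -1, 1)
        if (sum(u^2) <= 1) break
      }
      fz <- geom$cz + 0.85 * u[1L] * geom$azNm / vs[3L]
      fy <- geom$cy + 0.85 * u[2L] * geom$ayNm / vs[2L]
      fx <- geom$cx + 0.85 * u[3L] * geom$axNm / vs[1L]
      amp <- stats::runif(1, 0.7, 1.3)
      ez <- exp(-0.5 * ((zz - fz) * vs[3L])^2 / s2)
      ey <- exp(-0.5 * ((yy - fy) * vs[2L])^2 / s2)
      ex <- exp(-0.5 * ((xx - fx) * vs[1L])^2 / s2)
      FF <- FF + amp * .outer3(ez, ey, ex)
    }
  }
  Fin <- FF[inside]
  highOf <- function(level) {
    if (level >= 1) rep(TRUE, length(Fin))
    else if (level <= 0 || spec$nFoci == 0L || all(Fin == Fin[1L]))
      rep(FALSE, length(Fin))
    else Fin >= stats::quantile(Fin, 1 - level, names = FALSE)
  }
  highD <- highOf(spec$condLevel)
  highM <- if (geom$invert) {
    # inverted texture: methylation sits where chromatin is open
    if (spec$mecLevel <= 0 || spec$nFoci == 0L) rep(FALSE, length(Fin))
    else Fin <= stats::quantile(Fin, spec$mecLevel, names = FALSE)
  } else highOf(spec$mecLevel)

  dsub <- canvas$dapi[zz, yy, xx, drop = FALSE]
  msub <- canvas$mec[zz, yy, xx, drop = FALSE]
  lsub <- canvas$lab[zz, yy, xx, drop = FALSE]
  din <- ifelse(highD, spec$highDapi, spec$baseDapi) * geom$brightD
  min_ <- ifelse(highM, spec$highMec, spec$baseMec) * geom$brightM
  dsub[inside] <- din
  msub[inside] <- min_
  lsub[inside] <- label
  canvas$dapi[zz, yy, xx] <- dsub
  canvas$mec[zz, yy, xx] <- msub
  canvas$lab[zz, yy, xx] <- lsub

  list(canvas = canvas,
       row = data.frame(
         label = label, volumePx = sum(inside),
         mecLevel = mean(highM), condLevel = mean(highD),
         outlier = FALSE,
         cz = geom$cz, cy = geom$cy, cx = geom$cx,
         axNm = geom$axNm, ayNm = geom$ayNm, azNm = geom$azNm,
         brightD = geom$brightD, brightM = geom$brightM))
}

# confocal-like degradation: anisotropic blur, Poisson-Gaussian noise,
# 12-bit quantisation
.degrade <- function(vol, spec, voxelSize, maxLevel = 4095) {
  dm <- dim(vol)
  if (any(spec$blurSigmaNm > 0))
    vol <- .blur3d(vol, spec$blurSigmaNm, voxelSize)
  n <- length(vol)
  if (spec$noisePhotonScale > 0)
    vol <- stats::rpois(n, pmax(vol, 0) / spec$noisePhotonScale) *
      spec$noisePhotonScale
  if (spec$noiseGaussSd > 0)
    vol <- vol + stats::rnorm(n, 0, spec$noiseGaussSd)
  vol <- round(vol)
  nClip <- sum(vol < 0 | vol > maxLevel)
  if (nClip / n > 0.05)
    message(nClip, " voxel(s) clipped to the 12-bit range")
  array(pmin(pmax(vol, 0), maxLevel), dim = dm)
}

#' Generate a ground-truthed two-channel phantom field of nuclei
#'
#' Places \code{nNuclei} non-overlapping ellipsoidal nuclei by rejection
#' sampling, paints a two-level chromatin texture driven by a shared
#' heterochromatin focus field (DAPI high = condensed, MeC high =
#' methylated, spatially coupled), then degrades both channels with
#' anisotropic Gaussian blur, Poisson-Gaussian noise and 12-bit
#' quantisation. The ground truth (label volume, true volumes and texture
#' fractions) refers to the pre-noise geometry.
#'
#' @param nNuclei number of nuclei to place (0 gives a background-only
#'   field and an empty truth table).
#' @param spec a [phenotypeSpec()].
#' @param fieldShape stack shape in pixels, \code{c(z, y, x)}.
#' @param voxelSize physical pitch in nm, \code{c(x, y, z)}; default the
#'   acquisition constants \code{c(120, 120, 250)}.
#' @param seed integer RNG seed; the output is deterministic given the seed.
#' @param maxTriesPerNucleus placement retries before an infeasible-packing
#'   error.
#' @return \code{list(stack = ImageStack, truth = list(labels = <(z,y,x)
#'   integer array>, table = <per-nucleus data.frame>, spec, voxelSize))}.
#'   Table columns include \code{label, volumePx, mecLevel, condLevel,
#'   outlier} plus the planted geometry.
#' @examples
#' pop <- generatePopulation(2, phenotypeSpec("proliferating",
#'   radiusNm = 1200, radiusSdNm = 60), c(16, 64, 64), seed = 1)
#' pop$truth$table$volumePx
#' @export
generatePopulation <- function(nNuclei, spec, fieldShape,
                               voxelSize = c(120, 120, 250), seed,
                               maxTriesPerNucleus = 400L) {
  stopifnot(inherits(spec, "PhenotypeSpec"), nNuclei >= 0)
  set.seed(seed)
  dims <- as.integer(fieldShape)
  vs <- as.numeric(voxelSize)

  canvas <- list(
    dapi = array(spec$background, dims),
    mec = array(spec$background * 0.7, dims),
    lab = array(0L, dims)
  )
  geoms <- list()
  placed <- 0L
  tries <- 0L
  while (placed < nNuclei) {
    if (tries >= maxTriesPerNucleus * max(nNuclei, 1L))
      stop("placement error: could not fit ", nNuclei,
           " nuclei of radius ~", spec$radiusNm, " nm into the field")
    tries <- tries + 1L
    rl <- max(stats::rnorm(1, spec$radiusNm, spec$radiusSdNm),
              0.5 * spec$radiusNm)
    axNm <- rl * stats::runif(1, 0.9, 1.1)
    ayNm <- rl * stats::runif(1, 0.9, 1.1)
    azNm <- rl * spec$zFlatten
    # +4 px pad keeps the blurred halo off the stack faces
    margin <- c(azNm / vs[3L], ayNm / vs[2L], axNm / vs[1L]) + 4
    if (any(dims < 2 * margin + 2))
      stop("placement error: field too small for nuclei of radius ~",
           spec$radiusNm, " nm")
    cz <- stats::runif(1, 1 + margin[1L], dims[1L] - margin[1L])
    cy <- stats::runif(1, 1 + margin[2L], dims[2L] - margin[2L])
    cx <- stats::runif(1, 1 + margin[3L], dims[3L] - margin[3L])
    ok <- TRUE
    for (g in geoms) {
      dn <- sqrt((((cz - g$cz) * vs[3L]))^2 + (((cy - g$cy) * vs[2L]))^2 +
                 (((cx - g$cx) * vs[1L]))^2)
      if (dn < max(axNm, ayNm) + max(g$axNm, g$ayNm) + 300) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    placed <- placed + 1L
    geoms[[placed]] <- list(
      cz = cz, cy = cy, cx = cx, axNm = axNm, ayNm = ayNm, azNm = azNm,
      zr = c(max(1L, floor(cz - margin[1L])),
             min(dims[1L], ceiling(cz + margin[1L]))),
      yr = c(max(1L, floor(cy - margin[2L])),
             min(dims[2L], ceiling(cy + margin[2L]))),
      xr = c(max(1L, floor(cx - margin[3L])),
             min(dims[3L], ceiling(cx + margin[3L]))),
      brightD = exp(stats::rnorm(1, 0, 0.04)),
      brightM = exp(stats::rnorm(1, 0, 0.04)),
      invert = FALSE
    )
  }

  rows <- vector("list", length(geoms))
  for (i in seq_along(geoms)) {
    res <- .renderNucleus(canvas, geoms[[i]], spec, vs, i)
    canvas <- res$canvas
    rows[[i]] <- res$row
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(), volumePx = integer(),
               mecLevel = numeric(), condLevel = numeric(),
               outlier = logical(), cz = numeric(), cy = numeric(),
               cx = numeric(), axNm = numeric(), ayNm = numeric(),
               azNm = numeric(), brightD = numeric(), brightM = numeric())

  dapi <- .degrade(canvas$dapi, spec, vs)
  mec <- .degrade(canvas$mec, spec, vs)
  data <- array(0L, dim = c(2L, dims))
  data[1L, , , ] <- as.integer(dapi)
  data[2L, , , ] <- as.integer(mec)
  stack <- ImageStack(data, voxelSize = vs,
                      channelNames = c("DAPI", "MeC"))
  list(stack = stack,
       truth = list(labels = canvas$lab, table = table, spec = spec,
                    voxelSize = vs, seed = seed))
}

#' Plant one aberrant nucleus into a phantom population
#'
#' Replaces one randomly chosen nucleus by an aberrant texture so that the
#' K-L codistribution filter has a true positive. Mode
#' \code{"mitotic-compact"} mimics an M-phase cell: a much smaller body of
#' uniformly bright (condensed) DAPI with low MeC. Mode
#' \code{"inverted-texture"} keeps the nuclear shape but puts high MeC where
#' DAPI is low, anti-correlating the two channels and displacing the joint
#' MeC/DAPI histogram off the population's support.
#'
#' @param pop a population as returned by [generatePopulation()].
#' @param mode \code{"mitotic-compact"} or \code{"inverted-texture"}.
#' @param seed integer RNG seed (choice of nucleus and new texture).
#' @return A population list of the same shape, with the chosen nucleus
#'   replaced, its \code{outlier} flag set in the truth table, and the
#'   label volume updated.
#' @export
plantOutlier <- function(pop, mode = c("mitotic-compact",
                                       "inverted-texture"), seed) {
  mode <- match.arg(mode)
  truth <- pop$truth
  if (nrow(truth$table) < 1L)
    stop("no nucleus present to replace")
  set.seed(seed)
  i <- sample.int(nrow(truth$table), 1L)
  g <- as.list(truth$table[i, ])
  spec <- truth$spec
  vs <- truth$voxelSize
  lab <- g$label
  dims <- dim(truth$labels)

  data <- imgData(pop$stack)
  dapi <- array(as.numeric(data[1L, , , ]), dims)
  mec <- array(as.numeric(data[2L, , , ]), dims)

  oldPix <- which(truth$labels == lab)
  if (mode == "mitotic-compact") {
    # erase the old nucleus, then draw a compact bright body at its centre
    bgD <- spec$background + stats::rnorm(length(oldPix), 0, spec$noiseGaussSd)
    bgM <- spec$background * 0.7 +
      stats::rnorm(length(oldPix), 0, spec$noiseGaussSd)
    dapi[oldPix] <- pmin(pmax(round(bgD), 0), 4095)
    mec[oldPix] <- pmin(pmax(round(bgM), 0), 4095)
    truth$labels[oldPix] <- 0L
    g$axNm <- g$axNm * 0.55
    g$ayNm <- g$ayNm * 0.55
    g$azNm <- g$azNm * 0.55
  }
  margin <- c(g$azNm / vs[3L], g$ayNm / vs[2L], g$axNm / vs[1L]) + 1
  geom <- list(cz = g$cz, cy = g$cy, cx = g$cx,
               axNm = g$axNm, ayNm = g$ayNm, azNm = g$azNm,
               zr = c(max(1L, floor(g$cz - margin[1L])),
                      min(dims[1L], ceiling(g$cz + margin[1L]))),
               yr = c(max(1L, floor(g$cy - margin[2L])),
                      min(dims[2L], ceiling(g$cy + margin[2L]))),
               xr = c(max(1L, floor(g$cx - margin[3L])),
                      min(dims[3L], ceiling(g$cx + margin[3L]))),
               brightD = g$brightD, brightM = g$brightM,
               invert = (mode == "inverted-texture"))

  outSpec <- spec
  if (mode == "mitotic-compact") {
    # uniformly condensed chromatin, weak MeC signal
    outSpec$condLevel <- 1
    outSpec$mecLevel <- 0
    outSpec$highDapi <- min(spec$highDapi * 1.15, 4000)
  }
  canvas <- list(dapi = array(spec$background, dims),
                 mec = array(spec$background * 0.7, dims),
                 lab = array(0L, dims))
  res <- .renderNucleus(canvas, geom, outSpec, vs, lab)

  # degrade only the nucleus bounding region, then copy the nucleus pixels
  zz <- geom$zr[1L]:geom$zr[2L]
  yy <- geom$yr[1L]:geom$yr[2L]
  xx <- geom$xr[1L]:geom$xr[2L]
  subD <- .degrade(res$canvas$dapi[zz, yy, xx, drop = FALSE], outSpec, vs)
  subM <- .degrade(res$canvas$mec[zz, yy, xx, drop = FALSE], outSpec, vs)
  subL <- res$canvas$lab[zz, yy, xx, drop = FALSE]
  inNew <- subL == lab

  dSub <- dapi[zz, yy, xx, drop = FALSE]
  mSub <- mec[zz, yy, xx, drop = FALSE]
  lSub <- truth$labels[zz, yy, xx, drop = FALSE]
  dSub[inNew] <- subD[inNew]
  mSub[inNew] <- subM[inNew]
  lSub[lSub == lab] <- 0L
  lSub[inNew] <- lab
  dapi[zz, yy, xx] <- dSub
  mec[zz, yy, xx] <- mSub
  truth$labels[zz, yy, xx] <- lSub

  row <- res$row
  truth$table[i, c("volumePx", "mecLevel", "condLevel")] <-
    row[, c("volumePx", "mecLevel", "condLevel")]
  truth$table$outlier[i] <- TRUE
  truth$table[i, c("axNm", "ayNm", "azNm")] <- c(g$axNm, g$ayNm, g$azNm)

  data[1L, , , ] <- as.integer(dapi)
  data[2L, , , ] <- as.integer(mec)
  stack <- ImageStack(data, voxelSize = vs,
                      channelNames = channelNames(pop$stack))
  list(stack = stack, truth = truth)
}
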