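# Shared fixtures, built in code and memoised per test run.

.fix <- new.env(parent = emptyenv())

# a phenotype preset scaled down to test-sized nuclei (radius ~1-2 um keeps
# fields small while leaving dozens of 500 nm cubes per nucleus)
smallSpec <- function(name = "proliferating", scale = 0.3, ...) {
  sp <- phenotypeSpec(name, ...)
  sp$radiusNm <- sp$radiusNm * scale
  sp$radiusSdNm <- sp$radiusSdNm * scale
  sp
}

# 6-nucleus default-noise phantom reused across files
fixturePop <- function() {
  if (is.null(.fix$pop))
    .fix$pop <- suppressMessages(generatePopulation(
      6, smallSpec(), c(24, 160, 160), seed = 42))
  .fix$pop
}

# two-channel stack from plain (z, y, x) arrays
stack2ch <- function(dapi, mec, voxelSize = c(120, 120, 250)) {
  stopifnot(identical(dim(dapi), dim(mec)))
  a <- array(0L, c(2L, dim(dapi)))
  a[1L, , , ] <- as.integer(dapi)
  a[2L, , , ] <- as.integer(mec)
  ImageStack(a, voxelSize = voxelSize, channelNames = c("DAPI", "MeC"))
}

# single ROI covering the TRUE pixels of `sel` (a logical (z,y,x) array)
roiFromMask <- function(sel) {
  labels <- array(0L, dim(sel))
  labels[sel] <- 1L
  collectRois(labels, minVolumePx = 0L, excludeBorder = FALSE)[[1L]]
}

# logical ball mask |p - centre| <= rPx (isotropic, pixel units)
ballMask <- function(dims, centre, rPx) {
  z <- slice.index(array(0, dims), 1L)
  y <- slice.index(array(0, dims), 2L)
  x <- slice.index(array(0, dims), 3L)
  (z - centre[1L])^2 + (y - centre[2L])^2 + (x - centre[3L])^2 <= rPx^2
}

# random normalised histogram matrix
randHist <- function(nb, rng) {
  h <- matrix(rng(nb * nb), nb, nb)
  h / sum(h)
}
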