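# Internal helpers shared across modules.

# linear (1-based) index -> (z, y, x) matrix for a (nz, ny, nx) volume
.idx2zyx <- function(idx, dims) {
  idx0 <- idx - 1L
  z <- idx0 %% dims[1L]
  r <- idx0 %/% dims[1L]
  y <- r %% dims[2L]
  x <- r %/% dims[2L]
  cbind(z = z + 1L, y = y + 1L, x = x + 1L)
}

.zyx2idx <- function(zyx, dims) {
  (zyx[, 1L]) + dims[1L] * ((zyx[, 2L] - 1L) + dims[2L] * (zyx[, 3L] - 1L))
}

# Otsu threshold on an intensity sample, via EBImage's histogram-based
# implementation. Values are assumed integer-valued in [0, maxLevel].
# Returns a threshold on the raw intensity scale; foreground is `> thr`.
.otsu <- function(values, maxLevel = 4095L) {
  values <- as.numeric(values)
  rng <- range(values)
  if (rng[1L] == rng[2L])
    stop("no foreground separable: constant intensities")
  img <- EBImage::Image(matrix(values / maxLevel, ncol = 1L))
  thr <- EBImage::otsu(img, range = c(0, 1), levels = maxLevel + 1L)
  thr * maxLevel
}

# anisotropic Gaussian blur of a (z, y, x) volume, sigma in nm per axis
# given as c(x, y, z) to match voxelSize ordering
.blur3d <- function(vol, sigmaNm, voxelSizeNm) {
  sigmaPx <- c(
    z = sigmaNm[3L] / voxelSizeNm[3L],
    y = sigmaNm[2L] / voxelSizeNm[2L],
    x = sigmaNm[1L] / voxelSizeNm[1L]
  )
  out <- .gauss_blur3d_cpp(as.numeric(vol), dim(vol), as.numeric(sigmaPx))
  array(out, dim(vol))
}

.edt3d <- function(mask, voxelSizeNm) {
  d <- .edt3d_cpp(as.logical(mask), dim(mask),
                  as.numeric(c(voxelSizeNm[3L], voxelSizeNm[2L],
                               voxelSizeNm[1L])))
  array(d, dim(mask))
}
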