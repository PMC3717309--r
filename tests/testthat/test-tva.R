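calib0 <- list(tDapi = 500, tMec = 500, scaleDapi = 1000, scaleMec = 1000)

test_that("an ROI the size of one cube gives a single voxel at r = 0", {
  dims <- c(8, 16, 16)
  sel <- array(FALSE, dims)
  sel[3:4, 6:10, 6:10] <- TRUE  # 2 x 5 x 5 px = one 500 nm cube at 120/250 nm
  d <- array(0L, dims); d[sel] <- 900L
  s <- stack2ch(d, d)
  g <- voxelize(roiFromMask(sel), s)
  expect_equal(nrow(g$cells), 1L)
  expect_equal(g$cells$occ, 50L)
  expect_equal(g$cells$r, 0)
})

test_that("cubes straddling the ROI edge keep partial occupancy", {
  dims <- c(8, 16, 16)
  sel <- array(FALSE, dims)
  sel[3:4, 6:10, 6:12] <- TRUE  # 7 px in x: one full cube + a 2-px sliver
  s <- stack2ch(array(1L, dims), array(1L, dims))
  g <- voxelize(roiFromMask(sel), s)
  expect_equal(sort(g$cells$occ), c(20L, 50L))
  expect_equal(sum(g$cells$occ), sum(sel))
})

test_that("voxel occupancies partition every phantom nucleus exactly", {
  pop <- fixturePop()
  rois <- collectRois(pop$truth$labels, minVolumePx = 0,
                      excludeBorder = FALSE)
  for (r in rois) {
    g <- voxelize(r, pop$stack)
    expect_identical(sum(g$cells$occ), roiVolume(r))
    expect_true(all(g$cells$r >= 0 & g$cells$r <= 1))
  }
})

test_that("a cube smaller than the pixel pitch is rejected", {
  pop <- fixturePop()
  roi <- collectRois(pop$truth$labels, 0, FALSE)[[1L]]
  expect_error(voxelize(roi, pop$stack, cubeSizeNm = 200), "pitch")
})

test_that("voxel features hit their degenerate bounds", {
  dims <- c(4, 10, 10)
  sel <- array(FALSE, dims); sel[1:2, 1:5, 1:5] <- TRUE
  roi <- roiFromMask(sel)
  mk <- function(dv, mv) {
    d <- array(0L, dims); m <- array(0L, dims)
    d[sel] <- dv; m[sel] <- mv
    stack2ch(d, m)
  }
  # every pixel at the scale intensity in both channels
  f1 <- voxelFeatures(voxelize(roi, mk(1000L, 1000L)), mk(1000L, 1000L),
                      calib0)$cells
  expect_equal(f1$cond, 1); expect_equal(f1$meth, 1)
  expect_equal(f1$assoc, 1)
  # all-zero pixels: both-low everywhere is degenerate agreement
  f0 <- voxelFeatures(voxelize(roi, mk(0L, 0L)), mk(0L, 0L), calib0)$cells
  expect_equal(f0$cond, 0); expect_equal(f0$meth, 0)
  expect_equal(f0$assoc, 1)
  # thresholded-anticorrelated channels on every pixel
  dv <- array(0L, dims); mv <- array(0L, dims)
  half <- sel & slice.index(dv, 3L) <= 2
  dv[sel] <- 900L; dv[half] <- 100L
  mv[sel] <- 100L; mv[half] <- 900L
  sA <- stack2ch(dv, mv)
  fA <- voxelFeatures(voxelize(roi, sA), sA, calib0)$cells
  expect_equal(fA$assoc, 0)
})

test_that("aggregation is the occupancy-weighted mean (100,50 / 0.9,0.3 -> 0.7
          up to the shared-occupancy scale)", {
  dims <- c(4, 12, 8)
  vs <- c(100, 100, 250)
  sel <- array(FALSE, dims)
  sel[1:2, 1:5, 1:5] <- TRUE          # full cube: 50 px
  sel[1, 6:10, 1:5] <- TRUE           # half-filled cube: 25 px
  d <- array(0L, dims)
  d[1:2, 1:5, 1:5] <- 900L            # cond 0.9
  d[1, 6:10, 1:5] <- 300L             # cond 0.3
  s <- stack2ch(d, d, voxelSize = vs)
  roi <- roiFromMask(sel)
  g <- voxelFeatures(voxelize(roi, s), s, calib0)
  expect_setequal(g$cells$occ, c(50L, 25L))
  expect_setequal(round(g$cells$cond, 12), c(0.9, 0.3))
  agg <- aggregateVoxels(g, s, calib0)
  expect_equal(agg$cond, (50 * 0.9 + 25 * 0.3) / 75)  # = 0.7
})

test_that("at full occupancy the volume-weighted mean is the arithmetic mean", {
  dims <- c(4, 10, 15)
  vs <- c(100, 100, 250)
  sel <- array(FALSE, dims)
  sel[1:2, 1:5, 1:15] <- TRUE  # three full cubes along x
  d <- array(0L, dims)
  d[1:2, 1:5, 1:5] <- 200L
  d[1:2, 1:5, 6:10] <- 500L
  d[1:2, 1:5, 11:15] <- 800L
  s <- stack2ch(d, d, voxelSize = vs)
  g <- voxelFeatures(voxelize(roiFromMask(sel), s), s, calib0)
  agg <- aggregateVoxels(g, s, calib0)
  expect_equal(agg$cond, mean(g$cells$cond))
})

test_that("low-intensity thresholds are bimodal-splitting and deterministic", {
  dims <- c(4, 10, 10)
  sel <- array(FALSE, dims); sel[1:2, , ] <- TRUE
  d <- array(0L, dims)
  d[sel] <- rep(c(10L, 1000L), 100)
  s <- stack2ch(d, d)
  rois <- list(roiFromMask(sel))
  t1 <- lowIntensityThreshold(s, rois, "DAPI")
  expect_gt(t1, 10); expect_lt(t1, 1000)
  expect_identical(t1, lowIntensityThreshold(s, rois, "DAPI"))
})

test_that("LID%/LIM% count sub-threshold pixels exactly", {
  dims <- c(2, 10, 10)
  sel <- array(FALSE, dims); sel[1, , ] <- TRUE
  d <- array(0L, dims); m <- array(0L, dims)
  d[1, 1:5, ] <- 100L; d[1, 6:10, ] <- 900L   # exactly half below 500
  m[1, , ] <- 900L
  s <- stack2ch(d, m)
  roi <- roiFromMask(sel)
  ll <- lidLimPercent(s, roi, calib0)
  expect_equal(unname(ll), c(50, 0))
  s2 <- stack2ch(array(0L, dims), array(0L, dims))
  expect_equal(unname(lidLimPercent(s2, roi, calib0)), c(100, 100))
})

test_that("raising sub-threshold MeC pixels above the cut lowers LIM%", {
  pop <- fixturePop()
  rois <- collectRois(pop$truth$labels, 100, FALSE)
  calib <- channelCalibration(pop$stack, rois)
  roi <- rois[[1L]]
  before <- lidLimPercent(pop$stack, roi, calib)["lim_pct"]
  a <- imgData(pop$stack)
  mec <- a[2L, , , ]
  idx <- roiPixels(roi)
  low <- idx[mec[idx] < calib$tMec]
  mec[low[seq_len(length(low) %/% 2)]] <- as.integer(calib$tMec + 100)
  a[2L, , , ] <- mec
  s2 <- ImageStack(a, voxelSize = voxelSize(pop$stack),
                   channelNames = channelNames(pop$stack))
  after <- lidLimPercent(s2, roi, calib)["lim_pct"]
  expect_lt(after, before)
})

test_that("with one shell the radial profile equals the aggregate", {
  pop <- fixturePop()
  roi <- collectRois(pop$truth$labels, 100, FALSE)[[1L]]
  calib <- channelCalibration(pop$stack, list(roi))
  g <- voxelFeatures(voxelize(roi, pop$stack), pop$stack, calib)
  prof <- radialProfile(g, nShells = 1L)
  agg <- aggregateVoxels(g, pop$stack, calib)
  expect_equal(prof$cond, agg$cond)
  expect_equal(prof$meth, agg$meth)
  expect_equal(prof$assoc, agg$assoc)
})

test_that("a rim-bright ball shows monotonically increasing cond with r and a
          uniform ball stays flat", {
  dims <- c(24, 28, 28)
  vs <- c(250, 250, 250)
  centre <- c(12, 14, 14)
  sel <- ballMask(dims, centre, 10)
  z <- slice.index(sel, 1L); y <- slice.index(sel, 2L)
  x <- slice.index(sel, 3L)
  dist <- sqrt((z - centre[1])^2 + (y - centre[2])^2 + (x - centre[3])^2)
  rim <- array(0L, dims)
  rim[sel] <- as.integer(600 + 2800 * (dist[sel] / 10))
  sRim <- stack2ch(rim, rim, voxelSize = vs)
  roi <- roiFromMask(sel)
  calib <- list(tDapi = 1500, tMec = 1500, scaleDapi = 3400,
                scaleMec = 3400)
  pRim <- radialProfile(voxelFeatures(voxelize(roi, sRim), sRim, calib), 4L)
  cr <- pRim$cond[!is.na(pRim$cond)]
  expect_true(all(diff(cr) > 0))

  flat <- array(0L, dims); flat[sel] <- 1500L
  sFlat <- stack2ch(flat, flat, voxelSize = vs)
  pFlat <- radialProfile(voxelFeatures(voxelize(roi, sFlat), sFlat, calib),
                         4L)
  cf <- pFlat$cond[!is.na(pFlat$cond)]
  expect_lt(max(cf) - min(cf), 1e-12)
})

test_that("profile dispersion matches the two-sample closed form", {
  p1 <- data.frame(shell = 1:3, rMid = c(1, 3, 5) / 6, occ = 10,
                   cond = c(0.2, 0.3, 0.4), meth = c(0.1, 0.2, 0.3),
                   assoc = c(0.8, 0.8, 0.8))
  p2 <- p1
  p2$cond <- p1$cond + 0.1
  disp <- profileDispersion(list(p1, p2))
  condRows <- disp[disp$feature == "cond", ]
  expect_equal(condRows$sd, rep(0.1 / sqrt(2), 3))
  same <- profileDispersion(list(p1, p1))
  expect_true(all(same$sd == 0))
  expect_error(profileDispersion(list(p1)), "at least 2")
})

test_that("features are stable under a global intensity doubling", {
  set.seed(30)
  dims <- c(10, 20, 20)
  sel <- ballMask(dims, c(5, 10, 10), 7)
  d <- array(50L, dims); m <- array(50L, dims)
  d[sel] <- sample(200:1800, sum(sel), replace = TRUE)
  m[sel] <- sample(200:1800, sum(sel), replace = TRUE)
  s1 <- stack2ch(d, m)
  s2 <- stack2ch(d * 2L, m * 2L)
  roi <- roiFromMask(sel)
  c1 <- channelCalibration(s1, list(roi))
  c2 <- channelCalibration(s2, list(roi))
  f1 <- nucleusFeatures(s1, roi, c1)
  f2 <- nucleusFeatures(s2, roi, c2)
  expect_lt(abs(f2$cond - f1$cond) / f1$cond, 0.01)
  expect_lt(abs(f2$meth - f1$meth) / f1$meth, 0.01)
  expect_equal(f2$assoc, f1$assoc)
})
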