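test_that("otsu threshold splits a forced bimodal image", {
  set.seed(3)
  v <- array(100L, c(20, 20, 20))
  hi <- sample(length(v), length(v) %/% 10)
  v[hi] <- 3000L
  thr <- globalThreshold(v, method = "otsu")
  expect_gt(thr, 100)
  expect_lt(thr, 3000)
  expect_identical(v > thr, array(seq_along(v) %in% hi, dim(v)))
})

test_that("otsu is equivariant under exact intensity doubling", {
  set.seed(4)
  v <- array(sample(c(80L, 150L, 1200L, 1500L), 4000, replace = TRUE,
                    prob = c(.45, .45, .05, .05)), c(10, 20, 20))
  m1 <- v > globalThreshold(v, method = "otsu")
  m2 <- (v * 2L) > globalThreshold(v * 2L, method = "otsu")
  expect_identical(m1, m2)
})

test_that("constant images raise a no-foreground error", {
  expect_error(globalThreshold(array(7L, c(4, 4, 4))), "constant")
})

test_that("the envelope refinement stays strictly inside the range and below
          plain otsu on background-dominated fields", {
  pop <- fixturePop()
  dapi <- getChannel(pop$stack, "DAPI")
  t1 <- globalThreshold(dapi, "otsu")
  t2 <- globalThreshold(dapi, "envelope")
  expect_gt(t2, min(dapi))
  expect_lt(t2, max(dapi))
  expect_lt(t2, t1)
})

test_that("a single solid ball yields one seed at its centre", {
  mask <- ballMask(c(24, 32, 32), c(12, 16, 16), 8)
  seeds <- extractSeeds(mask, c(200, 200, 200), expectedRadiusNm = 1600)
  expect_equal(nrow(seeds), 1L)
  expect_true(all(abs(c(seeds$z, seeds$y, seeds$x) - c(12, 16, 16)) <= 1))
})

test_that("two balls fused by a neck yield two seeds and split correctly", {
  dims <- c(24, 32, 56)
  m <- ballMask(dims, c(12, 16, 18), 8) | ballMask(dims, c(12, 16, 38), 8)
  # thin bridging neck along x
  z <- slice.index(array(0, dims), 1L)
  y <- slice.index(array(0, dims), 2L)
  x <- slice.index(array(0, dims), 3L)
  m <- m | ((z - 12)^2 + (y - 16)^2 <= 2^2 & x >= 18 & x <= 38)
  seeds <- extractSeeds(m, c(200, 200, 200), expectedRadiusNm = 1600)
  expect_equal(nrow(seeds), 2L)
  labels <- watershed3D(array(0L, dims), seeds, m, c(200, 200, 200))
  vols <- tabulate(labels[labels > 0])
  ballVol <- 4 / 3 * pi * 8^3
  expect_true(all(abs(vols - ballVol) / ballVol < 0.15))
  # label partition covers the mask exactly
  expect_equal(sum(vols), sum(m))
})

test_that("an empty mask yields no seeds", {
  expect_equal(nrow(extractSeeds(array(FALSE, c(4, 4, 4)),
                                 c(120, 120, 250))), 0L)
})

test_that("with one seed the watershed reproduces the mask", {
  mask <- ballMask(c(16, 20, 20), c(8, 10, 10), 6)
  seeds <- extractSeeds(mask, c(200, 200, 200), expectedRadiusNm = 1200)
  labels <- watershed3D(array(0L, dim(mask)), seeds, mask, c(200, 200, 200))
  expect_identical(labels > 0, mask)
  expect_true(all(labels[mask] == 1L))
})

test_that("watershed labelling is deterministic", {
  pop <- fixturePop()
  dapi <- getChannel(pop$stack, "DAPI")
  thr <- globalThreshold(dapi, "envelope")
  mask <- dapi > thr
  seeds <- extractSeeds(mask, voxelSize(pop$stack), expectedRadiusNm = 1500)
  l1 <- watershed3D(dapi, seeds, mask, voxelSize(pop$stack))
  l2 <- watershed3D(dapi, seeds, mask, voxelSize(pop$stack))
  expect_identical(l1, l2)
})

test_that("a seed outside the mask is rejected", {
  mask <- ballMask(c(10, 10, 10), c(5, 5, 5), 3)
  bad <- data.frame(z = 1, y = 1, x = 1,
                    idx = 1L, dist = 0)
  expect_error(watershed3D(array(0L, dim(mask)), bad, mask,
                           c(120, 120, 250)),
               "outside")
})

test_that("ROI filters drop border-touching and undersized labels", {
  labels <- array(0L, c(8, 12, 12))
  labels[3:6, 4:8, 1:4] <- 1L    # touches the x = 1 face
  labels[3:6, 4:8, 7:10] <- 2L   # interior
  labels[2, 2, 6] <- 3L          # 1 px
  rois <- collectRois(labels, minVolumePx = 5L, excludeBorder = TRUE)
  expect_equal(vapply(rois, roiLabel, 1L), 2L)
  expect_equal(attr(rois, "excluded"), c(small = 1L, border = 1L))
  # without filtering, the label partition conserves pixel counts
  all3 <- collectRois(labels, minVolumePx = 0L, excludeBorder = FALSE)
  expect_equal(sum(vapply(all3, roiVolume, 1L)), sum(labels > 0))
})

test_that("ROI invariants hold on phantom segmentations", {
  pop <- fixturePop()
  seg <- segmentNuclei(pop$stack, expectedRadiusNm = 1500,
                       minVolumePx = 200)
  for (r in seg$rois) {
    expect_equal(roiVolume(r), length(roiPixels(r)))
    expect_true(all(roiCentroid(r) >= r@bbox[1L, ] &
                    roiCentroid(r) <= r@bbox[2L, ]))
  }
  expect_false(any(duplicated(vapply(seg$rois, roiLabel, 1L))))
})

test_that("a default-noise phantom of 10 nuclei is counted correctly", {
  pop <- suppressMessages(generatePopulation(10, smallSpec(),
                                             c(24, 240, 240), seed = 11))
  seg <- segmentNuclei(pop$stack, expectedRadiusNm = 1500,
                       minVolumePx = 200)
  expect_lte(abs(length(seg$rois) - 10L), 1L)  # count error <= 10%
})
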