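test_that("degenerate ROIs give single- and two-bin histograms", {
  d <- array(1000L, c(2, 4, 4))
  m <- array(2000L, c(2, 4, 4))
  # half the pixels carry a second intensity pair
  sel <- slice.index(d, 3L) > 2
  d2 <- d; m2 <- m
  d2[sel] <- 3000L
  m2[sel] <- 500L
  roi <- roiFromMask(array(TRUE, dim(d)))

  s1 <- stack2ch(d, m)
  e1 <- makeBinEdges(s1, list(roi), nBins = 8L)
  h1 <- codHist(jointHistogram(s1, roi, e1))
  expect_equal(sum(h1 > 0), 1L)
  expect_equal(max(h1), 1)

  s2 <- stack2ch(d2, m2)
  e2 <- makeBinEdges(s2, list(roi), nBins = 8L)
  h2 <- codHist(jointHistogram(s2, roi, e2))
  expect_equal(sort(h2[h2 > 0]), c(0.5, 0.5))
  expect_equal(attr(h2, "counts"), roiVolume(roi))
  expect_equal(sum(h2), 1)
})

test_that("histogram mass equals the ROI volume before normalisation", {
  pop <- fixturePop()
  rois <- collectRois(pop$truth$labels, minVolumePx = 100,
                      excludeBorder = FALSE)
  edges <- makeBinEdges(pop$stack, rois)
  for (r in rois[1:3]) {
    cd <- jointHistogram(pop$stack, r, edges)
    expect_equal(attr(codHist(cd), "counts"), roiVolume(r))
  }
})

test_that("K-L divergence is zero on identity and matches the closed form", {
  p <- c(1, 0)
  expect_equal(klDivergence(p, p), 0)
  # p = (1,0) vs q = (.5,.5): 1 * log2(1/0.5) = 1 bit as epsilon -> 0
  expect_equal(klDivergence(c(1, 0), c(0.5, 0.5), epsilon = 1e-12), 1,
               tolerance = 1e-6)
})

test_that("K-L divergence is non-negative on random histogram pairs", {
  set.seed(12)
  for (i in 1:50) {
    p <- randHist(16, runif)
    q <- randHist(16, runif)
    expect_gte(klDivergence(p, q), -1e-12)
  }
})

test_that("mismatched binning is rejected", {
  e1 <- list(dapi = 0:8, mec = 0:8)
  e2 <- list(dapi = 0:8 * 2, mec = 0:8)
  h <- matrix(1 / 64, 8, 8)
  p <- new("Codistribution", hist = h, binEdges = e1)
  q <- new("Codistribution", hist = h, binEdges = e2)
  expect_error(klDivergence(p, q), "bin edges")
  expect_error(klDivergence(c(1, 0), c(0.5, 0.5, 0)), "binning")
})

test_that("the population reference is the renormalised mean histogram", {
  e <- list(dapi = 0:4, mec = 0:4)
  mk <- function(h) new("Codistribution", hist = h, binEdges = e)
  h1 <- matrix(0, 4, 4); h1[1, 1] <- 1
  h2 <- matrix(0, 4, 4); h2[4, 4] <- 1
  ref <- populationReference(list(mk(h1), mk(h2)))
  expect_equal(codHist(ref)[1, 1], 0.5)
  expect_equal(codHist(ref)[4, 4], 0.5)
  same <- populationReference(list(mk(h1), mk(h1), mk(h1)))
  expect_equal(codHist(same), h1, ignore_attr = TRUE)
  expect_error(populationReference(list(mk(h1))), "at least 2")
  set.seed(5)
  cods <- lapply(1:6, function(i) mk(randHist(4, runif)))
  expect_equal(sum(codHist(populationReference(cods))), 1)
})

test_that("leave-one-out references stay within 2/n of the full mean", {
  set.seed(8)
  e <- list(dapi = 0:16, mec = 0:16)
  cods <- lapply(1:8, function(i)
    new("Codistribution", hist = randHist(16, runif), binEdges = e))
  full <- codHist(populationReference(cods))
  n <- length(cods)
  for (i in seq_len(n)) {
    loo <- codHist(populationReference(cods[-i]))
    expect_lte(max(abs(loo - full)), 2 / n)
  }
})

test_that("outlier flagging applies a strict > 4.5 cut by default", {
  e <- list(dapi = 0:2, mec = 0:2)
  mk <- function(k) {
    cd <- new("Codistribution", hist = matrix(0.25, 2, 2), binEdges = e)
    cd@kld <- k
    cd
  }
  fl <- flagOutliers(list(mk(0), mk(4.5), mk(5.0), mk(0.2)))
  expect_equal(fl$dissimilar, 3L)  # 5.0 > 4.5; 4.5 itself is retained
  expect_equal(fl$kept, c(1L, 2L, 4L))
  expect_equal(fl$fraction, 0.25)
  none <- flagOutliers(list(mk(0), mk(0)))
  expect_length(none$dissimilar, 0L)
  expect_error(flagOutliers(list(mk(NA_real_), mk(0))), "scored")
})

test_that("a planted inverted-texture nucleus dominates the K-L ranking", {
  pop <- suppressMessages(generatePopulation(12, smallSpec(),
                                             c(24, 240, 240), seed = 21))
  out <- suppressMessages(plantOutlier(pop, "inverted-texture", seed = 22))
  rois <- collectRois(out$truth$labels, minVolumePx = 100,
                      excludeBorder = FALSE)
  edges <- makeBinEdges(out$stack, rois)
  cods <- scoreKLD(lapply(rois, function(r)
    jointHistogram(out$stack, r, edges)))
  kld <- vapply(cods, codKLD, 1)
  lab <- vapply(rois, roiLabel, 1L)
  planted <- out$truth$table$label[out$truth$table$outlier]
  expect_equal(lab[which.max(kld)], planted)
  expect_gt(kld[lab == planted], 4.5)
  expect_true(all(kld[lab != planted] < 4.5))
})
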