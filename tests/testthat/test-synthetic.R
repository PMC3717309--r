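test_that("an empty population is all background with an empty truth table", {
  pop <- generatePopulation(0, smallSpec(), c(8, 32, 32), seed = 1)
  expect_equal(nrow(pop$truth$table), 0L)
  expect_true(all(pop$truth$labels == 0L))
  # background plus noise stays far below nuclear intensity
  expect_lt(max(imgData(pop$stack)), 500)
})

test_that("generation is deterministic given the seed", {
  p1 <- suppressMessages(generatePopulation(4, smallSpec(),
                                            c(20, 120, 120), seed = 9))
  p2 <- suppressMessages(generatePopulation(4, smallSpec(),
                                            c(20, 120, 120), seed = 9))
  expect_identical(imgData(p1$stack), imgData(p2$stack))
  expect_identical(p1$truth$labels, p2$truth$labels)
  expect_equal(p1$truth$table, p2$truth$table)
})

test_that("infeasible packing raises a placement error", {
  expect_error(generatePopulation(50, smallSpec(), c(10, 40, 40), seed = 1,
                                  maxTriesPerNucleus = 5L),
               "placement error")
})

test_that("senescent nuclei are larger than proliferating ones", {
  sen <- suppressMessages(generatePopulation(12, smallSpec("senescent"),
                                             c(26, 300, 300), seed = 3))
  pro <- suppressMessages(generatePopulation(12, smallSpec("proliferating"),
                                             c(26, 300, 300), seed = 3))
  expect_gt(mean(sen$truth$table$volumePx), mean(pro$truth$table$volumePx))
})

test_that("raising the generator's mec/cond levels raises measured meth/cond
          monotonically", {
  levels <- c(0.15, 0.40, 0.70)
  meth <- cond <- numeric(3)
  cfg <- defaultConfig(min_volume_px = 100)
  for (i in seq_along(levels)) {
    sp <- smallSpec(mecLevel = levels[i], condLevel = levels[i])
    pop <- suppressMessages(generatePopulation(8, sp, c(24, 220, 220),
                                               seed = 17))
    res <- analyzeStack(pop$stack, cfg, labels = pop$truth$labels)
    cells <- res$cells[!res$cells$outlier_flag, ]
    meth[i] <- mean(cells$meth)
    cond[i] <- mean(cells$cond)
  }
  expect_identical(order(meth), 1:3)  # Spearman rank correlation = 1
  expect_identical(order(cond), 1:3)
})

test_that("noise-free, blur-free phantoms segment to exact truth volumes", {
  sp <- smallSpec(blurSigmaNm = c(0, 0, 0), noiseGaussSd = 0,
                  noisePhotonScale = 0)
  pop <- generatePopulation(4, sp, c(22, 140, 140), seed = 5)
  dapi <- getChannel(pop$stack, "DAPI")
  mask <- dapi > 500  # true threshold: between background and chromatin base
  seeds <- extractSeeds(mask, voxelSize(pop$stack), expectedRadiusNm = 1500)
  labels <- watershed3D(dapi, seeds, mask, voxelSize(pop$stack))
  rois <- collectRois(labels, minVolumePx = 0, excludeBorder = FALSE)
  expect_setequal(vapply(rois, roiVolume, 1L), pop$truth$table$volumePx)
})

test_that("mitotic-compact outliers are smaller and brighter in DAPI", {
  pop <- fixturePop()
  out <- suppressMessages(plantOutlier(pop, "mitotic-compact", seed = 2))
  tab <- out$truth$table
  planted <- tab[tab$outlier, ]
  expect_equal(nrow(planted), 1L)
  expect_lt(planted$volumePx, mean(tab$volumePx[!tab$outlier]))
  dapi <- getChannel(out$stack, "DAPI")
  meanD <- vapply(tab$label, function(l)
    mean(dapi[out$truth$labels == l]), numeric(1))
  expect_gt(meanD[tab$outlier], mean(meanD[!tab$outlier]))
})

test_that("the same seed plants the same nucleus", {
  pop <- fixturePop()
  o1 <- suppressMessages(plantOutlier(pop, "inverted-texture", seed = 4))
  o2 <- suppressMessages(plantOutlier(pop, "inverted-texture", seed = 4))
  expect_identical(which(o1$truth$table$outlier),
                   which(o2$truth$table$outlier))
  expect_identical(imgData(o1$stack), imgData(o2$stack))
})
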