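test_that("nucleus detection recovers the generated count and filters size", {
  cfg <- imageSimConfig(nCells = 10, fracFilamented = 0.5, seed = 4)
  im <- generateCellImage(cfg)
  lab <- detectNuclei(nuclearChannel(im), reporterChannel(im))
  expect_equal(max(lab), 10)
  expect_setequal(unique(as.integer(lab[lab > 0])), 1:10)

  blank <- matrix(0.2, 64, 64)
  expect_equal(max(detectNuclei(blank, blank)), 0)

  # one tiny nucleus below the area filter
  nuc <- matrix(0, 64, 64); nuc[30:31, 30:31] <- 1
  sc <- segmentationConfig(minNucleusArea = 200)
  expect_equal(max(detectNuclei(nuc, nuc * 0, sc)), 0)

  expect_error(detectNuclei(matrix(0, 4, 4), matrix(0, 5, 5)), "shape")
})

test_that("nucleus count matches ground truth across seeds", {
  # recovery property at default noise: exact count in every probed field
  hits <- 0L; n <- 50L
  for (s in seq_len(n)) {
    cfg <- imageSimConfig(nCells = 8, width = 300L, height = 300L,
                          fracFilamented = (s %% 5) / 4, seed = 1000 + s)
    im <- generateCellImage(cfg)
    lab <- detectNuclei(nuclearChannel(im), reporterChannel(im))
    if (max(lab) == 8) hits <- hits + 1L
  }
  expect_gte(hits / n, 0.99)
})

test_that("cytoplasm expansion is radius-limited nearest-seed growth", {
  sc <- segmentationConfig(cytoplasmExpandRadius = 6)
  lab <- matrix(0L, 81, 81); lab[41, 41] <- 1L
  reg <- expandCytoplasm(lab, sc, pixelSize = 1)
  cyto <- cytoplasmLabels(reg)
  idx <- which(cyto == 1, arr.ind = TRUE)
  d <- sqrt((idx[, 1] - 41)^2 + (idx[, 2] - 41)^2)
  expect_lte(max(d), 6 + 1)        # annulus outer radius ~ r
  expect_false(cyto[41, 41] == 1)  # nucleus pixel excluded
  expect_gt(nrow(idx), pi * 5^2 - 30)

  # two nuclei: masks disjoint, boundary pixels nearer own seed
  lab2 <- matrix(0L, 61, 121); lab2[31, 31] <- 1L; lab2[31, 91] <- 2L
  reg2 <- expandCytoplasm(lab2, segmentationConfig(cytoplasmExpandRadius = 40),
                          pixelSize = 1)
  cy <- cytoplasmLabels(reg2)
  expect_equal(sum(cy == 1 & cy == 2), 0)
  i1 <- which(cy == 1, arr.ind = TRUE); i2 <- which(cy == 2, arr.ind = TRUE)
  d1own <- sqrt((i1[, 1] - 31)^2 + (i1[, 2] - 31)^2)
  d1oth <- sqrt((i1[, 1] - 31)^2 + (i1[, 2] - 91)^2)
  expect_true(all(d1own <= d1oth + 1e-9))

  # zero nuclei
  reg0 <- expandCytoplasm(matrix(0L, 10, 10))
  expect_equal(nCells(reg0), 0)
})

test_that("reporter enhancement is bounded and rescues dim filaments", {
  set.seed(42)
  img <- matrix(runif(64 * 64, 0, 7), 64, 64)
  enh <- enhanceReporter(img, segmentationConfig(claheKernel = 16L))
  expect_gte(min(enh), 0); expect_lte(max(enh), 1)

  # constant image: returned unchanged after rescale-to-zero
  flat <- matrix(2, 32, 32)
  expect_equal(enhanceReporter(flat), matrix(0, 32, 32))

  # dim filament (10% of full scale above local background) under an
  # illumination gradient: invisible to a global threshold before
  # enhancement, >= 95% recovered after CLAHE
  set.seed(42)
  n <- 256
  grad <- matrix(rep(seq(0.2, 0.7, length.out = n), each = n), n, n)
  img <- grad + matrix(rnorm(n^2, 0, 0.005), n, n)
  fil <- cbind(60:180, round(60 + 15 * sin((60:180) / 18)))
  filpx <- integer(0)
  for (k in seq_len(nrow(fil))) for (dr in -1:1) for (dc in -1:1) {
    r <- fil[k, 1] + dr; cc <- fil[k, 2] + dc
    img[r, cc] <- grad[r, cc] + 0.1
    filpx <- c(filpx, (cc - 1) * n + r)
  }
  filpx <- unique(filpx)
  sc <- segmentationConfig(claheKernel = 64L)
  pre <- binarizeObjects(CBSfilament:::percentileRescale(img, c(1, 99.5)), sc)
  expect_lt(mean(pre[filpx]), 0.5)
  post <- binarizeObjects(enhanceReporter(img, sc), sc)
  expect_gte(mean(post[filpx]), 0.95)
})

test_that("binarisation separates bimodal images and rejects degenerate ones", {
  img <- matrix(0.1, 32, 32); img[10:14, 20:24] <- 0.9
  m <- binarizeObjects(img)
  expect_identical(m, img > 0.5)

  expect_equal(sum(binarizeObjects(matrix(0.3, 16, 16))), 0)
  expect_error(binarizeObjects(matrix(2, 4, 4)), "\\[0, 1\\]")
})

test_that("binarised objects match the generator's raster (pixelwise F1)", {
  cfg <- imageSimConfig(fracFilamented = 0.5, seed = 6)  # default density
  im <- generateCellImage(cfg)
  mask <- binarizeObjects(enhanceReporter(reporterChannel(im)))
  truth <- truthMask(im) > 0
  tp <- sum(mask & truth)
  f1 <- 2 * tp / (2 * tp + sum(mask & !truth) + sum(!mask & truth))
  expect_gte(f1, 0.9)
})

test_that("object extraction respects cytoplasm territory and size filter", {
  # three puncta in one cell
  lab <- matrix(0L, 64, 64); lab[32, 32] <- 1L
  reg <- expandCytoplasm(lab, segmentationConfig(cytoplasmExpandRadius = 20),
                         pixelSize = 1)
  mask <- matrix(FALSE, 64, 64)
  mask[20:22, 30:32] <- TRUE; mask[40:42, 30:32] <- TRUE
  mask[30:32, 44:46] <- TRUE
  ob <- extractObjects(mask, reg)
  expect_equal(nrow(ob$table), 3)
  expect_true(all(ob$table$cell_id == 1))
  expect_equal(sort(ob$table$area_px), c(9, 9, 9))

  # object entirely outside any cytoplasm is not reported
  mask2 <- matrix(FALSE, 64, 64); mask2[2:4, 2:4] <- TRUE
  expect_equal(nrow(extractObjects(mask2, reg)$table), 0)

  # 1-px specks dropped at minObjectArea = 4
  mask3 <- matrix(FALSE, 64, 64); mask3[32, 20] <- TRUE
  expect_equal(nrow(extractObjects(mask3, reg,
                                   segmentationConfig(minObjectArea = 4))$table), 0)

  # pixel conservation: extracted pixels never exceed the mask
  ob4 <- extractObjects(mask, reg)
  expect_lte(sum(ob4$table$area_px), sum(mask))
})

test_that("segmentation is deterministic for identical inputs", {
  cfg <- imageSimConfig(nCells = 6, width = 256L, height = 256L, seed = 8)
  im <- generateCellImage(cfg)
  a <- classifyImage(im)
  b <- classifyImage(im)
  expect_identical(a$cells, b$cells)
  expect_identical(a$objects, b$objects)
})
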