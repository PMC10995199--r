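test_that("label counts follow round-half-up of n * fraction exactly", {
  cfg <- imageSimConfig(nCells = 10, fracFilamented = 1, seed = 1)
  im <- generateCellImage(cfg)
  expect_equal(nrow(groundTruth(im)), 10)
  expect_true(all(groundTruth(im)$true_class == "filamented"))

  cfg <- imageSimConfig(nCells = 200, width = 1400L, height = 1400L,
                        fracFilamented = 0.65, seed = 7)
  labs <- groundTruth(generateCellImage(cfg))
  expect_equal(sum(labs$true_class == "filamented"), 130)
  expect_equal(labs$cell_id, 1:200)

  # round-half-up, not banker's rounding
  cfg <- imageSimConfig(nCells = 10, fracFilamented = 0.25, seed = 2)
  expect_equal(sum(groundTruth(generateCellImage(cfg))$true_class ==
                     "filamented"), 3)
})

test_that("empty image carries background and noise only", {
  cfg <- imageSimConfig(nCells = 0, seed = 3, noiseSd = 0.02)
  im <- generateCellImage(cfg)
  expect_equal(nrow(groundTruth(im)), 0)
  expect_equal(sum(truthMask(im)), 0)
  expect_lt(max(abs(nuclearChannel(im) - 0.05)), 0.15)
})

test_that("identical configs give bit-identical images and labels", {
  cfg <- imageSimConfig(nCells = 12, fracFilamented = 0.5, seed = 9)
  a <- generateCellImage(cfg, index = 2L)
  b <- generateCellImage(cfg, index = 2L)
  expect_identical(nuclearChannel(a), nuclearChannel(b))
  expect_identical(reporterChannel(a), reporterChannel(b))
  expect_identical(groundTruth(a), groundTruth(b))
  # different image index => different stream
  c_ <- generateCellImage(cfg, index = 3L)
  expect_false(identical(reporterChannel(a), reporterChannel(c_)))
})

test_that("invalid configurations are rejected and density errors name it", {
  expect_error(imageSimConfig(fracFilamented = 1.2), "fracFilamented")
  expect_error(imageSimConfig(pixelSize = 0), "pixelSize")
  cfg <- imageSimConfig(nCells = 400, width = 128L, height = 128L)
  expect_error(generateCellImage(cfg), "density")
})

test_that("toy protomer is centred, distinct-distance and reproducible", {
  p <- makeToyProtomer(3, 5, seed = 1)
  xyz <- atomCoords(p)
  expect_equal(nrow(xyz), 3)
  d <- dist(xyz)
  expect_gt(min(abs(diff(sort(d)))), 0)
  expect_lt(max(abs(colMeans(xyz))), 1e-9)

  a <- makeToyProtomer(50, 10, seed = 2)
  b <- makeToyProtomer(50, 10, seed = 2)
  expect_identical(atomCoords(a), atomCoords(b))
  expect_error(makeToyProtomer(2), "3")
})

test_that("assay generator honours the noise contract and model identities", {
  # Hill midpoint: response at K_act is exactly midway
  cfg <- assaySimConfig("hill_activation",
                        list(vBasal = 4, vMax = 9, Kact = 30, nHill = 3),
                        design = c(1, 30, 100), noiseSd = 0, seed = 1)
  d <- generateAssayDataset(cfg)
  expect_equal(d$response[d$x == 30], (4 + 9) / 2)

  # Michaelis-Menten saturation at 1000 Km within 0.1% of Vmax
  cfg <- assaySimConfig("michaelis_menten", list(Vmax = 10, Km = 20),
                        design = c(1, 10, 20000), noiseSd = 0, seed = 1)
  d <- generateAssayDataset(cfg)
  expect_lt(abs(d$response[d$x == 20000] - 10) / 10, 0.001)

  # noiseless thermal data round-trips through the fitter at Tm = 49.5
  Tg <- seq(38, 60, by = 2)
  cfg <- assaySimConfig("thermal_sigmoid",
                        list(low = 1, high = 3, Tm = 49.5, slope = 1.5),
                        design = Tg, noiseSd = 0, seed = 1)
  d <- generateAssayDataset(cfg)
  fit <- fitThermalSigmoid(d$x, d$response)
  expect_equal(fit$Tm, 49.5, tolerance = 1e-6)

  # replicates are i.i.d., noiseless responses identical across them
  cfg <- assaySimConfig("michaelis_menten", list(Vmax = 10, Km = 20),
                        design = c(5, 10), noiseSd = 0, replicates = 3,
                        seed = 1)
  d <- generateAssayDataset(cfg)
  expect_equal(as.numeric(tapply(d$response, d$x, function(z) diff(range(z)))),
               c(0, 0))

  expect_error(assaySimConfig("logistic_mm", list(), 1:3), "supported")
})
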