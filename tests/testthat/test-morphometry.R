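test_that("box-count dimension hits the line/square/point oracles", {
  cfg <- morphometryConfig(boxSizes = c(2, 4, 8, 16, 32))
  expect_equal(boxCountDimension(cbind(5L, 5L), cfg)$D, 0)

  lineD <- boxCountDimension(coordsLine(128), cfg)
  expect_equal(lineD$counts$N, ceiling(128 / c(2, 4, 8, 16, 32)))
  expect_lt(abs(lineD$D - 1), 0.05)

  sqD <- boxCountDimension(coordsSquare(128), cfg)
  expect_equal(sqD$counts$N, ceiling(128 / c(2, 4, 8, 16, 32))^2)
  expect_lt(abs(sqD$D - 2), 0.05)

  expect_error(boxCountDimension(matrix(FALSE, 4, 4)), "empty")
})

test_that("box counter matches the brute-force oracle on random masks", {
  set.seed(7)
  cfg <- morphometryConfig(boxSizes = c(2, 3, 4, 6, 8))
  for (i in 1:100) {
    n <- sample(3:40, 1)
    coords <- unique(cbind(sample.int(30, n, replace = TRUE),
                           sample.int(30, n, replace = TRUE)))
    got <- boxCountDimension(coords, cfg)
    expect_identical(got$counts$N, as.numeric(bruteBoxCounts(coords,
                                                             cfg@boxSizes)))
    expect_equal(got$D, bruteBoxDimension(coords, cfg@boxSizes),
                 tolerance = 1e-12)
  }
})

test_that("D is invariant to whole-pixel translation", {
  set.seed(11)
  cfg <- morphometryConfig()
  for (i in 1:20) {
    coords <- unique(cbind(sample.int(40, 25, replace = TRUE),
                           sample.int(40, 25, replace = TRUE)))
    shifted <- sweep(coords, 2, c(sample.int(90, 1), sample.int(90, 1)), "+")
    expect_equal(boxCountDimension(coords, cfg)$D,
                 boxCountDimension(shifted, cfg)$D)
  }
})

test_that("perimeter equals the boundary-walk oracle and scales linearly", {
  expect_equal(objectPerimeter(cbind(1L, 1L), 0.3), 1.2)
  expect_equal(objectPerimeter(coordsSquare(10), 0.3), 12)

  set.seed(13)
  for (i in 1:20) {
    coords <- unique(cbind(sample.int(15, 20, replace = TRUE),
                           sample.int(15, 20, replace = TRUE)))
    expect_equal(objectPerimeter(coords, 1), bruteBoundarySteps(coords))
  }

  # doubling the shape in pixels doubles the perimeter
  sq <- coordsSquare(7)
  sq2 <- unique(rbind(
    cbind(2 * sq[, 1], 2 * sq[, 2]), cbind(2 * sq[, 1] - 1, 2 * sq[, 2]),
    cbind(2 * sq[, 1], 2 * sq[, 2] - 1),
    cbind(2 * sq[, 1] - 1, 2 * sq[, 2] - 1)))
  expect_equal(objectPerimeter(sq2, 1), 2 * objectPerimeter(sq, 1))

  expect_error(objectPerimeter(matrix(FALSE, 3, 3)), "empty")
})

test_that("majority-vote classification follows the met-or-exceeded rule", {
  cfg <- morphometryConfig()
  expect_equal(classifyCellByD(c(0.9, 0.8, 0.3), cfg), "filamented")
  expect_equal(classifyCellByD(c(0.5, 0.9), cfg), "tie")
  expect_equal(classifyCellByD(0.7, cfg), "filamented")  # threshold met
  expect_equal(classifyCellByD(numeric(0), cfg), "tie")

  expect_equal(classifyCellByPerimeter(c(12, 15, 3), cfg), "longer")
  expect_equal(classifyCellByPerimeter(c(3, 4), cfg), "shorter")
  expect_equal(classifyCellByPerimeter(c(12, 3), cfg), "tie")
  expect_equal(classifyCellByPerimeter(c(10, 3), cfg), "tie")  # 10 um meets
})

test_that("drawn filaments score high D / long perimeter, puncta low/short", {
  cfg <- imageSimConfig(nCells = 9, width = 300L, height = 300L,
                        fracFilamented = 1, seed = 21)
  fil <- classifyImage(generateCellImage(cfg))$objects
  cfg@fracFilamented <- 0
  cfg@seed <- 22L
  pun <- classifyImage(generateCellImage(cfg))$objects
  expect_gt(median(fil$D), 0.7)
  expect_lt(median(pun$D), 0.7)
  expect_gt(median(fil$perimeter_um), 10)
  expect_lt(median(pun$perimeter_um), 10)
})
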