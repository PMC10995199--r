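test_that("helical building satisfies identity and 360-degree closure", {
  p <- makeToyProtomer(15, 8, seed = 1)
  one <- applyHelicalSymmetry(p, helicalParams(-108, 51), 1)
  expect_equal(atomCoords(one), atomCoords(p))

  # twist -120 x 3 units: unit 3 is unit 0 rotated -360 (identity) + 150 A
  fil <- applyHelicalSymmetry(p, helicalParams(-120, 50), 4)
  u0 <- atomCoords(fil)[fil@unit == 0, ]
  u3 <- atomCoords(fil)[fil@unit == 3, ]
  expect_equal(u3, sweep(u0, 2, c(0, 0, 150), "+"), tolerance = 1e-9)

  # D1 doubles the atom count per unit
  d1 <- applyHelicalSymmetry(p, helicalParams(-108, 51, "D1"), 2)
  expect_equal(nrow(atomCoords(d1)), 4 * nrow(atomCoords(p)))
})

test_that("screw decomposition recovers pure and mixed transforms", {
  A <- atomCoords(makeToyProtomer(20, 10, seed = 3))
  idt <- screwDecompose(A, A)
  expect_equal(idt@angle, 0, tolerance = 1e-9)
  expect_equal(idt@translation, 0, tolerance = 1e-9)
  expect_equal(idt@rmsd, 0, tolerance = 1e-9)

  tr <- screwDecompose(A, sweep(A, 2, c(0, 0, 51), "+"))
  expect_equal(tr@angle, 0, tolerance = 1e-9)
  expect_equal(tr@translation, 51, tolerance = 1e-9)

  B <- sweep(A %*% t(rotZdeg(-178.6)), 2, c(0, 0, 46.7), "+")
  s <- screwDecompose(A, B)
  expect_equal(s@angle, -178.6, tolerance = 1e-6)
  expect_equal(s@translation, 46.7, tolerance = 1e-6)
  expect_equal(abs(s@axis[3]), 1, tolerance = 1e-9)

  expect_error(screwDecompose(cbind(0:4, 0, 0), cbind(0:4, 0, 0)),
               "collinear|degenerate")
})

test_that("helical parameters round-trip exactly and under noise", {
  p <- makeToyProtomer(25, 10, seed = 5)
  fil <- applyHelicalSymmetry(p, helicalParams(-108, 51), 5)
  r <- recoverHelicalParams(fil)
  expect_equal(twist(r$params), -108, tolerance = 1e-9)
  expect_equal(rise(r$params), 51, tolerance = 1e-9)

  # perturbed coordinates: recovery within +/- 0.5 deg and 0.5 A
  for (s in 1:20) {
    set.seed(s)
    noisy <- initialize(fil, coords = atomCoords(fil) +
                          matrix(rnorm(length(atomCoords(fil)), 0, 0.5),
                                 ncol = 3))
    rn <- recoverHelicalParams(noisy)
    expect_lt(abs(twist(rn$params) - (-108)), 0.5)
    expect_lt(abs(rise(rn$params) - 51), 0.5)
  }
})

test_that("composition of k twists equals a single composed operator", {
  p <- makeToyProtomer(18, 9, seed = 7)
  fil <- applyHelicalSymmetry(p, helicalParams(-108, 51), 6)
  for (k in 2:4) {
    r <- recoverHelicalParams(fil, unitPairs = cbind(0, k))
    expected <- ((-108 * k + 180) %% 360) - 180
    if (expected == -180) expected <- 180
    expect_equal(twist(r$params), expected, tolerance = 1e-8)
    expect_equal(rise(r$params), 51 * k, tolerance = 1e-8)
  }
})

test_that("negating twist mirrors the filament", {
  p <- makeToyProtomer(12, 6, seed = 9)
  left <- applyHelicalSymmetry(p, helicalParams(-108, 51), 4)
  mirrorP <- structureModel(atomCoords(p) %*% diag(c(-1, 1, 1)))
  right <- applyHelicalSymmetry(mirrorP, helicalParams(108, 51), 4)
  expect_equal(atomCoords(left) %*% diag(c(-1, 1, 1)), atomCoords(right),
               tolerance = 1e-9)
})

test_that("dimers per turn follows 360/|twist| with round-half-up", {
  b <- dimersPerTurn(-108)
  expect_equal(b$unitsPerTurn, 10 / 3, tolerance = 1e-3)
  expect_equal(b$nearestInteger, 3L)

  a <- dimersPerTurn(-178.6)
  expect_equal(a$unitsPerTurn, 2.016, tolerance = 1e-3)
  expect_equal(a$nearestInteger, 2L)

  expect_equal(dimersPerTurn(-120)$unitsPerTurn, 3)
  expect_equal(dimersPerTurn(-144)$nearestInteger, 3L)  # 2.5 rounds up
  expect_error(dimersPerTurn(0), "turn")
})

test_that("D1 filaments and unit selections recover parameters", {
  p <- makeToyProtomer(15, 8, seed = 11)
  fil <- applyHelicalSymmetry(p, helicalParams(-178.6, 46.7, "D1"), 4)
  r <- recoverHelicalParams(fil)
  expect_equal(twist(r$params), -178.6, tolerance = 1e-6)
  expect_equal(rise(r$params), 46.7, tolerance = 1e-6)
  expect_lt(r$twistSpread, 1e-6)

  # inconsistent atom counts across units are refused
  bad <- initialize(fil, unit = c(fil@unit[-1], 99L))
  expect_error(recoverHelicalParams(bad), "atom")
})

test_that("structure models survive a PDB round trip", {
  p <- makeToyProtomer(10, 7, seed = 13)
  fil <- applyHelicalSymmetry(p, helicalParams(-108, 51), 3)
  tmp <- tempfile(fileext = ".pdb")
  writeStructurePDB(fil, tmp)
  back <- readStructure(tmp)
  expect_equal(atomCoords(back), unname(atomCoords(fil)), tolerance = 1e-3)
  back <- assignUnits(back, list("A", "B", "C"))
  r <- recoverHelicalParams(back)
  expect_equal(twist(r$params), -108, tolerance = 1e-3)
})
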