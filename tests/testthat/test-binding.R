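test_that("H2S calibration inverts its own line and tolerates noise", {
  conc <- c(0, 5, 10, 20, 40)
  rate <- 3 + 0.8 * conc
  cal <- calibrateH2S(conc, rate)
  expect_equal(cal$slope, 0.8, tolerance = 1e-12)
  expect_equal(cal$intercept, 3, tolerance = 1e-12)
  expect_equal(cal$convert(3), 0, tolerance = 1e-12)
  expect_equal(cal$convert(rate), conc, tolerance = 1e-12)

  set.seed(31)
  noisy <- rate + rnorm(5, 0, 0.05 * max(rate))
  expect_lt(abs(calibrateH2S(conc, noisy)$slope - 0.8) / 0.8, 0.1)

  expect_error(calibrateH2S(c(1, 1, 1), c(1, 2, 3)), "degenerate")
})

test_that("Michaelis-Menten fits recover noiseless truth exactly", {
  S <- c(0.5, 1, 2, 5, 10, 20, 50, 100)
  v <- michaelisMenten(S, 10, 20)
  fit <- fitMichaelisMenten(S, v)
  expect_equal(fit$Vmax, 10, tolerance = 1e-6)
  expect_equal(fit$Km, 20, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-9)
  # definitional midpoint
  expect_equal(michaelisMenten(20, 10, 20), 5)
})

test_that("Km at the homocysteine scale is recovered from noisy data", {
  S <- c(0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 5)
  cfg <- assaySimConfig("michaelis_menten", list(Vmax = 10, Km = 0.3), S,
                        noiseSd = 0.3, replicates = 4, seed = 3)
  d <- generateAssayDataset(cfg)
  fit <- fitMichaelisMenten(d$x, d$response)
  expect_lt(abs(fit$Km - 0.3) / 0.3, 0.15)
})

test_that("Hill activation obeys its limits and midpoint identity", {
  S <- c(0, 2, 5, 10, 30, 90, 300, 1000)
  # n = 1 data: fitted n within 0.05 of 1
  v1 <- hillActivation(S, 5, 10, 30, 1)
  f1 <- fitHillActivation(S, v1)
  expect_lt(abs(f1$nHill - 1), 0.05)

  # midpoint: v(Kact) = (v_basal + v_max)/2 in noiseless data
  v3 <- hillActivation(S, 5, 10, 30, 3)
  f3 <- fitHillActivation(S, v3)
  expect_equal(hillActivation(f3$Kact, f3$vBasal, f3$vMax, f3$Kact,
                              f3$nHill),
               (f3$vBasal + f3$vMax) / 2, tolerance = 1e-9)
  expect_lt(f3$rss, 1e-9)

  # Hill n = 1 with zero basal reduces to Michaelis-Menten identically
  expect_equal(hillActivation(S, 0, 10, 30, 1), michaelisMenten(S, 10, 30))
})

test_that("thermal sigmoid is exact when noiseless and refuses a ramp", {
  Tg <- seq(38, 60, by = 2)
  v <- thermalSigmoid(Tg, 1, 3, 49.5, 1.5)
  fit <- fitThermalSigmoid(Tg, v)
  expect_equal(fit$Tm, 49.5, tolerance = 1e-6)
  # inflection identity: v(Tm) = mean of plateaus
  expect_equal(thermalSigmoid(fit$Tm, fit$low, fit$high, fit$Tm, fit$slope),
               (fit$low + fit$high) / 2)
  expect_error(fitThermalSigmoid(Tg, 0.1 * Tg), "inflection")
})

test_that("fitters are locally optimal against the generating truth", {
  # RSS at the fit never exceeds RSS at the generating parameters
  S <- c(0, 2, 5, 10, 30, 90, 300, 1000)
  cfg <- assaySimConfig("hill_activation",
                        list(vBasal = 5, vMax = 10, Kact = 30, nHill = 3),
                        S, noiseSd = 0.2, replicates = 2, seed = 41)
  d <- generateAssayDataset(cfg)
  fit <- fitHillActivation(d$x, d$response)
  rssTruth <- sum((hillActivation(d$x, 5, 10, 30, 3) - d$response)^2)
  expect_lte(fit$rss, rssTruth + 1e-9)
})

test_that("ITC forward model conserves mass and heat", {
  des <- itcExperiment()
  p <- itcTwoSetsParams(c(0.5, 0.5), c(160e-9, 600e-9), c(2, -8))

  # zero enthalpies give zero heats
  p0 <- itcTwoSetsParams(c(0.5, 0.5), c(160e-9, 600e-9), c(0, 0))
  expect_equal(itcModelHeats(p0, des), rep(0, 45))

  # bound + free = total after every injection, to 1e-10 relative
  mb <- CBSfilament:::itcMassBalance(p, des)
  expect_lt(max(abs(mb$free + mb$bound - mb$total) / mb$total), 1e-10)

  # integrated heat equals V0 * M * sum(N dH) at saturation within 1%
  pSat <- itcTwoSetsParams(c(0.5, 0.5), c(1e-9, 5e-9), c(2, -8))
  h <- itcModelHeats(pSat, des)
  V0 <- 200e-6
  # dilution washes macromolecule out as injections proceed; integrate
  # against the per-injection cell content implied by the model
  expected <- -18  # ucal: 200 ul x 30 uM x (0.5*2 + 0.5*(-8)) kcal/mol
  expect_lt(abs(sum(h) - expected) / abs(expected), 0.06)

  # stoichiometric-titration limit: cumulative heat is two straight
  # lines meeting at molar ratio N1
  pStoich <- itcTwoSetsParams(c(0.8, 0), c(1e-12, 1e-3), c(-5, 0))
  hs <- itcModelHeats(pStoich, des)
  expect_lt(max(abs(diff(hs[2:10]))), 0.02 * abs(hs[2]))   # flat before
  expect_lt(max(abs(hs[40:45])), 0.02 * abs(hs[2]))        # zero after
})

test_that("ITC two-sets fit recovers noiseless truth exactly", {
  des <- itcExperiment()
  cfg <- assaySimConfig("itc_two_sets",
                        list(N = c(0.5, 0.5), Kd = c(160e-9, 600e-9),
                             dH = c(2, -8)),
                        des, noiseSd = 0, seed = 1)
  d <- generateAssayDataset(cfg)
  fit <- fitItcTwoSets(itcExperiment(heatsUcal = d$heat_ucal))
  kd <- 1 / fit$params@K
  expect_equal(kd, c(160e-9, 600e-9), tolerance = 1e-3)
  expect_equal(fit$params@N, c(0.5, 0.5), tolerance = 1e-3)
  expect_equal(fit$params@dH, c(2, -8), tolerance = 1e-2)

  # thermodynamic identity dG = dH + (-TdS) holds for every report
  th <- fit$thermo
  expect_equal(th$dG, th$dH + th$minusTdS, tolerance = 1e-12)
  expect_equal(th$dG, -1.98720425864083e-3 * 298.15 * log(fit$params@K),
               tolerance = 1e-12)
})

test_that("SEC calibration and estimation round-trip", {
  std <- data.frame(mw_kda = c(670, 158, 44, 17), ve_ml = c(9, 12, 15, 18))
  # place standards exactly on a log-linear law
  V0 <- 8; Vt <- 22
  kav <- (std$ve_ml - V0) / (Vt - V0)
  std$mw_kda <- 10^(3 - 2.5 * kav)
  cal <- secCalibration(V0, Vt, std)
  # a sample at a standard's Ve returns that standard's MW
  est <- secMwEstimate(cal, std$ve_ml[2])
  expect_equal(est$mw_kda, std$mw_kda[2], tolerance = 1e-9)
  # Kav endpoints
  expect_equal(secMwEstimate(cal, Vt)$kav, 1)
  expect_equal(secMwEstimate(cal, V0 + 1e-12)$kav, 0, tolerance = 1e-9)
  # mid-curve recovery within 1%
  mid <- secMwEstimate(cal, 13.5)
  expect_lt(abs(mid$mw_kda - 10^(3 - 2.5 * (13.5 - V0) / (Vt - V0))) /
              mid$mw_kda, 0.01)
  # void-volume elution is flagged with no estimate
  expect_equal(secMwEstimate(cal, 7.9)$flag, "void_volume")
  expect_true(is.na(secMwEstimate(cal, 7.9)$mw_kda))
  # extrapolation flag
  expect_equal(secMwEstimate(cal, 21)$flag, "extrapolated")
})
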