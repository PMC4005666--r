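# One-site ITC simulation, fitting and thermodynamic derivation.

naturalParams <- function() {
  tab <- tppItcParams()
  deriveThermodynamics(n = tab$n[1L], dH = tab$dH[1L],
                       Ka = 1 / (tab$Kd_uM[1L] * 1e-6), T = 303.15)
}

test_that("zero enthalpy gives exactly zero heats and a molar ratio ramp", {
  p0 <- deriveThermodynamics(n = 1, dH = 0, Ka = 1e6, T = 303.15)
  sim <- simulateTitration(p0)
  expect_true(all(sim$heat == 0))
  expect_true(all(diff(sim$molarRatio) > 0))
  expect_equal(sim$index, seq_along(titrationProtocol()@injections))
})

test_that("noise requires a seed and is reproducible given one", {
  prm <- naturalParams()
  expect_error(simulateTitration(prm, noiseSd = 0.1), "seed")
  s1 <- simulateTitration(prm, noiseSd = 0.1, seed = 7L)
  s2 <- simulateTitration(prm, noiseSd = 0.1, seed = 7L)
  s3 <- simulateTitration(prm, noiseSd = 0.1, seed = 8L)
  expect_identical(s1$heat, s2$heat)
  expect_false(identical(s1$heat, s3$heat))
})

test_that("stoichiometric-limit heats track moles injected for very tight binding", {
  prm <- deriveThermodynamics(n = 1, dH = -20, Ka = 1e12, T = 303.15)
  prot <- titrationProtocol()
  sim <- simulateTitration(prm, prot, displacementCorrection = FALSE)
  cum <- cumsum(sim$heat)      # microjoules
  molesIn <- cumsum(prot@injections) * prot@syringeConc
  expected <- -20 * molesIn * 1e9
  # before saturation and before the displaced volume becomes appreciable
  # (the perfusion bookkeeping expels ~dV/2V0 of the cell content)
  before <- sim$molarRatio < 0.8 & cumsum(prot@injections) <= 25e-6
  expect_gte(sum(before), 3L)
  expect_true(all(abs(cum[before] / expected[before] - 1) < 0.01))
})

test_that("noiseless heats telescope to the final bound heat content", {
  prm <- naturalParams()
  prot <- titrationProtocol()
  sim <- simulateTitration(prm, prot, displacementCorrection = FALSE)
  tot <- kjunction:::.cellTotals(prot, sum(prot@injections))
  Bfinal <- kjunction:::.boundConc(prm@n, prm@Ka, tot$Mt, tot$Xt)
  expect_equal(sum(sim$heat), prot@cellVolume * prm@dH * Bfinal * 1e9,
               tolerance = 1e-9)
})

test_that("the natural-sequence titration is exothermic and decays past n", {
  prm <- naturalParams()
  sim <- simulateTitration(prm)
  expect_true(all(sim$heat < 0))
  past <- sim$heat[sim$molarRatio > prm@n]
  expect_true(all(diff(abs(past)) < 0))
  expect_lt(abs(past[length(past)]), 0.15 * max(abs(sim$heat)))
})

test_that("a noiseless simulate-fit round trip recovers parameters to 1e-4", {
  prm <- naturalParams()
  fit <- fitOneSite(simulateTitration(prm))
  expect_true(fitConverged(fit))
  est <- fitParams(fit)
  expect_lt(abs(est@n / prm@n - 1), 1e-4)
  expect_lt(abs(est@dH / prm@dH - 1), 1e-4)
  expect_lt(abs(est@Kd / prm@Kd - 1), 1e-4)
})

test_that("the fit is covariant under rescaling of the heats", {
  prm <- naturalParams()
  sim <- simulateTitration(prm, noiseSd = 0.05, seed = 31L)
  fit1 <- fitParams(fitOneSite(sim))
  sim1000 <- sim; sim1000$heat <- sim$heat * 1000
  fit2 <- fitParams(fitOneSite(sim1000))
  expect_equal(fit2@dH, fit1@dH * 1000, tolerance = 1e-6)
  expect_equal(fit2@n, fit1@n, tolerance = 1e-6)
  expect_equal(fit2@Ka, fit1@Ka, tolerance = 1e-4)
})

test_that("all-zero heats are flagged non-identifiable, not an error", {
  prot <- titrationProtocol()
  zero <- data.frame(index = seq_along(prot@injections),
                     volume = prot@injections, heat = 0)
  fit <- fitOneSite(zero, prot)
  expect_false(fitConverged(fit))
  expect_match(fitFlags(fit), "non-identifiable")
  expect_equal(fitParams(fit)@dH, 0)
})

test_that("thermodynamic derivation reproduces the tabulated free energies", {
  d1 <- deriveThermodynamics(n = 1.07, dH = -18.29, dS = -30, Ka = 1 / 0.23e-6,
                             T = 303.15)
  expect_equal(d1@dG, -9.20, tolerance = 0.01)
  d2 <- deriveThermodynamics(n = 0.88, dH = -21.18, dS = -41.2, Ka = 1 / 0.55e-6,
                             T = 303.15)
  expect_equal(d2@dG, -8.69, tolerance = 0.01)
  # dH == dG implies zero entropy
  d3 <- deriveThermodynamics(n = 1, dH = -10, dG = -10, Ka = 1e6, T = 303.15)
  expect_equal(d3@dS, 0)
  # Kd is the reciprocal of Ka by construction
  expect_equal(d1@Kd * d1@Ka, 1)
  # the -RT ln Ka audit matches the table on the kcal scale, not the kJ scale
  expect_equal(attr(d1, "dGfromKa_kcal"), -9.20, tolerance = 0.02)
  expect_gt(abs(attr(d1, "dGfromKa") - (-9.20)), 10)
})

test_that("heats survive a CSV round trip", {
  sim <- simulateTitration(naturalParams(), noiseSd = 0.1, seed = 3L)
  tf <- withr::local_tempfile(fileext = ".csv")
  writeHeatsCSV(sim, tf)
  back <- readHeatsCSV(tf)
  expect_equal(back$heat, sim$heat)
  expect_equal(back$volume, sim$volume)
})
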