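test_that("simulation is deterministic in the zero-noise limit and in seed", {
  lh <- gbmLifeHistory(g = 0.1, s = 0, mu0 = 0, xm = 1e6)
  cfg <- simConfig(dt = 0.01, horizon = 2, nPaths = 3L, seed = 5L)
  ens <- simulatePaths(lh, constantPolicy(0), cfg)
  expect_equal(ens@states[1, ], exp(0.1 * ens@ages), tolerance = 1e-3)
  ## halving dt shrinks the deterministic-limit error (exact in log scale,
  ## so check on a natural-scale model)
  sdeN <- controlledSDE(function(x, u, a) 0.1 * x,
                        function(x, u, a) 0 * x, x0 = 1, logScale = FALSE)
  lhN <- lifeHistory(sdeN, mortality(function(x, u, a) 0),
                     fertility("iteroparous", function(x, a) 0),
                     stateSpace(1e-6, 1e6))
  errAt <- function(dt) {
    e <- simulatePaths(lhN, constantPolicy(0),
                       simConfig(dt = dt, horizon = 2, nPaths = 1L,
                                 seed = 1L, storeEvery = 1L))
    abs(e@states[1, length(e@ages)] - exp(0.2))
  }
  e1 <- errAt(0.02); e2 <- errAt(0.01)
  expect_lt(e2, 0.6 * e1)  # O(dt)
  ## bitwise reproducibility from the seed
  lh2 <- twoResourceLifeHistory(refParams(), "semelparous")
  cfg2 <- simConfig(dt = 0.05, horizon = 10, nPaths = 500L, seed = 42L)
  a <- simulatePaths(lh2, constantPolicy(0.6), cfg2)
  b <- simulatePaths(lh2, constantPolicy(0.6), cfg2)
  expect_identical(a@states, b@states)
  expect_identical(a@maturityTimes, b@maturityTimes)
  ## chunked sub-seeding: enlarging nPaths preserves the first chunk
  cfgBig <- simConfig(dt = 0.05, horizon = 10, nPaths = 12000L, seed = 42L)
  cfgSmall <- simConfig(dt = 0.05, horizon = 10, nPaths = 10000L, seed = 42L)
  big <- simulatePaths(lh2, constantPolicy(0.6), cfgBig)
  small <- simulatePaths(lh2, constantPolicy(0.6), cfgSmall)
  expect_identical(big@states[1:10000, ], small@states)
})

test_that("GBM ensemble moments match the closed form", {
  lh <- gbmLifeHistory(g = 0.1, s = 0.2, mu0 = 0, xm = 1e6)
  cfg <- simConfig(dt = 0.01, horizon = 1, nPaths = 20000L, seed = 8L)
  ens <- simulatePaths(lh, constantPolicy(0), cfg)
  xT <- ens@states[, length(ens@ages)]
  se <- sd(xT) / sqrt(length(xT))
  expect_lt(abs(mean(xT) - exp(0.1)), 3 * se)
})

test_that("alive-mass is non-increasing and survivorship weights are exact
          for constant hazard", {
  lh <- twoResourceLifeHistory(refParams(), "semelparous")
  cfg <- simConfig(dt = 0.05, horizon = 20, nPaths = 200L, seed = 3L)
  ens <- simulatePaths(lh, constantPolicy(0.5), cfg)
  expect_true(all(apply(ens@weights, 1, function(w) all(diff(w) <= 1e-12))))
  ## with mu = mu0 constant, the weight of a still-growing path is
  ## exp(-mu0 * age)
  alive <- is.na(ens@maturityTimes)
  if (any(alive)) {
    j <- length(ens@ages)
    expect_equal(ens@weights[alive, j],
                 rep(exp(-0.05 * ens@ages[j]), sum(alive)),
                 tolerance = 1e-10)
  }
})

test_that("Monte-Carlo ERS matches state-independent closed forms", {
  ## iteroparous, b and mu constant: F(tau) = b0 exp(-mu0 tau)
  lh <- gbmLifeHistory(g = 0.1, s = 0.3, mu0 = 0.2,
                       breeding = "iteroparous", b0 = 2, alpha = 1e-12,
                       omega = Inf)
  cfg <- simConfig(dt = 0.02, horizon = 10, nPaths = 4000L, seed = 9L)
  ens <- simulatePaths(lh, constantPolicy(0), cfg)
  ers <- estimateErsMC(ens, lh)
  ref <- 2 * exp(-0.2 * ers@ages)
  dev <- abs(ers@values - ref)
  expect_true(all(dev <= 3 * pmax(ers@se, 1e-12) + 1e-9))
  ## sigma = 0 semelparous: a single atom at ln(xm/x0)/g with weight
  ## q exp(-mu0 T)
  lhS <- gbmLifeHistory(g = 0.2, s = 0, mu0 = 0.1, xm = 2, q = 3)
  cfgS <- simConfig(dt = 0.001, horizon = 10, nPaths = 10L, seed = 2L)
  ensS <- simulatePaths(lhS, constantPolicy(0), cfgS)
  ersS <- estimateErsMC(ensS, lhS)
  Tdet <- log(2) / 0.2
  expect_equal(unique(round(ersS@atomAges, 6)), round(Tdet, 6),
               tolerance = 1e-3)
  expect_equal(sum(ersS@atomWeights), 3 * exp(-0.1 * Tdet),
               tolerance = 1e-3)
})

test_that("Monte-Carlo objective matches exponential and first-passage
          closed forms", {
  ## phi(0) is the estimated R0 by definition
  lh <- gbmLifeHistory(g = 0.25, s = 0.2, mu0 = 0.1, xm = 2, q = 2)
  cfg <- simConfig(dt = 0.02, horizon = 60, nPaths = 20000L, seed = 12L,
                   bridgeCorrection = TRUE)
  ens <- simulatePaths(lh, constantPolicy(0), cfg)
  ers <- estimateErsMC(ens, lh)
  o0 <- estimateObjectiveMC(ens, lh, 0)
  expect_equal(unname(o0["value"]), sum(ers@atomWeights), tolerance = 1e-12)
  ## matches the first-passage transform at two lambdas within 3 SE
  for (lam in c(0, 0.1)) {
    o <- estimateObjectiveMC(ens, lh, lam)
    cf <- singleResourceObjective(0.25, 0.2, 0.1, 1, 2, 2, lam)
    expect_lt(abs(unname(o["value"]) - cf), 3 * unname(o["se"]))
  }
  ## phi-hat is strictly decreasing in lambda
  lams <- seq(-0.05, 0.3, by = 0.05)
  vals <- vapply(lams, function(l)
    unname(estimateObjectiveMC(ens, lh, l)["value"]), numeric(1))
  expect_true(all(diff(vals) < 0))
  ## iteroparous constant rates: phi = b0 / (lambda + mu0)
  lhI <- gbmLifeHistory(g = 0.1, s = 0.3, mu0 = 0.3,
                        breeding = "iteroparous", b0 = 1, alpha = 1e-12,
                        omega = Inf)
  cfgI <- simConfig(dt = 0.02, horizon = 40, nPaths = 4000L, seed = 13L)
  ensI <- simulatePaths(lhI, constantPolicy(0), cfgI)
  oI <- estimateObjectiveMC(ensI, lhI, 0.2)
  expect_lt(abs(unname(oI["value"]) - 1 / 0.5), 3 * unname(oI["se"]) + 0.01)
})

test_that("restarting an ensemble reproduces the age-(s+t) distribution", {
  ## Chapman-Kolmogorov / strong-Markov property as a two-sample test
  lh <- gbmLifeHistory(g = 0.1, s = 0.25, mu0 = 0, xm = 1e8)
  cfg1 <- simConfig(dt = 0.01, horizon = 2, nPaths = 4000L, seed = 21L)
  direct <- simulatePaths(lh, constantPolicy(0),
                          simConfig(dt = 0.01, horizon = 4,
                                    nPaths = 4000L, seed = 22L))
  stage1 <- simulatePaths(lh, constantPolicy(0), cfg1)
  xs <- stage1@states[, length(stage1@ages)]
  stage2 <- simulatePaths(lh, constantPolicy(0),
                          simConfig(dt = 0.01, horizon = 2,
                                    nPaths = 4000L, seed = 23L),
                          init = xs)
  xA <- direct@states[, length(direct@ages)]
  xB <- stage2@states[, length(stage2@ages)]
  expect_gt(suppressWarnings(ks.test(xA, xB)$p.value), 1e-3)
})

test_that("breeding-age resampling matches known stable densities", {
  ## constant rates at lambda = 0: exponential ages, mean 1/mu0
  lh <- gbmLifeHistory(g = 0.05, s = 0.2, mu0 = 0.5,
                       breeding = "iteroparous", b0 = 1, alpha = 1e-12,
                       omega = Inf)
  cfg <- simConfig(dt = 0.02, horizon = 25, nPaths = 4000L, seed = 31L)
  ens <- simulatePaths(lh, constantPolicy(0), cfg)
  smp <- sampleBreedingAges(ens, lh, 0, 20000L, seed = 32L)
  expect_lt(abs(mean(smp) - 2), 3 * sd(smp) / sqrt(length(smp)) + 0.05)
  ## degenerate model (no reproduction at all) raises an error
  lhNo <- gbmLifeHistory(g = 0.01, s = 0.05, mu0 = 0.1, xm = 1e6)
  ensNo <- simulatePaths(lhNo, constantPolicy(0),
                         simConfig(dt = 0.1, horizon = 5, nPaths = 20L,
                                   seed = 33L))
  expect_error(sampleBreedingAges(ensNo, lhNo, 0, 10L), "degenerate")
})

test_that("ensembles round-trip through the columnar export", {
  lh <- twoResourceLifeHistory(refParams(), "semelparous")
  cfg <- simConfig(dt = 0.1, horizon = 8, nPaths = 40L, seed = 7L)
  ens <- simulatePaths(lh, constantPolicy(0.7), cfg)
  f <- tempfile(fileext = ".tsv")
  writeEnsemble(ens, f)
  ens2 <- readEnsemble(f)
  expect_equal(ens2@states, ens@states, tolerance = 1e-12)
  expect_equal(ens2@weights, ens@weights, tolerance = 1e-12)
  expect_equal(ens2@maturityTimes, ens@maturityTimes)
  expect_identical(ens2@seed, ens@seed)
})
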