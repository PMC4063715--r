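test_that("the mixed SDE reduces to the pure resources at the box ends", {
  p <- refParams()
  sde <- twoResourceSde(p)
  x <- c(1, 2)
  expect_equal(sde@drift(x, 1, 0), p@m1 * x)
  expect_equal(sde@drift(x, 0, 0), p@m2 * x)
  expect_equal(sde@diffusion(x, 1, 0)[, 1], p@s1 * x)
  expect_true(all(sde@diffusion(x, 1, 0)[, 2] == 0))
  ## independent noises add in variance: equal intensities at u = 1/2
  ## give an effective intensity s/sqrt(2)
  pe <- twoResourceParams(s1 = 0.3 + 1e-12, s2 = 0.3)
  mc <- mixCoefficients(pe, 0.5)
  expect_equal(sqrt(mc$s2), 0.3 / sqrt(2), tolerance = 1e-9)
})

test_that("the single-resource objective solves its defining quadratic", {
  p <- corrParams()
  g <- 0.3; s <- 0.2
  for (lam in c(-0.05, 0, 0.1, 0.5)) {
    phi <- singleResourceObjective(g, s, p@mu0, p@x0, p@xm, p@q, lam)
    theta <- log(p@q / phi) / log(p@xm / p@x0)
    ## theta must satisfy s^2 th^2/2 + (g - s^2/2) th - (lam + mu0) = 0
    expect_equal(0.5 * s^2 * theta^2 + (g - s^2 / 2) * theta -
                   (lam + p@mu0), 0, tolerance = 1e-12)
  }
  ## s -> 0 limit: deterministic hitting time discount
  Tdet <- log(p@xm / p@x0) / g
  expect_equal(singleResourceObjective(g, 0, p@mu0, p@x0, p@xm, p@q, 0.1),
               p@q * exp(-(0.1 + p@mu0) * Tdet))
  ## lambda = -mu0 with s -> 0: no discounting, no killing
  expect_equal(singleResourceObjective(g, 0, p@mu0, p@x0, p@xm, p@q,
                                       -p@mu0), p@q)
  ## far below the abscissa of convergence: flagged divergent
  expect_identical(singleResourceObjective(g, s, p@mu0, p@x0, p@xm, p@q,
                                           -10), Inf)
})

test_that("the convexity index behaves as an efficiency-of-conversion
          measure", {
  p <- refParams()
  n0 <- convexityIndex(p)
  ## doubling the maturation fertility strictly increases the index
  p2 <- twoResourceParams(q = 2 * p@q, xm = p@xm)
  expect_gt(convexityIndex(p2), n0)
  ## invariant under common rescaling of both sizes
  pc <- twoResourceParams(x0 = 3 * p@x0, xm = 3 * p@xm, q = p@q)
  expect_equal(convexityIndex(pc), n0, tolerance = 1e-12)
  ## index is inversely proportional to the log size ratio
  expect_equal(convexityIndex(p), log(p@q) / log(p@xm / p@x0))
  ## size ratio to infinity: index to 0+
  pBig <- twoResourceParams(xm = 1e12, q = p@q)
  expect_lt(convexityIndex(pBig), 0.03)
  expect_gt(convexityIndex(pBig), 0)
})

test_that("single-resource fitness agrees with the Euler-Lotka machinery", {
  p <- corrParams()
  ## s = 0: atom root ln(q)/T - mu0
  Tdet <- log(p@xm / p@x0) / 0.3
  expect_equal(as.numeric(singleResourceFitness(0.3, 0, p)),
               log(p@q) / Tdet - p@mu0, tolerance = 1e-12)
  ## numeric root of the closed-form objective agrees to 1e-8
  lamCf <- as.numeric(singleResourceFitness(0.3, 0.2, p))
  sol <- solveEulerLotka(function(l)
    singleResourceObjective(0.3, 0.2, p@mu0, p@x0, p@xm, p@q, l),
    cumulants = FALSE)
  expect_equal(sol@lambda, lamCf, tolerance = 1e-8)
  ## the sign of the fitness response to s is governed by the index
  dLam <- function(p, s0 = 0.1, h = 0.02) {
    (as.numeric(singleResourceFitness(0.3, s0 + h, p)) -
       as.numeric(singleResourceFitness(0.3, s0 - h, p))) / (2 * h)
  }
  pLow <- twoResourceParams(q = 2, xm = 2^(1 / 0.5))   # n = 0.5
  pHigh <- twoResourceParams(q = 2, xm = 2^(1 / 1.5))  # n = 1.5
  expect_lt(dLam(pLow), 0)
  expect_gt(dLam(pHigh), 0)
})

test_that("the semelparous optimal mix satisfies its defining algebra", {
  p <- refParams()
  mx <- semelparousOptimalMix(p)
  n <- mx@exponent
  ## the power exponent equals the convexity index at the root
  expect_equal(n, convexityIndex(p), tolerance = 1e-14)
  ## the optimized Hamiltonian algebra: sup_u [g(u) n + s2(u) n(n-1)/2]
  ## equals lambda* + mu0 at u* (relation between exponent and root)
  mc <- mixCoefficients(p, mx@uStar)
  expect_equal(mc$g * n + 0.5 * mc$s2 * n * (n - 1),
               mx@lambdaStar + p@mu0, tolerance = 1e-12)
  ## and u* is a stationary point of that expression (interior regime)
  f <- function(u) {
    m <- mixCoefficients(p, u)
    m$g * n + 0.5 * m$s2 * n * (n - 1)
  }
  eps <- 1e-6
  expect_lt(abs((f(mx@uStar + eps) - f(mx@uStar - eps)) / (2 * eps)), 1e-6)
  ## vanishing noise: pure higher-drift specialist
  p0 <- twoResourceParams(s1 = 1e-9, s2 = 0)
  expect_equal(semelparousOptimalMix(p0)@uStar, 1)
  ## equal drifts: variance-minimizing mix (brute-force oracle)
  pEq <- twoResourceParams(m1 = 0.15 + 1e-12, m2 = 0.15)
  mxEq <- semelparousOptimalMix(pEq)
  expect_equal(mxEq@uStar, pEq@s2^2 / (pEq@s1^2 + pEq@s2^2),
               tolerance = 1e-9)
  ug <- seq(0, 1, by = 1e-4)
  lamU <- vapply(ug, function(u) stoclife:::.twoResourceLambdaU(pEq, u),
                 numeric(1))
  expect_lt(abs(ug[which.max(lamU)] - mxEq@uStar), 2e-4)
  ## index above one: the weight on the low-risk resource is zero
  pHi <- twoResourceParams(q = 2, xm = 2^(1 / 1.3))
  mxHi <- semelparousOptimalMix(pHi)
  expect_identical(mxHi@info$r2Weight, 0)
  expect_identical(mxHi@regime, "R1-specialist")
})

test_that("the generalist window matches the clamping events exactly", {
  p <- refParams()
  win <- generalistWindow(p)
  nHi <- win[2]
  mixAt <- function(n) {
    semelparousOptimalMix(twoResourceParams(q = p@q,
                                            xm = p@x0 * p@q^(1 / n)))
  }
  expect_lt(mixAt(nHi - 1e-8)@uStar, 1)
  expect_identical(mixAt(nHi + 1e-8)@uStar, 1)
  ## the closed-form boundary equals the root of the clamping condition
  nClamp <- uniroot(function(n)
    (p@s2^2 + (p@m1 - p@m2) / (1 - n)) / (p@s1^2 + p@s2^2) - 1,
    c(0.01, 0.99), tol = 1e-12)$root
  expect_equal(nClamp, nHi, tolerance = 1e-8)
  ## the low-risk specialist is never selected below the window
  expect_gt(mixAt(0.02)@uStar, 0)
})

test_that("fitness and risky weight increase with the convexity index", {
  p <- refParams()
  ns <- seq(0.05, 0.95, by = 0.05)
  mixes <- lapply(ns, function(n)
    semelparousOptimalMix(twoResourceParams(q = p@q,
                                            xm = p@x0 * p@q^(1 / n))))
  u <- vapply(mixes, function(m) m@uStar, numeric(1))
  lam <- vapply(mixes, function(m) m@lambdaStar, numeric(1))
  expect_true(all(diff(u) > -1e-12))          # non-decreasing
  expect_lt(max(abs(diff(u))), 0.15)          # continuous, no jump
  persistent <- lam >= 0
  expect_true(all(diff(lam[persistent]) > 0)) # increasing where viable
})

test_that("the iteroparous mix mirrors the semelparous formula in alpha", {
  p <- refParams()
  mi <- iteroparousOptimalMix(p)
  ## identical formula with alpha in place of the convexity index
  pSem <- twoResourceParams(q = p@q, xm = p@x0 * p@q^(1 / p@alpha))
  mxSem <- semelparousOptimalMix(pSem)
  expect_equal(mi@uStar, mxSem@uStar, tolerance = 1e-8)
  ## vanishing noise: risky specialist
  p0 <- twoResourceParams(s1 = 1e-9, s2 = 0)
  expect_equal(iteroparousOptimalMix(p0)@uStar, 1)
  ## closed-form mix matches the brute-force argmax within grid spacing
  lhI <- twoResourceLifeHistory(p, "iteroparous")
  bf <- bruteForceConstantPolicy(lhI, seq(0, 1, length.out = 101L),
                                 route = "closed_form")
  expect_lt(abs(attr(bf, "argmax") - mi@uStar), 0.01 + 1e-12)
  ## exact fitness solves the transcendental Euler-Lotka equation
  expect_equal(iteroparousObjective(p, mi@uStar, mi@lambdaStar), 1,
               tolerance = 1e-8)
  ## and is bounded by the infinite-lifespan root
  expect_lt(mi@lambdaStar, mi@info$lambdaInfty)
})

test_that("iteroparous breeding-age structure follows its closed forms", {
  p <- jShapeParams()
  mi <- iteroparousOptimalMix(p)
  dem <- iteroparousDemography(p, mi)
  ## R0 equals phi(0) of the numeric ERS
  expect_equal(dem$R0, iteroparousObjective(p, mi@uStar, 0),
               tolerance = 1e-6)
  ## density integrates to one (closed form)
  expect_equal(integrate(dem$density, 0, p@omega,
                         rel.tol = 1e-12)$value, 1, tolerance = 1e-10)
  ## J-shaped here: positive exponent, increasing density
  expect_identical(dem$shape, "increasing")
  expect_gt(dem$exponent, 0)
  a <- seq(0.1, p@omega - 0.1, length.out = 50)
  expect_true(all(diff(dem$density(a)) > 0))
  ## exactly uniform when the exponent vanishes: calibrate b0 so that
  ## the fitness root coincides with the growth-exponent rate
  pU0 <- twoResourceParams(alpha = 0.8, omega = 30,
                           b0 = 1 / 30)  # b0 x0^alpha omega = 1
  miU <- iteroparousOptimalMix(pU0)
  demU <- iteroparousDemography(pU0, miU)
  expect_identical(demU$shape, "uniform")
  expect_equal(demU$density(c(1, 10, 29)), rep(1 / 30, 3))
  ## minimal viable lifespan: monotone bisection against R0 = 1
  demJ <- iteroparousDemography(p, mi)
  omMin <- demJ$minViableOmega
  R0at <- function(w) {
    pw <- twoResourceParams(alpha = p@alpha, b0 = p@b0, omega = w)
    iteroparousDemography(pw, iteroparousOptimalMix(pw))$R0
  }
  expect_lt(R0at(omMin * 0.95), 1)
  expect_gte(R0at(omMin * 1.05), 1)
  ## iteroparous fitness increases with the maximum lifespan
  lams <- vapply(c(10, 20, 40, 80), function(w)
    iteroparousOptimalMix(twoResourceParams(alpha = p@alpha, b0 = p@b0,
                                            omega = w))@lambdaStar,
    numeric(1))
  expect_true(all(diff(lams) > 0))
})

test_that("the optimal-mix ERS rises with the allometric exponent", {
  p <- refParams()
  ages <- c(0.5, 2, 5, 10, 20)
  ersAt <- function(alpha) {
    pa <- twoResourceParams(alpha = alpha, b0 = p@b0, omega = p@omega,
                            x0 = 2)  # x0 > 1 so x0^alpha also grows
    ma <- iteroparousOptimalMix(pa)
    pa@b0 * pa@x0^alpha * exp(ma@info$lambdaTilde * ages)
  }
  e1 <- ersAt(0.3); e2 <- ersAt(0.5); e3 <- ersAt(0.7)
  expect_true(all(e2 > e1) && all(e3 > e2))
})

test_that("the maturation-age density matches its defining transforms", {
  p <- refParams()
  u <- semelparousOptimalMix(p)@uStar
  md <- matureAgeDensity(p, u)
  ## normalized density integrates to one
  expect_equal(integrate(md$density, 0, Inf, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-7)
  ## q times the unnormalized density integrates to R0 = phi(0)
  R0 <- twoResourceObjective(p, u, 0)
  expect_equal(p@q * integrate(md$unnormalized, 0, Inf,
                               rel.tol = 1e-10)$value, R0,
               tolerance = 1e-6)
  ## the cdf is consistent with the density
  expect_equal(md$cdf(15), integrate(md$density, 0, 15,
                                     rel.tol = 1e-10)$value,
               tolerance = 1e-7)
  ## vanishing noise: point mass at the deterministic hitting age
  p0 <- twoResourceParams(s1 = 1e-9, s2 = 0)
  md0 <- matureAgeDensity(p0, 0)
  expect_equal(md0$pointMass, log(p0@xm / p0@x0) / p0@m2, tolerance = 1e-9)
  ## degenerate: zero drift with zero noise never matures
  pNeg <- twoResourceParams(m1 = 0, m2 = -0.1, s1 = 1e-9, s2 = 0)
  expect_error(matureAgeDensity(pNeg, 0), "never matures")
  ## maturation shifts toward younger ages as the index grows
  meanAt <- function(n) {
    pn <- twoResourceParams(q = p@q, xm = p@x0 * p@q^(1 / n))
    un <- semelparousOptimalMix(pn)@uStar
    mdn <- matureAgeDensity(pn, un)
    integrate(function(t) t * mdn$density(t), 0, Inf)$value
  }
  expect_gt(meanAt(0.2), meanAt(0.4))
  expect_gt(meanAt(0.4), meanAt(0.8))
})

test_that("the stochasticity threshold sits at index one", {
  scan <- stochasticitySensitivityScan(refParams(),
                                       nValues = c(0.5, 0.8, 1.2, 1.5))
  expect_true(all(scan$table$sign[scan$table$n < 1] < 0))
  expect_true(all(scan$table$sign[scan$table$n > 1] > 0))
  expect_equal(scan$threshold, 1, tolerance = 1e-3)
})

test_that("optimal mature size maximizes the objective over the boundary", {
  p <- corrParams()
  res <- optimalMatureSize(p, lambda = 0.05, u = 1)
  ## oracle: dense grid search over the same objective
  mc <- mixCoefficients(p, 1)
  qFun <- function(x) p@q * x * exp(-x / (2 * p@xm))
  xg <- seq(p@x0 * 1.001, 50, length.out = 20000L)
  og <- vapply(xg, function(xm) qFun(xm) / p@q *
                 singleResourceObjective(mc$g, sqrt(mc$s2), p@mu0, p@x0,
                                         xm, p@q, 0.05), numeric(1))
  expect_lt(abs(res$xm - xg[which.max(og)]), 0.01)
  expect_gt(res$xm, p@x0)
})
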