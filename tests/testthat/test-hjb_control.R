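test_that("the control Hamiltonian matches its defining expression", {
  p <- refParams()
  lh <- twoResourceLifeHistory(p, "semelparous")
  ## V = 0 and b = 0 give zero for every control
  for (u in c(0, 0.3, 1))
    expect_identical(controlHamiltonian(lh, 2, 0, 0, 0, 0.1, u), 0)
  ## sigma = 0, V = exp(x): reduces to (g - lambda - mu) e^x + b,
  ## checked against direct symbolic evaluation
  lhD <- gbmLifeHistory(g = 0.3, s = 0, mu0 = 0.2, xm = 10)
  x <- 1.5; lam <- 0.07
  H <- controlHamiltonian(lhD, x, exp(x), exp(x), exp(x), lam, 0)
  expect_equal(H, (0.3 * x - lam - 0.2) * exp(x), tolerance = 1e-12)
  ## two-resource Hamiltonian is quadratic in u with negative leading
  ## coefficient when Vxx < 0
  Hu <- function(u) controlHamiltonian(lh, 2, 1, -0.5, 1, 0.1, u)
  a2 <- (Hu(0) - 2 * Hu(0.5) + Hu(1)) * 2  # second difference
  expect_lt(a2, 0)
  ## and the cubic term vanishes (exactly quadratic)
  h4 <- Hu(0) - 3 * Hu(1 / 3) + 3 * Hu(2 / 3) - Hu(1)
  expect_lt(abs(h4), 1e-10)
})

test_that("pointwise Hamiltonian minimization finds the Markovian control", {
  p <- refParams()
  lh <- twoResourceLifeHistory(p, "semelparous")
  ## Vxx = 0: linear in u, optimum on the boundary of the box
  r <- minimizeHamiltonianPointwise(lh, 2, 1, 0, 1, 0.1)
  expect_true(r$u %in% c(0, 1))
  expect_identical(r$u, 1)  # m1 > m2 prefers the risky resource
  ## equal drifts: pure variance minimization at s2^2/(s1^2+s2^2)
  sdeEq <- controlledSDE(
    drift = function(x, u, a) 0.15 * x,
    diffusion = function(x, u, a) cbind(u * 0.5 * x, (1 - u) * 0.2 * x),
    nNoise = 2L, x0 = 1, logScale = TRUE)
  lhEq <- lifeHistory(sdeEq, mortality(function(x, u, a) 0.05),
                      fertility("semelparous", function(x, a) 2),
                      stateSpace(1e-4, 4,
                                 c("truncation", "absorbing-maturity")))
  rEq <- minimizeHamiltonianPointwise(lhEq, 2, 1, -1, 1, 0.1)
  expect_equal(rEq$u, 0.2^2 / (0.5^2 + 0.2^2), tolerance = 1e-10)
  ## grid mode agrees with the analytic extremum to the grid spacing
  m <- 10000L
  rG <- minimizeHamiltonianPointwise(lhEq, 2, 1, -1, 1, 0.1, mode = "grid",
                                     nControl = m)
  expect_lt(abs(rG$u - rEq$u), 2 / m)
  ## a non-quadratic Hamiltonian falls back to grid mode with a warning
  sdeNq <- controlledSDE(
    drift = function(x, u, a) sin(3 * u) * x,
    diffusion = function(x, u, a) 0.1 * x,
    x0 = 1, logScale = TRUE)
  lhNq <- lifeHistory(sdeNq, mortality(function(x, u, a) 0.05),
                      fertility("semelparous", function(x, a) 2),
                      stateSpace(1e-4, 4,
                                 c("truncation", "absorbing-maturity")))
  expect_warning(minimizeHamiltonianPointwise(lhNq, 2, 1, -1, 1, 0.1),
                 "not quadratic")
})

test_that("the stationary solver recovers the deterministic hitting value", {
  ## no control, sigma = 0, g * x growth, constant mortality:
  ## V(x) = q (x/x*)^((lambda + mu0)/g)
  lh <- gbmLifeHistory(g = 0.5, s = 0, mu0 = 0.15, xm = 4, q = 3)
  lam <- 0.1
  kap <- (lam + 0.15) / 0.5
  grid <- grid1d(exp(-6) * 4, 4, 2001)
  cfg <- hjbConfig(stencil = "central")
  vg <- solveStationaryHjb(lh, lam, grid, cfg,
                           lowerValue = 3 * (grid[1] / 4)^kap)
  Vex <- 3 * (vg@nodes / 4)^kap
  expect_lt(max(abs(vg@V - Vex)) / max(Vex), 1e-4)
  ## V is decreasing in lambda at every node
  vg2 <- solveStationaryHjb(lh, lam + 0.1, grid, cfg)
  expect_true(all(vg2@V <= vg@V + 1e-10))
})

test_that("the stationary solver matches the two-resource power law", {
  p <- refParams()
  mx <- semelparousOptimalMix(p)
  lh <- twoResourceLifeHistory(p, "semelparous")
  grid <- grid1d(p@x0 * exp(-12), p@xm, 321)
  vg <- solveStationaryHjb(lh, mx@lambdaStar, grid)
  Vex <- mx@info$C * vg@nodes^mx@exponent
  expect_lt(max(abs(vg@V - Vex)) / max(Vex), 0.01)
  ## the extracted policy is constant in x (interior nodes where the
  ## value function is resolved; boundary nodes carry no information)
  interior <- vg@nodes >= p@x0 * exp(-2) & vg@nodes < p@xm
  expect_lt(max(abs(vg@policy[interior] - mx@uStar)), 0.02)
})

test_that("the finite-horizon solver matches closed-form values", {
  ## constant b and mu, no control:
  ## V(a, x) = b0 (1 - exp(-(lambda + mu0)(omega - a))) / (lambda + mu0)
  om <- 12
  lh <- gbmLifeHistory(g = 0.1, s = 0.2, mu0 = 0.3,
                       breeding = "iteroparous", b0 = 2, alpha = 1e-14,
                       omega = om)
  lam <- 0.05
  grid <- grid1d(exp(-4), exp(4), 201)
  ages <- seq(0, om, length.out = 241)
  vg <- solveFiniteHorizonHjb(lh, lam, grid, ages)
  k <- lam + 0.3
  Vex <- outer(rep(1, 201), 2 * (1 - exp(-k * (om - ages))) / k)
  expect_lt(max(abs(vg@V - Vex)) / max(Vex), 0.01)
  ## two-resource iteroparous: V(0, x) matches the separable closed form
  ## and the policy is age-independent (mortality carries no control)
  p <- refParams()
  mi <- iteroparousOptimalMix(p)
  lhI <- twoResourceLifeHistory(p, "iteroparous")
  gridI <- grid1d(p@x0 * exp(-7), p@x0 * exp(9), 401)
  agesI <- seq(0, p@omega, length.out = 401)
  vgI <- solveFiniteHorizonHjb(lhI, mi@lambdaStar, gridI, agesI)
  VexI <- vapply(gridI, function(x) mi@info$value(0, x), numeric(1))
  mid <- gridI >= p@x0 * exp(-3) & gridI <= p@x0 * exp(5)
  expect_lt(max(abs(vgI@V[mid, 1] - VexI[mid])) / max(VexI[mid]), 0.01)
  expect_lt(max(abs(vgI@policy[mid, 1] - mi@uStar)), 0.021)
  ageSpread <- apply(vgI@policy[mid, 1:380], 1, function(r) diff(range(r)))
  expect_lt(max(ageSpread), 0.02)
  ## the policy maximizing the ERS alone (any lambda) equals the policy
  ## from the fitness-coupled solve when mortality is control-free
  vgI2 <- solveFiniteHorizonHjb(lhI, mi@lambdaStar + 0.3, gridI, agesI)
  expect_lt(max(abs(vgI2@policy[mid, 1] - vgI@policy[mid, 1])), 0.02)
})

test_that("a long horizon approaches the stationary value", {
  p <- refParams()
  mi <- iteroparousOptimalMix(p)
  ## stationary solver on the omega = Inf variant
  pLong <- twoResourceParams(alpha = p@alpha, b0 = p@b0, omega = Inf)
  lhInf <- twoResourceLifeHistory(pLong, "iteroparous")
  lam <- mi@info$lambdaInfty + 0.05  # safely above the abscissa
  grid <- grid1d(p@x0 * exp(-7), p@x0 * exp(9), 401)
  vgS <- solveStationaryHjb(lhInf, lam, grid)
  ## finite-horizon at omega = 10 mean breeding ages
  meanAge <- 1 / (lam - mi@info$lambdaTilde)
  om <- 10 * meanAge
  pFin <- twoResourceParams(alpha = p@alpha, b0 = p@b0, omega = om)
  lhFin <- twoResourceLifeHistory(pFin, "iteroparous")
  vgF <- solveFiniteHorizonHjb(lhFin, lam, grid,
                               seq(0, om, length.out = 401))
  i0 <- which.min(abs(grid - p@x0))
  expect_lt(abs(vgF@V[i0, 1] - vgS@V[i0]) / vgS@V[i0], 0.01)
})

test_that("the optimal fitness equals the Euler-Lotka root of the
          uncontrolled model", {
  ## degenerate control set: the HJB route must reproduce demography
  lh <- gbmLifeHistory(g = 0.5, s = 0, mu0 = 0.15, xm = 4, q = 3)
  lamEL <- log(3) / (log(4) / 0.5) - 0.15  # atom Euler-Lotka
  of <- optimalFitness(lh, grid1d(4 * exp(-8), 4, 2001),
                       hjbConfig(stencil = "central"),
                       bracket0 = c(0, 0.5))
  expect_lt(abs(of$lambda - lamEL), 1e-4)
  ## diffusive uncontrolled model against the closed-form root
  p <- corrParams()
  lhG <- gbmLifeHistory(g = 0.3, s = 0.2, mu0 = p@mu0, xm = p@xm, q = p@q)
  lamCf <- as.numeric(singleResourceFitness(0.3, 0.2, p))
  ofG <- optimalFitness(lhG, grid1d(p@x0 * exp(-10), p@xm, 601))
  expect_lt(abs(ofG$lambda - lamCf), 5e-4)
})

test_that("enlarging the control set never decreases the fitness", {
  p <- refParams()
  lh <- twoResourceLifeHistory(p, "semelparous")
  grid <- grid1d(p@x0 * exp(-10), p@xm, 281)
  ofFull <- optimalFitness(lh, grid)
  for (u0 in c(0.3, 0.9)) {
    lhFix <- lh
    lhFix@sde@controlLower <- u0
    lhFix@sde@controlUpper <- u0
    ofFix <- optimalFitness(lhFix, grid)
    expect_gte(ofFull$lambda, ofFix$lambda - 1e-6)
  }
})

test_that("brute-force constant policies bound the HJB policy from below", {
  p <- refParams()
  lh <- twoResourceLifeHistory(p, "semelparous")
  bf <- bruteForceConstantPolicy(lh, seq(0, 1, length.out = 101L),
                                 route = "closed_form")
  mx <- semelparousOptimalMix(p)
  ## the analytic optimum matches the brute-force argmax within spacing
  expect_lt(abs(attr(bf, "argmax") - mx@uStar), 0.01 + 1e-12)
  expect_true(all(bf$lambda <= mx@lambdaStar + 1e-10))
  ## lambda(u) is continuous in u (no bang-bang jump)
  expect_lt(max(abs(diff(bf$lambda))), 0.02)
  ## degenerate identical resources: lambda(u) flat
  sdeFlat <- controlledSDE(
    drift = function(x, u, a) 0.25 * x,
    diffusion = function(x, u, a) cbind(u * 0.3 * x, (1 - u) * 0.3 * x),
    nNoise = 2L, x0 = 1, logScale = TRUE)
  lhFlat <- lifeHistory(sdeFlat, mortality(function(x, u, a) 0.1),
                        fertility("semelparous", function(x, a) 2),
                        stateSpace(exp(-8), 3,
                                   c("truncation", "absorbing-maturity")))
  grid <- grid1d(exp(-6), 3, 161)
  ages <- seq(0, 50, length.out = 101)
  bfF <- bruteForceConstantPolicy(lhFlat, c(0, 0.25, 0.5, 1),
                                  route = "pde", grid = grid, ages = ages)
  ## identical resources are exchangeable: lambda(u) = lambda(1 - u)
  expect_lt(abs(bfF$lambda[1] - bfF$lambda[4]), 1e-6)
  ## mixing two independent identical noises halves the variance (the
  ## portfolio effect), so the spread follows the closed-form prediction
  n <- log(2) / log(3)
  predSpread <- abs(0.5 * 0.3^2 * n * (n - 1)) * 0.5
  expect_lt(abs((max(bfF$lambda) - min(bfF$lambda)) - predSpread), 2e-3)
})

test_that("the discounted value process is a martingale along optimal
          paths (Dynkin)", {
  p <- refParams()
  mx <- semelparousOptimalMix(p)
  lh <- twoResourceLifeHistory(p, "semelparous")
  n <- mx@exponent; C <- mx@info$C
  Vfun <- function(x) C * x^n
  tEval <- 8
  cfg <- simConfig(dt = 0.01, horizon = tEval, nPaths = 8000L, seed = 51L,
                   bridgeCorrection = TRUE)
  ens <- simulatePaths(lh, constantPolicy(mx@uStar), cfg)
  disc <- exp(-(mx@lambdaStar + p@mu0))
  contrib <- ifelse(is.na(ens@maturityTimes) | ens@maturityTimes > tEval,
                    disc^tEval * Vfun(ens@states[, length(ens@ages)]),
                    disc^ens@maturityTimes * p@q)
  se <- sd(contrib) / sqrt(length(contrib))
  expect_lt(abs(mean(contrib) - Vfun(p@x0)), 3 * se + 0.01)
})

test_that("values compose across an intermediate age (Bellman principle)", {
  p <- refParams()
  mi <- iteroparousOptimalMix(p)
  lh <- twoResourceLifeHistory(p, "iteroparous")
  grid <- grid1d(p@x0 * exp(-7), p@x0 * exp(9), 301)
  full <- solveFiniteHorizonHjb(lh, mi@lambdaStar, grid,
                                seq(0, p@omega, length.out = 301))
  ## restart the sweep at an intermediate age from the attained values
  aSplit <- 12
  js <- which.min(abs(full@ages - aSplit))
  pTail <- twoResourceParams(omega = p@omega - full@ages[js])
  ## compose by sweeping the head with the tail solution as terminal data:
  ## reuse the backward recursion on the same grid
  headAges <- seq(0, full@ages[js], length.out = js)
  om <- p@omega
  lhHead <- lh
  lhHead@fertility@maxLifespan <- full@ages[js]
  vgHead <- solveFiniteHorizonHjb(lhHead, mi@lambdaStar, grid, headAges)
  ## linear superposition: V_full(0,.) = V_head(0,.) + E[disc x V_tail];
  ## check at x0 using the closed-form tail
  tailV <- vapply(grid, function(x) mi@info$value(full@ages[js], x),
                  numeric(1))
  ## transport the tail value to age 0 with the projection kernel
  kern <- solveFokkerPlanck(lh, constantPolicy(mi@uStar),
                           grid1d(p@x0 * exp(-7), p@x0 * exp(9), 301),
                           seq(0, full@ages[js], length.out = js),
                           dt = 0.05)
  h <- kern@info$h
  x <- exp(kern@nodes)
  tailAt0 <- sum(vapply(seq_along(x), function(i)
    kern@density[i, js] * mi@info$value(full@ages[js], x[i]),
    numeric(1))) * h * exp(-mi@lambdaStar * full@ages[js])
  i0 <- which.min(abs(grid - p@x0))
  expect_lt(abs(vgHead@V[i0, 1] + tailAt0 - full@V[i0, 1]) /
              full@V[i0, 1], 0.02)
})
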