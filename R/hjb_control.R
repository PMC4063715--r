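## Optimal control: the control Hamiltonian, stationary (semelparous,
## Dirichlet) and finite-horizon (iteroparous, terminal-value) HJB
## solvers, Markovian policy extraction, and the outer fitness loop that
## couples the optimized objective to the Euler-Lotka root.
##
## Numerical contract: the spatial operator is discretized with a hybrid
## stencil -- central differences where the cell Peclet number allows,
## monotone (M-matrix) one-sided differences otherwise -- so the implicit
## scheme is monotone, consistent and stable, hence convergent to the
## viscosity solution; no smoothness is assumed.

#' Control Hamiltonian
#'
#' `H(u) = g(x,u) Vx + sigma2(x,u) Vxx / 2 - (lambda + mu(x,u)) V + b(x)`
#' (the iteroparous source `b`; semelparous fertility enters only through
#' the boundary condition).  The HJB equation balances the age derivative
#' against the supremum of `H` over the control set.
#'
#' @param lh a [LifeHistory-class].
#' @param x state (scalar).
#' @param Vx,Vxx,V value-function derivatives and value at `x`.
#' @param lambda discount (candidate fitness).
#' @param u control point.
#' @param age age at evaluation (stationary problems use 0).
#' @return scalar Hamiltonian value.
#' @export
controlHamiltonian <- function(lh, x, Vx, Vxx, V, lambda, u, age = 0) {
  g <- lh@sde@drift(x, u, age)
  sig <- lh@sde@diffusion(x, u, age)
  v <- sum(sig^2)
  mu <- lh@mortality@rate(x, u, age)
  b <- if (lh@fertility@kind == "iteroparous")
         lh@fertility@rate(x, age) else 0
  g * Vx + 0.5 * v * Vxx - (lambda + mu) * V + b
}

## Vectorized argmax of a Hamiltonian over a 1-D control box.
## Hfun(u) must return the Hamiltonian at every node for scalar u.
## "analytic" fits the exact quadratic through three control points and
## verifies it at a fourth; non-quadratic Hamiltonians fall back to the
## control grid with a warning.  Ties break toward the smaller u.
.argmaxH <- function(Hfun, lo, hi, mode = "analytic", nControl = 33L) {
  if (hi <= lo) {  # degenerate control set
    H <- Hfun(lo)
    return(rep(lo, length(H)))
  }
  if (mode == "analytic") {
    um <- (lo + hi) / 2
    H0 <- Hfun(lo); H1 <- Hfun(um); H2 <- Hfun(hi)
    ## quadratic through (lo, um, hi): H = a u^2 + b u + c
    d <- (hi - lo)
    a <- 2 * (H0 - 2 * H1 + H2) / d^2
    b <- (H2 - H0) / d - a * (lo + hi)
    uchk <- lo + 0.37 * d
    Hq <- a * uchk^2 + b * uchk + (H0 - a * lo^2 - b * lo)
    Hc <- Hfun(uchk)
    scale <- max(abs(H0), abs(H1), abs(H2), 1e-12)
    if (max(abs(Hq - Hc)) > 1e-6 * scale) {
      warning("Hamiltonian is not quadratic in u; falling back to grid mode")
      return(.argmaxH(Hfun, lo, hi, mode = "grid", nControl = max(nControl,
                                                                  201L)))
    }
    uint <- ifelse(a < 0, pmin(pmax(-b / (2 * a), lo), hi), NA_real_)
    ## compare candidates: interior (when concave) and both endpoints
    Hci <- ifelse(is.na(uint), -Inf, a * uint^2 + b * uint)
    Hc0v <- a * lo^2 + b * lo
    Hc1v <- a * hi^2 + b * hi
    best <- uint
    Hbest <- Hci
    pickLo <- is.na(best) | Hc0v >= Hbest - 1e-15 * abs(Hbest)
    best[pickLo] <- lo
    Hbest[pickLo] <- Hc0v[pickLo]
    pickHi <- Hc1v > Hbest + 1e-15 * pmax(abs(Hbest), 1)
    best[pickHi] <- hi
    return(best)
  }
  ug <- seq(lo, hi, length.out = nControl)
  Hm <- vapply(ug, Hfun, Hfun(lo))
  if (is.null(dim(Hm))) Hm <- matrix(Hm, nrow = 1L)
  ug[apply(Hm, 1L, which.max)]   # which.max: first maximum = smaller u
}

#' Pointwise minimization of the control Hamiltonian
#'
#' Analytic mode uses the closed-form extremum of the quadratic-in-u
#' Hamiltonian, clamped to the control box (this realizes the Markovian
#' control); grid mode takes the argmax over a discretized control set,
#' ties broken toward the smaller u.
#'
#' @inheritParams controlHamiltonian
#' @param mode `"analytic"` or `"grid"`.
#' @param nControl control grid points for grid mode.
#' @return list with `u` (optimal control) and `value` (Hamiltonian
#'   there).
#' @export
minimizeHamiltonianPointwise <- function(lh, x, Vx, Vxx, V, lambda,
                                         mode = c("analytic", "grid"),
                                         nControl = 1001L) {
  mode <- match.arg(mode)
  lo <- lh@sde@controlLower[1L]; hi <- lh@sde@controlUpper[1L]
  Hfun <- function(u) controlHamiltonian(lh, x, Vx, Vxx, V, lambda, u)
  u <- .argmaxH(Hfun, lo, hi, mode = mode, nControl = nControl)
  list(u = u, value = Hfun(u))
}

#' HJB solver settings
#'
#' @param scheme `"policy_iteration"` or `"backward"`.
#' @param controlMode `"analytic"` or `"grid"`.
#' @param nControl control grid points in grid mode.
#' @param tol convergence tolerance on the value function.
#' @param maxIter maximum policy iterations.
#' @param damping damping on policy updates (undamped iteration can cycle
#'   in grid mode).
#' @param stencil first-derivative discretization (`"hybrid"`, `"central"`,
#'   `"upwind"`).
#' @return an [HjbConfig-class].
#' @export
hjbConfig <- function(scheme = "policy_iteration", controlMode = "analytic",
                      nControl = 101L, tol = 1e-9, maxIter = 200L,
                      damping = 0.5, stencil = c("hybrid", "central",
                                                 "upwind")) {
  new("HjbConfig", scheme = scheme, controlMode = controlMode,
      nControl = as.integer(nControl), tol = tol,
      maxIter = as.integer(maxIter), damping = damping,
      stencil = match.arg(stencil))
}

## transformed Hamiltonian pieces on the solving coordinate; returns
## closures evaluating drift/variance/mu/b at every node for scalar u
.hjbCoefs <- function(lh, nodes, age = 0) {
  useLog <- lh@sde@logScale
  x <- nodes
  list(
    adv = function(u) {
      g <- lh@sde@drift(x, u, age)
      if (length(g) == 1L) g <- rep(g, length(x))
      if (!useLog) return(g)
      sig <- lh@sde@diffusion(x, u, age)
      if (!is.matrix(sig)) sig <- matrix(sig, ncol = lh@sde@nNoise)
      g / x - rowSums(sig^2) / (2 * x^2)
    },
    D = function(u) {
      sig <- lh@sde@diffusion(x, u, age)
      if (!is.matrix(sig)) sig <- matrix(sig, ncol = lh@sde@nNoise)
      v <- rowSums(sig^2)
      if (useLog) v / (2 * x^2) else v / 2
    },
    mu = function(u) .muVec(lh, x, u, age, length(x)),
    b = if (lh@fertility@kind == "iteroparous") {
      function() {
        b <- lh@fertility@rate(x, age)
        if (length(b) == 1L) b <- rep(b, length(x)) else b
      }
    } else function() numeric(length(x)))
}

## Coefficients at a per-node control vector.  Models whose evaluable
## mappings vectorize elementwise in u are evaluated in one call (checked
## against a scalar evaluation at one node); otherwise fall back to a loop
## over the distinct controls.
.coefsAt <- function(co, u, n) {
  fast <- tryCatch({
    adv <- co$adv(u); D <- co$D(u); mu <- co$mu(u)
    i <- max(1L, n %/% 2L)
    ok <- length(adv) == n && length(D) == n && length(mu) == n &&
      isTRUE(all.equal(adv[i], co$adv(u[i])[i])) &&
      isTRUE(all.equal(D[i], co$D(u[i])[i]))
    if (ok) list(adv = adv, D = D, mu = mu) else NULL
  }, error = function(e) NULL)
  if (!is.null(fast)) return(fast)
  adv <- numeric(n); D <- numeric(n); mu <- numeric(n)
  for (uv in unique(u)) {
    m <- u == uv
    adv[m] <- co$adv(uv)[m]; D[m] <- co$D(uv)[m]; mu[m] <- co$mu(uv)[m]
  }
  list(adv = adv, D = D, mu = mu)
}

## finite-difference derivatives of V on a uniform grid (one-sided at the
## ends, second order interior)
.dV <- function(V, h) {
  n <- length(V)
  Vz <- c((V[2] - V[1]) / h,
          (V[3:n] - V[1:(n - 2)]) / (2 * h),
          (V[n] - V[n - 1]) / h)
  Vzz <- c(0, (V[3:n] - 2 * V[2:(n - 1)] + V[1:(n - 2)]) / h^2, 0)
  list(Vz = Vz, Vzz = Vzz)
}

## Tridiagonal rows of  adv*Dz + D*Dzz - kappa  with the hybrid
## central/upwind first derivative (M-matrix off the Peclet limit).
## Returns dl, d, du (the operator applied to V).
.hjbOperator <- function(adv, D, kappa, h, n, stencil = "hybrid") {
  dl <- numeric(n - 1); dd <- numeric(n); du <- numeric(n - 1)
  pe <- abs(adv) * h / (2 * pmax(D, 1e-300))
  central <- switch(stencil,
                    hybrid = pe <= 1 & D > 0,
                    central = rep(TRUE, n),
                    upwind = rep(FALSE, n))
  for (i in 2:(n - 1)) {
    if (central[i]) {
      dl[i - 1] <- dl[i - 1] + D[i] / h^2 - adv[i] / (2 * h)
      dd[i] <- dd[i] - 2 * D[i] / h^2
      du[i] <- du[i] + D[i] / h^2 + adv[i] / (2 * h)
    } else if (adv[i] >= 0) {
      dl[i - 1] <- dl[i - 1] + D[i] / h^2
      dd[i] <- dd[i] - 2 * D[i] / h^2 - adv[i] / h
      du[i] <- du[i] + D[i] / h^2 + adv[i] / h
    } else {
      dl[i - 1] <- dl[i - 1] + D[i] / h^2 - adv[i] / h
      dd[i] <- dd[i] - 2 * D[i] / h^2 + adv[i] / h
      du[i] <- du[i] + D[i] / h^2
    }
  }
  dd <- dd - kappa
  list(dl = dl, d = dd, du = du)
}

#' Stationary HJB equation (semelparous Dirichlet problem)
#'
#' Howard policy iteration for
#' `sup_u [ g Vx + sigma2 Vxx / 2 - (lambda + mu) V + b ] = 0` with the
#' Dirichlet condition `V = q(x*)` on the mature boundary.  Each iteration
#' solves the linear operator equation under the current policy by
#' implicit finite differences and re-extracts the policy by pointwise
#' Hamiltonian maximization (damped).  The lower state boundary of a
#' degenerate (GBM-like) diffusion is a natural boundary; the truncated
#' domain imposes `V = lowerValue` (default 0) far below the initial
#' state, and insensitivity to the truncation is part of the test
#' contract.
#'
#' @param lh a semelparous [LifeHistory-class] (or iteroparous with
#'   unbounded lifespan).
#' @param lambda discount (candidate fitness).
#' @param grid nodes from [grid1d()], last node on the mature boundary.
#' @param cfg an [HjbConfig-class].
#' @param lowerValue Dirichlet value at the truncation end.
#' @param uInit initial policy guess (vector or scalar).
#' @return a [ValueGrid-class] with the stationary value and policy.
#' @export
solveStationaryHjb <- function(lh, lambda, grid, cfg = hjbConfig(),
                               lowerValue = 0, uInit = NULL) {
  useLog <- lh@sde@logScale
  z <- if (useLog) log(grid) else as.numeric(grid)
  n <- length(z)
  h <- z[2] - z[1]
  if (max(abs(diff(z) - h)) > 1e-8 * h)
    stop("grid must be uniform in the solving coordinate")
  semel <- lh@fertility@kind == "semelparous"
  if (semel) {
    face <- .matureFaceValue(lh)
    qb <- lh@fertility@rate(face$value, 0)
  } else {
    if (is.finite(lh@fertility@maxLifespan))
      stop("stationary solver needs a semelparous history or omega = Inf")
    qb <- NA_real_
  }
  co <- .hjbCoefs(lh, grid)
  lo <- lh@sde@controlLower[1L]; hi <- lh@sde@controlUpper[1L]
  u <- rep(if (is.null(uInit)) (lo + hi) / 2 else uInit, length.out = n)
  V <- if (semel) qb * exp(z - z[n]) else rep(0, n)
  damping <- cfg@damping
  bfix <- co$b()
  resid <- Inf; it <- 0L
  dVnorm_prev <- Inf; grow <- 0L
  repeat {
    it <- it + 1L
    ## (i) linear solve under the current policy
    cc <- .coefsAt(co, u, n)
    adv <- cc$adv; D <- cc$D; mu <- cc$mu
    op <- .hjbOperator(adv, D, lambda + mu, h, n, cfg@stencil)
    rhs <- -bfix
    ## Dirichlet rows at both ends
    op$d[1] <- 1; op$du[1] <- 0; rhs[1] <- lowerValue
    op$d[n] <- 1; op$dl[n - 1] <- 0
    rhs[n] <- if (semel) qb else {
      ## unbounded-lifespan upper end: first-order outflow row
      op$d[n] <- -(lambda + mu[n]) - adv[n] / h
      op$dl[n - 1] <- adv[n] / h
      -bfix[n]
    }
    Vnew <- .cpp_thomas(op$dl, op$d, op$du, rhs)
    dVn <- max(abs(Vnew - V)) / max(max(abs(Vnew)), 1e-300)
    if (dVn > dVnorm_prev * 1.0001) {
      ## value oscillation: raise the damping once, keep iterating
      grow <- grow + 1L
      if (grow == 3L) damping <- min(0.95, damping + 0.25)
    }
    dVnorm_prev <- dVn
    V <- Vnew
    ## (ii) pointwise Hamiltonian maximization
    dv <- .dV(V, h)
    Hfun <- function(uv) co$adv(uv) * dv$Vz + co$D(uv) * dv$Vzz -
      (lambda + co$mu(uv)) * V + bfix
    uStar <- .argmaxH(Hfun, lo, hi, mode = cfg@controlMode,
                      nControl = cfg@nControl)
    dU <- max(abs(uStar - u))
    u <- u + damping * (uStar - u)
    resid <- {
      c2 <- .coefsAt(co, uStar, n)
      r <- c2$adv * dv$Vz + c2$D * dv$Vzz - (lambda + c2$mu) * V + bfix
      max(abs(r[2:(n - 1)])) / max(max(abs(V)), 1e-300)
    }
    ## converged when the value function reaches a fixed point (policy
    ## chatter where V is negligible does not alter V)
    if (dVn < cfg@tol || it >= cfg@maxIter) break
  }
  if (it >= cfg@maxIter && dVn > 100 * cfg@tol)
    stop("policy iteration did not converge; last value change ",
         signif(dVn, 4), ", residual ", signif(resid, 4))
  new("ValueGrid", nodes = as.numeric(grid), ages = numeric(), V = V,
      policy = u, lambda = lambda, residual = resid, iterations = it,
      info = list(h = h, coord = if (useLog) "log" else "natural",
                  damping = damping))
}

#' Finite-horizon HJB equation (iteroparous terminal-value problem)
#'
#' Backward-in-age implicit sweep from the terminal condition
#' `V(omega, .) = 0`, each step extracting the control by pointwise
#' Hamiltonian maximization (semi-Lagrangian in the control) before the
#' implicit linear solve.
#'
#' @param lh an iteroparous [LifeHistory-class] with finite lifespan.
#' @param lambda discount (candidate fitness).
#' @param grid nodes from [grid1d()].
#' @param ages uniform age grid from 0 up to `omega`.
#' @param cfg an [HjbConfig-class].
#' @return a [ValueGrid-class] with `V` and the policy as
#'   `nodes x ages` matrices.
#' @export
solveFiniteHorizonHjb <- function(lh, lambda, grid, ages, cfg = hjbConfig()) {
  if (lh@fertility@kind != "iteroparous" ||
      !is.finite(lh@fertility@maxLifespan))
    stop("finite-horizon solver needs an iteroparous history with finite ",
         "omega")
  useLog <- lh@sde@logScale
  z <- if (useLog) log(grid) else as.numeric(grid)
  n <- length(z)
  h <- z[2] - z[1]
  nA <- length(ages)
  da <- ages[2] - ages[1]
  if (abs(ages[nA] - lh@fertility@maxLifespan) > 1e-8 * (1 + da))
    stop("age grid must end at omega")
  lo <- lh@sde@controlLower[1L]; hi <- lh@sde@controlUpper[1L]
  co <- .hjbCoefs(lh, grid)   # age enters only through b below
  Vmat <- matrix(0, n, nA)
  Umat <- matrix((lo + hi) / 2, n, nA)
  V <- rep(0, n)
  for (j in (nA - 1L):1L) {
    age <- ages[j]
    b <- lh@fertility@rate(grid, age)
    if (length(b) == 1L) b <- rep(b, n)
    dv <- .dV(V, h)
    Hfun <- function(uv) co$adv(uv) * dv$Vz + co$D(uv) * dv$Vzz -
      (lambda + co$mu(uv)) * V + b
    u <- .argmaxH(Hfun, lo, hi, mode = cfg@controlMode,
                  nControl = cfg@nControl)
    cc <- .coefsAt(co, u, n)
    adv <- cc$adv; D <- cc$D; mu <- cc$mu
    op <- .hjbOperator(adv, D, lambda + mu, h, n, cfg@stencil)
    ## implicit step (I - da L) V_j = V_{j+1} + da b, first-order
    ## one-sided rows at the state boundaries (diffusion dropped there)
    dl <- -da * op$dl; dd <- 1 - da * op$d; du <- -da * op$du
    rhs <- V + da * b
    ## boundary rows: first-order one-sided advection, diffusion dropped
    a1 <- adv[1]
    dd[1] <- 1 + da * (lambda + mu[1]) + da * a1 / h
    du[1] <- -da * a1 / h
    an <- adv[n]
    dd[n] <- 1 + da * (lambda + mu[n]) - da * an / h
    dl[n - 1] <- da * an / h
    V <- .cpp_thomas(dl, dd, du, rhs)
    Vmat[, j] <- V
    Umat[, j] <- u
  }
  Umat[, nA] <- Umat[, nA - 1L]
  new("ValueGrid", nodes = as.numeric(grid), ages = ages, V = Vmat,
      policy = Umat, lambda = lambda, residual = NA_real_,
      iterations = nA - 1L,
      info = list(h = h, coord = if (useLog) "log" else "natural"))
}

## interpolate a stationary/initial-age value at x0
.valueAtX0 <- function(vg, x0) {
  V <- if (is.matrix(vg@V)) vg@V[, 1L] else vg@V
  approx(vg@nodes, V, xout = x0, rule = 2)$y
}

#' Fitness of the optimally controlled life history
#'
#' Outer root search on `lambda` for the scalar condition
#' `V_lambda(x0) = 1`: the optimized objective equals one exactly at the
#' Euler-Lotka root of the optimally controlled life history, which
#' unifies the optimal-life-schedule problem with the demographic model.
#' Each evaluation re-solves the HJB equation at that `lambda`
#' (warm-started from the previous solution); the root is bracketed by
#' outward doubling and closed by bisection with a secant polish.
#'
#' @param lh a [LifeHistory-class] (semelparous: stationary solver;
#'   iteroparous with finite omega: backward solver).
#' @param grid nodes from [grid1d()].
#' @param cfg an [HjbConfig-class].
#' @param ages age grid for the iteroparous solver (default: 400 steps to
#'   omega).
#' @param bracket0 initial `lambda` bracket.
#' @param tol tolerance on `lambda`.
#' @return list with `lambda` (the optimal fitness), `value` (the
#'   [ValueGrid-class] at the root) and `objective` (`V(x0)` there).
#' @export
optimalFitness <- function(lh, grid, cfg = hjbConfig(), ages = NULL,
                           bracket0 = c(-1, 1), tol = 1e-8) {
  semel <- lh@fertility@kind == "semelparous"
  if (!semel && is.null(ages))
    ages <- seq(0, lh@fertility@maxLifespan, length.out = 401L)
  uWarm <- NULL
  solveAt <- function(lam) {
    vg <- if (semel)
      solveStationaryHjb(lh, lam, grid, cfg, uInit = uWarm)
    else solveFiniteHorizonHjb(lh, lam, grid, ages, cfg)
    if (semel) uWarm <<- vg@policy
    vg
  }
  ## below the abscissa of convergence the stationary problem has no
  ## solution; treat solver failure there as an unusable probe
  f <- function(lam) tryCatch(
    .valueAtX0(solveAt(lam), lh@sde@x0[1L]) - 1,
    error = function(e) NA_real_)
  lo <- bracket0[1]; hi <- bracket0[2]
  it <- 0L
  fhi <- f(hi)
  while (!is.na(fhi) && fhi > 0 && it < 60L) {
    hi <- 2 * abs(hi) + 1; fhi <- f(hi); it <- it + 1L
  }
  if (is.na(fhi) || fhi > 0) stop("no upper bracket for the fitness root")
  flo <- f(lo)
  while ((is.na(flo) || flo < 0) && it < 200L) {
    if (is.na(flo)) lo <- (lo + hi) / 2       # back out of the divergence
    else if (flo < 0) { hi <- lo; fhi <- flo; lo <- lo - 2 * abs(lo) - 1 }
    flo <- f(lo); it <- it + 1L
    if (hi - lo < 1e-12)
      stop("extinction range: optimized objective below one for all ",
           "probed lambda")
  }
  if (is.na(flo) || flo < 0)
    stop("extinction range: optimized objective below one for all probed ",
         "lambda")
  r <- uniroot(function(l) f(l), c(lo, hi), tol = tol)
  vg <- solveAt(r$root)
  list(lambda = r$root, value = vg,
       objective = .valueAtX0(vg, lh@sde@x0[1L]))
}

#' Fitness of every constant policy on a control grid
#'
#' The brute-force oracle for the optimality claims: for each constant
#' control the fitness is computed through the demographic route
#' (Fokker-Planck ERS or Monte-Carlo ERS plus the Euler-Lotka root, or
#' the closed-form objective for the registered two-resource family).
#'
#' @param lh a [LifeHistory-class].
#' @param uGrid constant controls to evaluate.
#' @param route `"closed_form"` (two-resource family only), `"pde"` or
#'   `"mc"`.
#' @param grid,ages Fokker-Planck discretization for the PDE route.
#' @param cfg a [SimConfig-class] for the MC route.
#' @return data frame with columns `u` and `lambda`, attribute `argmax`.
#' @export
bruteForceConstantPolicy <- function(lh, uGrid = seq(0, 1, length.out = 101L),
                                     route = c("closed_form", "pde", "mc"),
                                     grid = NULL, ages = NULL, cfg = NULL) {
  route <- match.arg(route)
  lamOf <- switch(route,
    closed_form = {
      if (lh@family != "two_resource_gbm")
        stop("closed-form route needs the two_resource_gbm family")
      pl <- lh@params
      p <- twoResourceParams(m1 = pl$m1, m2 = pl$m2, s1 = pl$s1, s2 = pl$s2,
                             mu0 = pl$mu0, x0 = pl$x0, xm = pl$xm, q = pl$q,
                             b0 = pl$b0, alpha = pl$alpha, omega = pl$omega)
      if (pl$breeding == "semelparous") {
        function(u) solveEulerLotka(function(l) twoResourceObjective(p, u, l),
                                    cumulants = FALSE)@lambda
      } else {
        function(u) solveEulerLotka(function(l)
          iteroparousObjective(p, u, l), cumulants = FALSE)@lambda
      }
    },
    pde = function(u) {
      kern <- solveFokkerPlanck(lh, constantPolicy(u), grid, ages)
      solveEulerLotka(ersFromKernel(kern, lh), cumulants = FALSE)@lambda
    },
    mc = function(u) {
      ens <- simulatePaths(lh, constantPolicy(u), cfg)
      solveEulerLotka(function(l)
        unname(estimateObjectiveMC(ens, lh, l)["value"]),
        cumulants = FALSE)@lambda
    })
  lam <- vapply(uGrid, lamOf, numeric(1))
  out <- data.frame(u = uGrid, lambda = lam)
  attr(out, "argmax") <- uGrid[which.max(lam)]
  out
}
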