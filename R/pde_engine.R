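## Deterministic counterparts of the simulator: Fokker-Planck marching of
## the projection kernel, the Feynman-Kac ERS, the Chapman-Kolmogorov
## (integral-projection) property, and the discretized age-size transition
## matrix model with its eigen-fitness.
##
## Multiplicative dynamics are solved on a log-uniform grid (constant
## coefficients for GBM, better conditioning); the operator is discretized
## in conservative flux form with upwinded advection and central
## differences on the diffusive flux, so mass is conserved exactly up to
## boundary fluxes.  Time stepping is implicit (backward Euler,
## theta = 1), unconditionally stable.

#' Build a one-dimensional solver grid
#'
#' @param from,to domain in natural scale.
#' @param n number of nodes (>= 3).
#' @param spacing `"log-uniform"` for multiplicative dynamics, `"uniform"`
#'   otherwise.
#' @return numeric nodes in natural scale with attribute `spacing`.
#' @export
grid1d <- function(from, to, n, spacing = c("log-uniform", "uniform")) {
  spacing <- match.arg(spacing)
  stopifnot(n >= 3, from < to)
  nodes <- if (spacing == "log-uniform") exp(seq(log(from), log(to),
                                                length.out = n))
           else seq(from, to, length.out = n)
  attr(nodes, "spacing") <- spacing
  nodes
}

## transformed drift/diffusion coefficients on the solving coordinate
.fpCoefs <- function(lh, nodes, u, age = 0) {
  useLog <- lh@sde@logScale
  x <- nodes
  g <- lh@sde@drift(x, u, age)
  sig <- lh@sde@diffusion(x, u, age)
  if (!is.matrix(sig)) sig <- matrix(sig, ncol = lh@sde@nNoise)
  v <- rowSums(sig^2)
  mu <- .muVec(lh, x, u, age, length(x))
  if (useLog) list(adv = g / x - v / (2 * x^2), D = v / (2 * x^2), mu = mu)
  else list(adv = g, D = v / 2, mu = mu)
}

## tridiagonal entries of M = I - dt*L + dt*diag(mu) in flux form;
## dirichletLast: absorbing barrier at the final node (k = 0 there).
.fpMatrix <- function(adv, D, mu, h, dt, dirichletLast = FALSE) {
  n <- length(adv)
  Ldl <- numeric(n - 1); Ldd <- numeric(n); Ldu <- numeric(n - 1)
  ## face f between i and i+1 (i = 1..n-1): flux
  ##   F_f = a_f * k_upwind - (D_{i+1} k_{i+1} - D_i k_i)/h
  ## dk_i/dt += -(F_i - F_{i-1})/h
  af <- (adv[-n] + adv[-1L]) / 2
  for (i in seq_len(n - 1L)) {
    a <- af[i]
    cu <- if (a > 0) c(a, 0) else c(0, a)   # (k_i, k_{i+1}) advective
    ci <- cu[1L] + D[i] / h                 # coefficient of k_i in F_f
    cj <- cu[2L] - D[i + 1L] / h            # coefficient of k_{i+1} in F_f
    ## node i gains -F_f/h ; node i+1 gains +F_f/h
    Ldd[i] <- Ldd[i] - ci / h
    Ldu[i] <- Ldu[i] - cj / h
    Ldl[i] <- Ldl[i] + ci / h
    Ldd[i + 1L] <- Ldd[i + 1L] + cj / h
  }
  dl <- -dt * Ldl
  dd <- 1 - dt * Ldd + dt * mu
  du <- -dt * Ldu
  if (dirichletLast) {
    dd[n] <- 1; dl[n - 1L] <- 0
  }
  list(dl = dl, d = dd, du = du)
}

#' Solve the Fokker-Planck equation for the projection kernel
#'
#' Marches `dk/dtau = -d(adv k)/dz + d2(D k)/dz2 - mu k` on the solving
#' coordinate `z` (log state for multiplicative dynamics) by implicit
#' finite differences.  The Dirac initial condition is a narrow Gaussian
#' surrogate of width twice the grid spacing.  For semelparous histories
#' the mature boundary is absorbing and the absorbed flux is recorded per
#' step.
#'
#' @param lh a [LifeHistory-class] (one state dimension).
#' @param policy a stationary [ControlPolicy-class].
#' @param grid nodes from [grid1d()]; for a semelparous history the last
#'   node must sit on the mature boundary.
#' @param ages output ages (uniformly spaced, starting at 0).
#' @param dt internal time step (default: the age spacing).
#' @return a [ProjectionKernel-class].  Negative-density oscillations
#'   beyond round-off raise a warning advising a finer grid.
#' @export
solveFokkerPlanck <- function(lh, policy, grid, ages, dt = NULL) {
  useLog <- lh@sde@logScale
  z <- if (useLog) log(grid) else as.numeric(grid)
  h <- diff(z)
  if (max(abs(h - h[1])) > 1e-8 * h[1])
    stop("grid must be uniform in the solving coordinate")
  h <- h[1]
  if (any(diff(ages) <= 0) || ages[1] != 0)
    stop("ages must increase from 0")
  dAge <- ages[2] - ages[1]
  if (is.null(dt)) dt <- dAge
  sub <- max(1L, round(dAge / dt))
  dt <- dAge / sub
  semel <- lh@fertility@kind == "semelparous"
  if (semel) {
    face <- .matureFaceValue(lh)
    zb <- if (useLog) log(face$value) else face$value
    if (abs(z[length(z)] - zb) > 1e-8 * (1 + abs(zb)))
      stop("last grid node must sit on the mature boundary")
  }
  u <- controlAt(policy, grid, 0, lh)
  cf <- .fpCoefs(lh, grid, u)
  M <- .fpMatrix(cf$adv, cf$D, cf$mu, h, dt, dirichletLast = semel)
  ## Gaussian surrogate of the Dirac delta at x0
  z0 <- if (useLog) log(lh@sde@x0[1L]) else lh@sde@x0[1L]
  w <- 2 * h
  k0 <- exp(-(z - z0)^2 / (2 * w^2))
  if (semel) k0[length(k0)] <- 0
  k0 <- k0 / (sum(k0) * h)
  nsteps <- (length(ages) - 1L) * sub
  out <- .cpp_fp_march(M$dl, M$d, M$du, k0, cf$mu, h, dt, nsteps, sub)
  dens <- out$states
  if (min(dens) < -1e-8 * max(dens))
    warning("oscillatory (negative) densities detected; refine the grid")
  dens[dens < 0] <- 0
  massAges <- seq(0, by = dt, length.out = nsteps + 1L)
  new("ProjectionKernel", nodes = z, coord = if (useLog) "log" else "natural",
      ages = ages, density = dens, survivorship = out$mass,
      massAges = massAges, absorbedFlux = out$absorbed,
      info = list(dt = dt, h = h, bumpWidth = w, policy = policy,
                  semelparous = semel, u = u))
}

#' ERS from a projection kernel
#'
#' Iteroparous: `F(tau) = integral b(x) k(tau; x0 -> x) dx` on the kernel's
#' stored ages (zero beyond the maximum lifespan).  Semelparous:
#' `F(tau) = q` times the absorbed-flux rate at the mature boundary.
#'
#' @param kernel a [ProjectionKernel-class] solved from `lh`.
#' @param lh the [LifeHistory-class].
#' @return an [ErsCurve-class].
#' @export
ersFromKernel <- function(kernel, lh) {
  if (lh@fertility@kind == "semelparous") {
    face <- .matureFaceValue(lh)
    dt <- kernel@info$dt
    mid <- kernel@massAges[-1L] - dt / 2
    q <- vapply(mid, function(tt) lh@fertility@rate(face$value, tt),
                numeric(1))
    return(ersCurve(ages = mid, values = pmax(q * kernel@absorbedFlux / dt,
                                              0)))
  }
  x <- if (kernel@coord == "log") exp(kernel@nodes) else kernel@nodes
  h <- kernel@info$h
  om <- lh@fertility@maxLifespan
  vals <- vapply(seq_along(kernel@ages), function(j) {
    if (kernel@ages[j] > om) return(0)
    b <- lh@fertility@rate(x, kernel@ages[j])
    if (length(b) == 1L) b <- rep(b, length(x))
    sum(b * kernel@density[, j]) * h
  }, numeric(1))
  ersCurve(ages = kernel@ages, values = pmax(vals, 0))
}

#' Chapman-Kolmogorov residual of the projection kernel
#'
#' The kernel of an autonomous life history is an integral-projection
#' kernel: `k(s + t; x0 -> .) = integral k(t; y -> .) k(s; x0 -> y) dy`.
#' The y-sweep reuses the solver with point initial masses on the grid
#' nodes; the sup-norm of the difference (relative to the peak density)
#' vanishes under grid refinement.
#'
#' @param kernel a [ProjectionKernel-class] (provides grid, dt and policy).
#' @param lh,policy the life history and stationary policy used.
#' @param s,t intermediate and remaining ages (`s + t` within the kernel's
#'   age range; both are rounded to the kernel's internal step).
#' @return scalar relative sup-norm residual.
#' @export
chapmanKolmogorovResidual <- function(kernel, lh, policy, s, t) {
  if (s == 0) return(0)
  dt <- kernel@info$dt
  h <- kernel@info$h
  z <- kernel@nodes
  u <- kernel@info$u
  grid <- if (kernel@coord == "log") exp(z) else z
  cf <- .fpCoefs(lh, grid, u)
  M <- .fpMatrix(cf$adv, cf$D, cf$mu, h, dt,
                 dirichletLast = kernel@info$semelparous)
  ns <- round(s / dt); nt <- round(t / dt)
  ## k(s; x0 -> y): march the stored initial bump
  z0 <- if (kernel@coord == "log") log(lh@sde@x0[1L]) else lh@sde@x0[1L]
  w <- kernel@info$bumpWidth
  k0 <- exp(-(z - z0)^2 / (2 * w^2))
  if (kernel@info$semelparous) k0[length(k0)] <- 0
  k0 <- k0 / (sum(k0) * h)
  ks <- .cpp_fp_march(M$dl, M$d, M$du, k0, cf$mu, h, dt, ns, ns)$states
  ks <- ks[, ncol(ks)]
  kst <- .cpp_fp_march(M$dl, M$d, M$du, k0, cf$mu, h, dt, ns + nt,
                       ns + nt)$states
  kst <- kst[, ncol(kst)]
  ## transition over t restarted from every node, using the same Gaussian
  ## delta surrogate as the solver (an honest discretized composition:
  ## exact unit-vector restarts would reproduce the march identically)
  n <- length(z)
  Kt <- matrix(0, n, n)
  for (j in seq_len(n)) {
    kj <- exp(-(z - z[j])^2 / (2 * w^2))
    if (kernel@info$semelparous) kj[n] <- 0
    sj <- sum(kj) * h
    if (sj == 0) next
    kj <- kj / sj
    Kt[, j] <- .cpp_fp_march(M$dl, M$d, M$du, kj, cf$mu, h, dt, nt,
                             nt)$states[, 2L]
  }
  composed <- as.vector(Kt %*% ks) * h
  max(abs(composed - kst)) / max(kst)
}

#' Assemble the age-size transition matrix model
#'
#' Size-transition blocks are the one-step (age step `da`) kernel between
#' size-class midpoints, obtained by restarting the Fokker-Planck solver
#' from a point mass in each class; fertility blocks place newborns in the
#' size class of `x0` (iteroparous: `da * b(mid)`; semelparous: `q` times
#' the flux absorbed at the mature boundary during the step).  Age classes
#' chain in Leslie fashion.
#'
#' @param lh a [LifeHistory-class].
#' @param policy stationary [ControlPolicy-class].
#' @param da age-class width.
#' @param A number of age classes (iteroparous histories may leave `NULL`
#'   for `ceiling(omega / da)`).
#' @param S number of size classes.
#' @param sizeRange natural-scale range of the size domain (defaults to
#'   the life-history truncation bounds, capped at the mature boundary for
#'   semelparity).
#' @param dt internal Fokker-Planck substep.
#' @param spillThreshold warn when more than this fraction of a one-step
#'   column's mass lands beyond the adjacent size classes (age step too
#'   coarse).
#' @param dropTol entries below `dropTol` are dropped from the sparse
#'   assembly.
#' @return a [TransitionMatrixModel-class].
#' @export
buildAgeSizeTmm <- function(lh, policy, da, A = NULL, S = 60L,
                            sizeRange = NULL, dt = NULL,
                            spillThreshold = 0.5, dropTol = 1e-12) {
  semel <- lh@fertility@kind == "semelparous"
  useLog <- lh@sde@logScale
  if (is.null(A)) {
    om <- lh@fertility@maxLifespan
    if (!is.finite(om)) stop("A must be given for unbounded lifespans")
    A <- as.integer(ceiling(om / da))
  }
  A <- as.integer(A); S <- as.integer(S)
  if (is.null(sizeRange)) {
    sizeRange <- c(lh@space@lower[1L],
                   if (semel) .matureFaceValue(lh)$value
                   else lh@space@upper[1L])
  }
  zr <- if (useLog) log(sizeRange) else sizeRange
  ## S interior classes; the mature boundary adds one Dirichlet node
  edgesZ <- seq(zr[1], zr[2], length.out = S + 1L)
  h <- edgesZ[2] - edgesZ[1]
  midsZ <- edgesZ[-1L] - h / 2
  nodesZ <- if (semel) c(midsZ, zr[2]) else midsZ
  nodes <- if (useLog) exp(nodesZ) else nodesZ
  if (is.null(dt)) dt <- da / 8
  sub <- max(1L, round(da / dt))
  dt <- da / sub
  u <- controlAt(policy, nodes, 0, lh)
  cf <- .fpCoefs(lh, nodes, u)
  M <- .fpMatrix(cf$adv, cf$D, cf$mu, h, dt, dirichletLast = semel)
  os <- .cpp_fp_onestep(M$dl, M$d, M$du, cf$mu, h, dt, sub)
  K <- os$K[seq_len(S), seq_len(S), drop = FALSE]
  absFrac <- os$absorbed[seq_len(S)]
  ## spill check: mass beyond the adjacent classes
  spill <- vapply(seq_len(S), function(j) {
    nb <- max(1L, j - 1L):min(S, j + 1L)
    tot <- sum(K[, j])
    if (tot <= 0) 0 else 1 - sum(K[nb, j]) / tot
  }, numeric(1))
  if (max(spill) > spillThreshold)
    warning("one-step kernel mass spills past neighbor classes (",
            signif(max(spill), 3), "); da may be too coarse")
  mids <- if (useLog) exp(midsZ) else midsZ
  ## newborn mass split linearly between the two size classes bracketing
  ## x0 (keeps the initial size exact on a grid whose midpoints miss it)
  z0 <- if (useLog) log(lh@sde@x0[1L]) else lh@sde@x0[1L]
  jlo <- max(1L, min(S - 1L, findInterval(z0, midsZ)))
  wHi <- min(max((z0 - midsZ[jlo]) / h, 0), 1)
  born <- c(jlo, jlo + 1L)
  bornW <- c(1 - wHi, wHi)
  keepB <- bornW > 0
  born <- born[keepB]; bornW <- bornW[keepB]
  ## assemble sparse block matrix, column convention n(t+da) = M n(t)
  Ksp <- which(K > dropTol, arr.ind = TRUE)
  nK <- nrow(Ksp)
  offs <- S * seq_len(A - 1L)             # row offset of age class a+1
  ii <- rep(offs, each = nK) + rep(Ksp[, 1L], A - 1L)
  jj <- rep(offs - S, each = nK) + rep(Ksp[, 2L], A - 1L)
  vv <- rep(K[Ksp], A - 1L)
  for (a in seq_len(A)) {
    fer <- if (semel) lh@fertility@rate(.matureFaceValue(lh)$value,
                                        (a - 0.5) * da) * absFrac
           else da * lh@fertility@rate(mids, (a - 0.5) * da)
    if (length(fer) == 1L) fer <- rep(fer, S)
    nz <- which(fer > dropTol)
    if (!length(nz)) next
    ii <- c(ii, rep(born, times = length(nz)))
    jj <- c(jj, rep((a - 1L) * S + nz, each = length(born)))
    vv <- c(vv, as.vector(outer(bornW, fer[nz])))
  }
  ## duplicated (i, j) pairs (fertility into the same cell) are summed
  mat <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                              dims = c(A * S, A * S))
  edges <- if (useLog) exp(edgesZ) else edgesZ
  new("TransitionMatrixModel", matrix = mat, da = da, A = A, S = S,
      edges = edges, mids = mids, coord = if (useLog) "log" else "natural",
      info = list(K = K, absorbed = absFrac, born = born, bornW = bornW,
                  spill = max(spill)))
}

#' Dominant-eigenvalue fitness of a transition matrix model
#'
#' Power iteration on the assembled matrix (tolerance `tol` on the
#' eigenvalue); on a detected period-2 cycle the iteration is retried on
#' the shifted matrix `M + c I` (which shares eigenvectors).  The fitness
#' is `log(rho) / da`: the root of the generalized Euler-Lotka
#' (characteristic) equation of the matrix model.
#'
#' @param tmm a [TransitionMatrixModel-class].
#' @param tol convergence tolerance on the eigenvalue.
#' @param maxIter iteration cap.
#' @return scalar fitness with attribute `rho` (dominant eigenvalue per
#'   age step).
#' @export
tmmFitness <- function(tmm, tol = 1e-12, maxIter = 100000L) {
  M <- tmm@matrix
  n <- nrow(M)
  powerIt <- function(shift, cap) {
    v <- rep(1 / n, n)
    rho <- NA_real_; rhoPrev <- Inf
    for (it in seq_len(cap)) {
      w <- as.vector(M %*% v) + shift * v
      nw <- sum(abs(w))
      if (nw == 0) stop("matrix model is nilpotent (zero growth)")
      rho <- nw
      v <- w / nw
      if (abs(rho - rhoPrev) < tol * max(1, rho))
        return(list(rho = rho - shift, it = it, cycled = FALSE))
      rhoPrev <- rho
    }
    list(rho = NA_real_, it = cap, cycled = TRUE)  # periodic structure
  }
  res <- powerIt(0, min(2000L, maxIter))
  if (res$cycled) res <- powerIt(0.5, maxIter)  # shift breaks periodicity
  if (res$cycled || is.na(res$rho))
    stop("power iteration did not converge even on the shifted matrix")
  lam <- log(res$rho) / tmm@da
  attr(lam, "rho") <- res$rho
  lam
}

#' Export a transition matrix model
#'
#' Dense tab-delimited matrix plus a JSON header (`<file>.json`) with the
#' age step and class edges.
#'
#' @param tmm a [TransitionMatrixModel-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeTmm <- function(tmm, file) {
  write.table(as.matrix(tmm@matrix), file, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  jsonlite::write_json(list(da = tmm@da, A = tmm@A, S = tmm@S,
                            edges = tmm@edges, coord = tmm@coord),
                       paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}
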