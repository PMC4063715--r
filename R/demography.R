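## Linear-demographic layer: the Laplace-transform objective, the
## Euler-Lotka fitness root, breeding-age structure and renewal diagnostics.

#' Construct an ERS curve
#'
#' @param ages age grid (may be empty for purely atomic reproduction).
#' @param values `F(tau)` on the grid.
#' @param se optional standard errors.
#' @param atomAges,atomWeights optional point masses (semelparous
#'   maturation atoms).
#' @return an [ErsCurve-class].
#' @export
ersCurve <- function(ages = numeric(), values = numeric(), se = numeric(),
                     atomAges = numeric(), atomWeights = numeric()) {
  new("ErsCurve", ages = as.numeric(ages), values = as.numeric(values),
      se = as.numeric(se), atomAges = as.numeric(atomAges),
      atomWeights = as.numeric(atomWeights))
}

## plain trapezoid integral
.trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

#' Laplace-transform objective of an ERS curve
#'
#' `phi(lambda) = integral exp(-lambda tau) F(tau) dtau`, computed by the
#' trapezoid rule on the grid part plus an exact sum over atoms.  The
#' objective is monotonically decreasing in `lambda`; maximizing it is
#' equivalent to maximizing fitness.
#'
#' @param ers an [ErsCurve-class].
#' @param lambda Laplace argument.
#' @return the objective value (`Inf` flags divergence).
#' @export
objectiveFromErs <- function(ers, lambda) {
  tot <- 0
  if (length(ers@ages))
    tot <- tot + .trapz(ers@ages, exp(-lambda * ers@ages) * ers@values)
  if (length(ers@atomAges))
    tot <- tot + sum(ers@atomWeights * exp(-lambda * ers@atomAges))
  tot
}

#' Solve the Euler-Lotka equation
#'
#' Finds the unique root of `phi(lambda) = 1`, where `phi` is either the
#' Laplace-transform objective of an [ErsCurve-class] or any evaluable
#' monotone-decreasing mapping `lambda -> phi(lambda)`.  The bracket starts
#' at `[bracket0[1], bracket0[2]]` and doubles outward until it straddles
#' one; Brent root finding is followed by a secant polish to drive
#' `|phi - 1|` below `tol`.  The solution carries `R0 = phi(0)`, the
#' breeding-age density (for curve input) and the first four cumulants of
#' breeding age.
#'
#' @param x an [ErsCurve-class] or a function of `lambda`.
#' @param tol tolerance on `phi(lambda) - 1`.
#' @param bracket0 initial bracket, doubled outward as needed.
#' @param cumulants compute breeding-age cumulants (numerical derivatives
#'   of `log phi`); disable for noisy objectives.
#' @return a [DemographicSolution-class].  If `phi < 1` everywhere in the
#'   probed range the model is in the extinction range and an error is
#'   raised with that diagnosis.
#' @examples
#' ## F(tau) = b0 exp(-mu0 tau) with b0 = 2, mu0 = 1 has fitness 1
#' sol <- solveEulerLotka(function(l) 2 / (l + 1))
#' fitness(sol)
#' @export
solveEulerLotka <- function(x, tol = 1e-10, bracket0 = c(-1, 1),
                            cumulants = TRUE) {
  phi <- if (is.function(x)) x else function(l) objectiveFromErs(x, l)
  ## a divergent objective (lambda below the abscissa of convergence)
  ## counts as "above one" for bracketing purposes
  fB <- function(l) {
    v <- phi(l)
    if (!is.finite(v)) Inf else v - 1
  }
  lo <- bracket0[1]; hi <- bracket0[2]
  it <- 0L
  while (fB(hi) > 0 && it < 200L) { hi <- 2 * abs(hi) + 1; it <- it + 1L }
  while (fB(lo) < 0 && it < 400L) {
    lo <- lo - 2 * abs(lo) - 1
    it <- it + 1L
    if (lo < -1e6) break
  }
  if (fB(lo) < 0)
    stop("extinction range: phi(lambda) < 1 over the probed bracket [",
         signif(lo, 4), ", ", signif(hi, 4), "]")
  ## bisection (safe against the divergent left tail), then secant polish
  for (k in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (fB(mid) >= 0) lo <- mid else hi <- mid
    if (hi - lo < .Machine$double.eps * (1 + abs(hi))) break
    it <- it + 1L
  }
  lam <- (lo + hi) / 2
  lamBest <- lam; residBest <- abs(fB(lam))
  for (k in 1:8) {
    fl <- fB(lam)
    if (!is.finite(fl)) break
    if (abs(fl) < residBest) { lamBest <- lam; residBest <- abs(fl) }
    if (abs(fl) < tol) break
    h <- 1e-7 * (1 + abs(lam))
    d <- (fB(lam + h) - fB(lam - h)) / (2 * h)
    if (!is.finite(d) || d == 0) break
    lam <- lam - fl / d
  }
  lam <- lamBest
  resid <- residBest
  if (!is.finite(resid) || resid > 1e-6)
    stop("extinction range: the Euler-Lotka equation has no root above ",
         "the abscissa of convergence (residual ", signif(resid, 3), ")")
  R0 <- phi(0)
  cum <- if (cumulants) {
    vapply(1:4, function(k) breedingAgeCumulants(phi, lam, k), numeric(1))
  } else numeric()
  psiAges <- numeric(); psi <- numeric()
  psiAA <- numeric(); psiAW <- numeric()
  if (is(x, "ErsCurve")) {
    d <- breedingAgeDensity(x, lam)
    psiAges <- d$ages; psi <- d$density
    psiAA <- d$atomAges; psiAW <- d$atomWeights
  }
  new("DemographicSolution", lambda = lam, R0 = R0, psiAges = psiAges,
      psi = psi, psiAtomAges = psiAA, psiAtomWeights = psiAW,
      cumulants = cum,
      diagnostics = list(bracket = c(lo, hi), iterations = it,
                         residual = resid))
}

#' Breeding-age density in the fittest (stable) population
#'
#' `psi(a)` proportional to `exp(-lambda a) F(a)`, normalized.  At the
#' Euler-Lotka root the normalization constant equals one; its deviation is
#' reported as a diagnostic.
#'
#' @param ers an [ErsCurve-class].
#' @param lambda the fitness (Euler-Lotka root).
#' @return list with `ages`, `density`, `atomAges`, `atomWeights` and
#'   `normalization` (the raw integral before normalizing).
#' @export
breedingAgeDensity <- function(ers, lambda) {
  Z <- objectiveFromErs(ers, lambda)
  dens <- if (length(ers@ages)) exp(-lambda * ers@ages) * ers@values / Z
          else numeric()
  aw <- if (length(ers@atomAges))
          ers@atomWeights * exp(-lambda * ers@atomAges) / Z else numeric()
  list(ages = ers@ages, density = dens, atomAges = ers@atomAges,
       atomWeights = aw, normalization = Z)
}

#' Cumulants of breeding age from the objective function
#'
#' The log of the objective is the cumulant generating function of breeding
#' age in the stable population (as a Taylor series around the fitness
#' root); the k-th cumulant is `(-1)^k` times the k-th derivative of
#' `log phi` at `lambda*`.  Derivatives are central finite differences with
#' automatic step control; a step-halving consistency check warns on
#' instability (noisy Monte-Carlo objectives).
#'
#' @param phi evaluable objective `lambda -> phi(lambda)`.
#' @param lambdaStar the Euler-Lotka root.
#' @param k cumulant order, 1 to 4.
#' @return the k-th cumulant (mean for `k = 1`, variance for `k = 2`, ...).
#' @export
breedingAgeCumulants <- function(phi, lambdaStar, k) {
  stopifnot(k >= 1, k <= 4)
  lphi <- function(l) log(phi(l))
  ## step control: the k-th derivative of log phi scales like the k-th
  ## power of the mean breeding age, so the step must resolve 1/mean
  h0 <- 1e-4 * (1 + abs(lambdaStar))
  meanAge <- abs((lphi(lambdaStar + h0) - lphi(lambdaStar - h0)) / (2 * h0))
  h <- min(0.05 * (1 + abs(lambdaStar)), 0.1 / (1 + meanAge))
  d1 <- pracma::fderiv(lphi, lambdaStar, n = k, h = h, method = "central")
  d2 <- pracma::fderiv(lphi, lambdaStar, n = k, h = h / 2, method = "central")
  d <- (4 * d2 - d1) / 3   # Richardson-extrapolated O(h^4) value
  if (abs(d1 - d2) > 0.2 * (1 + abs(d)))
    warning("step instability in cumulant derivative (order ", k, ")")
  (-1)^k * d
}

#' Renewal-equation diagnostic
#'
#' Simulates the offspring dynamics `B(t) = G(t) + int F(a) B(t-a) da`
#' forward from a unit founding cohort and fits the asymptotic slope of
#' `log B(t)` on the tail.  By the Sharp-Lotka-Feller theorem the slope
#' converges to the Euler-Lotka root, so `slope - lambda` is a
#' self-consistency residual; the standard deviation of the tail fit
#' residuals measures the remaining oscillation.
#'
#' @param ers an [ErsCurve-class].
#' @param lambda the Euler-Lotka root to compare against.
#' @param horizon simulated time span (should be several mean breeding
#'   ages; a warning is issued when the transient has clearly not decayed).
#' @param dt time step (atoms are binned to the nearest grid point).
#' @return list with `slope`, `residual` (`slope - lambda`), `amplitude`,
#'   `times`, `births`.
#' @export
renewalResidual <- function(ers, lambda, horizon, dt = NULL) {
  if (is.null(dt)) {
    dt <- if (length(ers@ages) > 1L) min(diff(ers@ages))
          else max(min(ers@atomAges) / 50, 1e-3)
    dt <- min(dt, horizon / 200)
  }
  times <- seq(0, horizon, by = dt)
  K <- length(times)
  ## birth-rate kernel on the grid: curve part + atoms as binned rates
  Fg <- if (length(ers@ages))
          approx(ers@ages, ers@values, xout = times, rule = 2,
                 yleft = 0, yright = 0)$y
        else numeric(K)
  if (length(ers@ages)) Fg[times > max(ers@ages)] <- 0
  if (length(ers@atomAges)) {
    idx <- pmin(pmax(round(ers@atomAges / dt) + 1L, 1L), K)
    for (j in seq_along(idx))
      Fg[idx[j]] <- Fg[idx[j]] + ers@atomWeights[j] / dt
  }
  ## trapezoid convolution; the implicit j = 1 (zero-lag) term is moved
  ## to the left-hand side
  B <- numeric(K)
  B[1] <- Fg[1]
  for (k in 2:K) {
    conv <- if (k > 2)
      sum(Fg[2:(k - 1)] * B[(k - 1):2]) + Fg[k] * B[1] / 2
    else Fg[k] * B[1] / 2
    B[k] <- (Fg[k] + dt * conv) / (1 - dt * Fg[1] / 2)
  }
  tail_i <- which(times >= horizon / 2 & B > 0)
  if (length(tail_i) < 5L) {
    warning("horizon too short for the renewal transient to decay")
    return(list(slope = NA_real_, residual = NA_real_,
                amplitude = NA_real_, times = times, births = B))
  }
  fit <- lm(log(B[tail_i]) ~ times[tail_i])
  slope <- unname(coef(fit)[2])
  amp <- sd(residuals(fit))
  list(slope = slope, residual = slope - lambda, amplitude = amp,
       times = times, births = B)
}

#' @importFrom stats residuals
NULL

#' Export an ERS curve or demographic solution as a table
#'
#' @param x an [ErsCurve-class] or [DemographicSolution-class].
#' @param file path of the tab-delimited output.
#' @return the written data frame, invisibly.
#' @export
writeDemographyTable <- function(x, file) {
  df <- if (is(x, "ErsCurve")) {
    rbind(
      if (length(x@ages))
        data.frame(age = x@ages, value = x@values, kind = "curve"),
      if (length(x@atomAges))
        data.frame(age = x@atomAges, value = x@atomWeights, kind = "atom"))
  } else if (is(x, "DemographicSolution")) {
    rbind(
      if (length(x@psiAges))
        data.frame(age = x@psiAges, value = x@psi, kind = "density"),
      if (length(x@psiAtomAges))
        data.frame(age = x@psiAtomAges, value = x@psiAtomWeights,
                   kind = "atom"))
  } else stop("unsupported object")
  write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
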