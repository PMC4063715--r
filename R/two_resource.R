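## Two-resource utilization model: closed forms for the optimal resource
## mix under semelparous and iteroparous breeding, plus constructors that
## expose the model to the generic simulation / PDE / HJB machinery.
##
## Size is a controlled geometric Brownian motion
##   dx = (u m1 + (1-u) m2) x da + u s1 x dB1 + (1-u) s2 x dB2,
## with independent resource noises, so the effective variance rate is
## (u^2 s1^2 + (1-u)^2 s2^2) x^2.  Mortality is the constant baseline mu0
## (control-free).  Every closed form below is entered once here and unit
## tests verify it against its defining equation and against the generic
## solvers, so a slip is caught structurally.

#' Construct two-resource model parameters
#'
#' Defaults give the package's reference configuration: a generalist
#' semelparous species (convexity index 0.4, generalist window (0, 0.6)).
#'
#' @param m1,m2 drift rates of R1 and R2 (`m1 > m2`).
#' @param s1,s2 diffusion intensities (`s1 > s2 >= 0`).
#' @param mu0 baseline mortality rate.
#' @param x0 initial size.
#' @param xm mature size (semelparity).
#' @param q fertility released at maturation (semelparity).
#' @param b0,alpha allometric fertility rate and exponent (iteroparity).
#' @param omega maximum lifespan (iteroparity).
#' @return a [TwoResourceParams-class].
#' @examples
#' p <- twoResourceParams()
#' convexityIndex(p)
#' @export
twoResourceParams <- function(m1 = 0.2, m2 = 0.1, s1 = 0.5, s2 = 0.2,
                              mu0 = 0.05, x0 = 1, xm = 2^(1 / 0.4), q = 2,
                              b0 = 0.1, alpha = 0.4, omega = 30) {
  new("TwoResourceParams", m1 = m1, m2 = m2, s1 = s1, s2 = s2, mu0 = mu0,
      x0 = x0, xm = xm, q = q, b0 = b0, alpha = alpha, omega = omega)
}

#' Effective drift and variance of a resource mix
#'
#' @param p a [TwoResourceParams-class].
#' @param u utilization weight on R1 in `[0, 1]`.
#' @return list with `g` (drift rate) and `s2` (variance rate
#'   `u^2 s1^2 + (1-u)^2 s2^2`; independent noises add in variance).
#' @export
mixCoefficients <- function(p, u) {
  list(g = u * p@m1 + (1 - u) * p@m2,
       s2 = u^2 * p@s1^2 + (1 - u)^2 * p@s2^2)
}

#' Controlled SDE of the two-resource model
#'
#' @param p a [TwoResourceParams-class].
#' @return a [ControlledSDE-class] with two independent noise channels and
#'   control box `[0, 1]`.
#' @export
twoResourceSde <- function(p) {
  controlledSDE(
    drift = function(x, u, a) (u * p@m1 + (1 - u) * p@m2) * x,
    diffusion = function(x, u, a) cbind(u * p@s1 * x, (1 - u) * p@s2 * x),
    nNoise = 2L, controlLower = 0, controlUpper = 1, x0 = p@x0,
    logScale = TRUE)
}

#' Two-resource life history
#'
#' @param p a [TwoResourceParams-class].
#' @param breeding breeding system.
#' @return a [LifeHistory-class] tagged with family `"two_resource_gbm"`.
#' @export
twoResourceLifeHistory <- function(p, breeding = c("semelparous",
                                                   "iteroparous")) {
  breeding <- match.arg(breeding)
  sde <- twoResourceSde(p)
  mort <- mortality(function(x, u, a) p@mu0)
  if (breeding == "semelparous") {
    sp <- stateSpace(p@x0 * exp(-12), p@xm,
                     boundary = c("truncation", "absorbing-maturity"))
    fert <- fertility("semelparous", function(x, a) p@q)
  } else {
    sp <- stateSpace(p@x0 * exp(-12), p@x0 * exp(15))
    fert <- fertility("iteroparous", function(x, a) p@b0 * x^p@alpha,
                      maxLifespan = p@omega)
  }
  lifeHistory(sde, mort, fert, sp, family = "two_resource_gbm",
              params = list(m1 = p@m1, m2 = p@m2, s1 = p@s1, s2 = p@s2,
                            mu0 = p@mu0, x0 = p@x0, xm = p@xm, q = p@q,
                            b0 = p@b0, alpha = p@alpha, omega = p@omega,
                            breeding = breeding))
}

## ---- single-resource closed forms --------------------------------------

#' First-passage Laplace objective of a single-resource GBM
#'
#' For size growing as a GBM with drift rate `g` and intensity `s`, killed
#' at rate `mu0`, the Laplace-transform objective of the semelparous ERS is
#' `q * (x0/xm)^theta(lambda)` with `theta` the principal root of the
#' characteristic quadratic
#' `s^2 theta^2 / 2 + (g - s^2/2) theta - (lambda + mu0) = 0`.
#' The limit `s -> 0` gives the deterministic hitting value
#' `q * exp(-(lambda + mu0) * log(xm/x0) / g)`.
#'
#' @param g,s drift rate and diffusion intensity.
#' @param mu0 mortality rate.
#' @param x0,xm initial and mature size.
#' @param q maturation fertility.
#' @param lambda Laplace argument (the candidate fitness).
#' @return the objective value; `Inf` (flagged divergent) when `lambda`
#'   lies below the abscissa of convergence, `NA` for a deterministic model
#'   that never matures.
#' @export
singleResourceObjective <- function(g, s, mu0, x0, xm, q, lambda) {
  delta <- log(xm / x0)
  rho <- lambda + mu0
  if (s == 0) {
    if (g <= 0) return(NA_real_)  # never reaches xm
    return(q * exp(-rho * delta / g))
  }
  gb <- g - s^2 / 2
  disc <- gb^2 + 2 * s^2 * rho
  if (disc < 0) return(Inf)  # below the abscissa of convergence
  theta <- (-gb + sqrt(disc)) / s^2
  q * exp(-theta * delta)
}

#' Convexity index of a semelparous life history
#'
#' `n = log(q) / log(xm / x0)`: the power exponent at which the value
#' function meets the Euler-Lotka root.  It grows with the maturation
#' fertility and shrinks with the size ratio `xm / x0` (it is invariant
#' under a common rescaling of both sizes), and it governs risk appetite:
#' internal stochasticity lowers the fitness if and only if `n < 1`.
#'
#' @param p a [TwoResourceParams-class].
#' @return positive scalar.
#' @export
convexityIndex <- function(p) {
  if (abs(p@xm - p@x0) < .Machine$double.eps * p@x0)
    stop("degenerate model: xm equals x0")
  log(p@q) / log(p@xm / p@x0)
}

#' Closed-form semelparous fitness of a single resource
#'
#' `lambda = g n + s^2 n (n - 1) / 2 - mu0` with `n` the convexity index;
#' the unique root of the first-passage objective equalling one.  The
#' principal-branch condition `g + s^2 (n - 1/2) >= 0` is required for the
#' root to exist; otherwise the model is in the extinction range and `NA`
#' is returned with attribute `viable = FALSE`.
#'
#' @param g,s drift rate and diffusion intensity of the (possibly mixed)
#'   resource.
#' @param p a [TwoResourceParams-class] providing `mu0`, `x0`, `xm`, `q`.
#' @return the fitness, with attribute `viable`.
#' @export
singleResourceFitness <- function(g, s, p) {
  n <- convexityIndex(p)
  lam <- g * n + 0.5 * s^2 * n * (n - 1) - p@mu0
  viable <- s == 0 || (g + s^2 * (n - 0.5)) >= 0
  if (!viable) {
    out <- NA_real_
    attr(out, "viable") <- FALSE
    return(out)
  }
  attr(lam, "viable") <- TRUE
  lam
}

## lambda(u) of a constant mix, closed form (semelparous)
.twoResourceLambdaU <- function(p, u, n = convexityIndex(p)) {
  mc <- mixCoefficients(p, u)
  mc$g * n + 0.5 * mc$s2 * n * (n - 1) - p@mu0
}

#' Closed-form objective of a constant two-resource mix
#'
#' @param p a [TwoResourceParams-class].
#' @param u constant utilization weight on R1.
#' @param lambda Laplace argument.
#' @return the semelparous first-passage objective of the mixed GBM.
#' @export
twoResourceObjective <- function(p, u, lambda) {
  mc <- mixCoefficients(p, u)
  singleResourceObjective(mc$g, sqrt(mc$s2), p@mu0, p@x0, p@xm, p@q, lambda)
}

#' Generalist window of the convexity index
#'
#' The index range on which the optimal mix is interior:
#' `(0, 1 - (m1 - m2)/s1^2)` (empty when the drift advantage of R1 exceeds
#' its variance `s1^2`).
#'
#' @param p a [TwoResourceParams-class].
#' @return numeric `c(n_lo, n_hi)`.
#' @export
generalistWindow <- function(p) {
  c(0, max(0, 1 - (p@m1 - p@m2) / p@s1^2))
}

## ---- semelparous optimal mix -------------------------------------------

#' Optimal resource utilization of a semelparous species
#'
#' With the power ansatz `V(x) = C x^nu` the stationary HJB equation forces
#' `nu` to equal the convexity index `n` at the Euler-Lotka root, and the
#' quadratic-in-u Hamiltonian has the interior extremum
#' `u* = (s2^2 + (m1 - m2)/(1 - n)) / (s1^2 + s2^2)`, clamped to `[0, 1]`.
#' The optimal utilization is constant over the lifetime.  For `n >= 1`
#' stochasticity raises fitness and the R2 weight is zero (R1 specialist);
#' the R2 specialist is never selected.
#'
#' @param p a [TwoResourceParams-class].
#' @return a [MixResult-class]; `info` carries the unclamped mix, the
#'   value-function constant `C = q / xm^n`, and the R2 weight.
#' @export
semelparousOptimalMix <- function(p) {
  n <- convexityIndex(p)
  win <- generalistWindow(p)
  if (p@s1 == 0 && p@s2 == 0) {
    uUnc <- 1  # deterministic dominance of the higher drift
  } else if (n >= 1) {
    uUnc <- 1
  } else {
    uUnc <- (p@s2^2 + (p@m1 - p@m2) / (1 - n)) / (p@s1^2 + p@s2^2)
  }
  u <- min(max(uUnc, 0), 1)
  lam <- .twoResourceLambdaU(p, u, n)
  ## structural consistency: the mixed coefficients must reproduce lambda
  mc <- mixCoefficients(p, u)
  lamChk <- singleResourceFitness(mc$g, sqrt(mc$s2), p)
  if (is.na(lamChk) || abs(lamChk - lam) > 1e-10)
    stop("internal inconsistency between mix and single-resource fitness")
  regime <- if (u >= 1) "R1-specialist" else if (u <= 0) "R2-specialist"
            else "generalist"
  new("MixResult", uStar = u, lambdaStar = lam, exponent = n,
      regime = regime, window = win,
      info = list(uUnclamped = uUnc, C = p@q / p@xm^n, r2Weight = 1 - u))
}

## ---- iteroparous closed forms ------------------------------------------

## kappa(alpha): optimized growth exponent rate
##   kappa = sup_u [ g(u) alpha + s2(u) alpha (alpha - 1) / 2 ]
## lambdaTilde = kappa - mu0 is the semelparous fitness function evaluated
## at index alpha (the formal bridge between the two breeding systems).
.iteroKappa <- function(p, u) {
  mc <- mixCoefficients(p, u)
  mc$g * p@alpha + 0.5 * mc$s2 * p@alpha * (p@alpha - 1)
}

#' Iteroparous objective (Laplace transform of the allometric ERS)
#'
#' Under the optimal (or any constant) mix the ERS is
#' `F(tau) = b0 x0^alpha exp(lambdaTilde tau)` on `[0, omega]`, with
#' `lambdaTilde` the semelparous fitness function evaluated at the
#' allometric exponent, so
#' `phi(lambda) = b0 x0^alpha (1 - exp(-(lambda - lambdaTilde) omega)) /
#' (lambda - lambdaTilde)`.
#'
#' @param p a [TwoResourceParams-class].
#' @param u constant utilization weight.
#' @param lambda Laplace argument.
#' @return the objective value.
#' @export
iteroparousObjective <- function(p, u, lambda) {
  lt <- .iteroKappa(p, u) - p@mu0
  z <- lambda - lt
  amp <- p@b0 * p@x0^p@alpha
  if (z == 0) return(amp * p@omega)
  amp * -expm1(-z * p@omega) / z
}

#' Optimal resource utilization of an iteroparous species
#'
#' With allometric fertility `b(x) = b0 x^alpha` the finite-horizon HJB
#' equation is solved by the separable ansatz `V(a, x) = f(a) x^alpha`, so
#' the optimal mix has the same form as the semelparous one with `alpha`
#' playing the role of the convexity index:
#' `u* = (s2^2 + (m1 - m2)/(1 - alpha)) / (s1^2 + s2^2)` clamped to
#' `[0, 1]`, independent of age and of the fitness (mortality carries no
#' control).  The age factor is
#' `f(a) = b0 (1 - exp(-(lambda + mu0 - kappa)(omega - a))) /
#' (lambda + mu0 - kappa)` with `kappa` the optimized growth exponent rate.
#' The Euler-Lotka equation built from this value function is
#' transcendental; the exact fitness is found numerically, and the
#' infinite-lifespan root `lambdaTilde + b0 x0^alpha` is reported as the
#' monotone bound the fitness approaches as `omega` grows.
#'
#' @param p a [TwoResourceParams-class].
#' @return a [MixResult-class]; `info` carries `lambdaTilde`, the value
#'   function `V(a, x)` at the fitness root, and the infinite-lifespan
#'   bound.
#' @export
iteroparousOptimalMix <- function(p) {
  a <- p@alpha
  win <- generalistWindow(p)
  if (p@s1 == 0 && p@s2 == 0) {
    uUnc <- 1
  } else if (a >= 1) {
    uUnc <- 1
  } else {
    uUnc <- (p@s2^2 + (p@m1 - p@m2) / (1 - a)) / (p@s1^2 + p@s2^2)
  }
  u <- min(max(uUnc, 0), 1)
  kap <- .iteroKappa(p, u)
  lt <- kap - p@mu0
  ## exact fitness: numerical root of the transcendental Euler-Lotka eq.
  sol <- solveEulerLotka(function(l) iteroparousObjective(p, u, l))
  lam <- sol@lambda
  Vfun <- local({
    b0 <- p@b0; alpha <- a; om <- p@omega; den <- lam + p@mu0 - kap
    function(age, x) {
      if (abs(den) < 1e-12) return(b0 * x^alpha * (om - age))
      b0 * x^alpha * (1 - exp(-den * (om - age))) / den
    }
  })
  regime <- if (u >= 1) "R1-specialist" else if (u <= 0) "R2-specialist"
            else "generalist"
  new("MixResult", uStar = u, lambdaStar = lam, exponent = a,
      regime = regime, window = win,
      info = list(uUnclamped = uUnc, lambdaTilde = lt, kappa = kap,
                  value = Vfun, lambdaInfty = lt + p@b0 * p@x0^a,
                  r2Weight = 1 - u, solution = sol))
}

#' Breeding-age structure of the optimal iteroparous life history
#'
#' Closed-form basic reproductive number
#' `R0 = b0 x0^alpha (exp(lambdaTilde omega) - 1) / lambdaTilde`, the
#' breeding-age density `psi(a) = r exp(r a) / (exp(r omega) - 1)` on
#' `[0, omega]` with exponent `lambdaTilde - lambda*` (exactly uniform
#' when it vanishes, J-shaped/increasing when positive), and the smallest viable
#' lifespan (`R0 >= 1`), located by monotone bisection.
#'
#' @param p a [TwoResourceParams-class].
#' @param mix result of [iteroparousOptimalMix()] (recomputed when
#'   missing).
#' @return list with `R0`, `exponent`, `shape` (`"increasing"`,
#'   `"uniform"`, `"decreasing"`), `density` (a function on `[0, omega]`),
#'   and `minViableOmega`.
#' @export
iteroparousDemography <- function(p, mix = iteroparousOptimalMix(p)) {
  lt <- mix@info$lambdaTilde
  amp <- p@b0 * p@x0^p@alpha
  R0 <- if (abs(lt) < 1e-12) amp * p@omega else amp * expm1(lt * p@omega) / lt
  r <- lt - mix@lambdaStar
  ## the root is numerical: exponents below its tolerance are uniform
  if (abs(r) < 1e-8) r <- 0
  om <- p@omega
  density <- local({
    r <- r; om <- om
    function(a) {
      out <- numeric(length(a))
      inside <- a >= 0 & a <= om
      if (r == 0) out[inside] <- 1 / om
      else out[inside] <- r * exp(r * a[inside]) / expm1(r * om)
      out
    }
  })
  shape <- if (r == 0) "uniform" else if (r > 0) "increasing"
           else "decreasing"
  R0ofOmega <- function(w) {
    if (abs(lt) < 1e-12) amp * w else amp * expm1(lt * w) / lt
  }
  minOmega <- NA_real_
  hi <- 1
  while (R0ofOmega(hi) < 1 && hi < 1e7) hi <- hi * 2
  if (R0ofOmega(hi) >= 1) {
    lo <- 0
    for (i in 1:200) {  # monotone bisection: R0 increases in omega
      mid <- (lo + hi) / 2
      if (R0ofOmega(mid) >= 1) hi <- mid else lo <- mid
      if (hi - lo < 1e-10 * (1 + hi)) break
    }
    minOmega <- hi
  }
  list(R0 = R0, exponent = r, shape = shape, density = density,
       minViableOmega = minOmega)
}

## ---- maturation-age density (semelparous) ------------------------------

#' Maturation-age density of a semelparous mix
#'
#' The first-passage-time density of the mixed GBM from `x0` to `xm` with
#' killing at rate `mu0`.  On the log scale this is Brownian motion with
#' drift, so the density is inverse-Gaussian; exponential tilting by the
#' killing turns the unnormalized (killed) density into
#' `(x0/xm)^theta(0)` times an inverse-Gaussian with upgraded drift
#' `sqrt(gbar^2 + 2 s^2 mu0)`.  The unnormalized density integrates to
#' `R0 / q`.
#'
#' @param p a [TwoResourceParams-class].
#' @param u constant utilization weight on R1.
#' @return list with `density` (normalized over maturing paths), `cdf`,
#'   `unnormalized`, the `normalizer` `R0/q`, and `pointMass` (the
#'   deterministic maturation age, non-`NA` only when both intensities
#'   vanish).
#' @export
matureAgeDensity <- function(p, u) {
  mc <- mixCoefficients(p, u)
  delta <- log(p@xm / p@x0)
  if (mc$s2 == 0) {
    if (mc$g <= 0) stop("degenerate model: never matures (g <= 0, s = 0)")
    Tm <- delta / mc$g
    return(list(density = NULL, cdf = function(t) as.numeric(t >= Tm),
                unnormalized = NULL, normalizer = exp(-p@mu0 * Tm),
                pointMass = Tm))
  }
  s2 <- mc$s2
  gb <- mc$g - s2 / 2
  gstar <- sqrt(gb^2 + 2 * s2 * p@mu0)  # tilted drift
  norm <- exp(-delta * (gstar - gb) / s2)  # (x0/xm)^theta(0) = R0/q
  dens <- local({
    delta <- delta; gstar <- gstar; s2 <- s2
    function(t) {
      out <- numeric(length(t))
      pos <- t > 0
      tp <- t[pos]
      out[pos] <- delta / sqrt(2 * pi * s2 * tp^3) *
        exp(-(delta - gstar * tp)^2 / (2 * s2 * tp))
      out
    }
  })
  cdf <- local({
    mu_m <- delta / gstar; lam_sh <- delta^2 / s2
    function(t) {
      out <- numeric(length(t))
      pos <- t > 0
      tp <- t[pos]
      z1 <- sqrt(lam_sh / tp) * (tp / mu_m - 1)
      z2 <- -sqrt(lam_sh / tp) * (tp / mu_m + 1)
      out[pos] <- stats::pnorm(z1) + exp(2 * lam_sh / mu_m) * stats::pnorm(z2)
      pmin(pmax(out, 0), 1)
    }
  })
  unnorm <- local({
    dens <- dens; norm <- norm
    function(t) norm * dens(t)
  })
  list(density = dens, cdf = cdf, unnormalized = unnorm, normalizer = norm,
       pointMass = NA_real_)
}

## ---- sensitivity of fitness to stochasticity ---------------------------

#' Sign of the fitness response to internal stochasticity
#'
#' Sweeps the convexity index `n` (by moving the mature size at fixed
#' fertility, so `n` is inversely proportional to `log(xm/x0)`), computes
#' the single-resource fitness as a numerical Euler-Lotka root of the
#' first-passage objective, and estimates `d lambda* / d s` by central
#' differences at a small intensity.  The sign change is then located by
#' bisection on `n`: stochasticity lowers fitness below the threshold and
#' raises it above.
#'
#' @param p a [TwoResourceParams-class] (drift `m1`, `mu0`, `x0`, `q` are
#'   used).
#' @param nValues indices to tabulate.
#' @param sProbe small intensity at which the derivative is probed.
#' @param h central-difference step.
#' @return list with `table` (`n`, `dlambda_ds`, `sign`) and `threshold`
#'   (the located sign-change index).
#' @export
stochasticitySensitivityScan <- function(p, nValues = seq(0.4, 1.6, by = 0.2),
                                         sProbe = 0.1, h = 0.05) {
  g <- p@m1
  lamNum <- function(n, s) {
    xm <- p@x0 * p@q^(1 / n)
    sol <- solveEulerLotka(function(l)
      singleResourceObjective(g, s, p@mu0, p@x0, xm, p@q, l))
    sol@lambda
  }
  dlam <- function(n) (lamNum(n, sProbe + h) - lamNum(n, sProbe - h)) / (2 * h)
  tab <- data.frame(n = nValues,
                    dlambda_ds = vapply(nValues, dlam, numeric(1)))
  tab$sign <- sign(tab$dlambda_ds)
  lo <- 0.5; hi <- 1.5
  stopifnot(dlam(lo) < 0, dlam(hi) > 0)
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (dlam(mid) < 0) lo <- mid else hi <- mid
  }
  list(table = tab, threshold = (lo + hi) / 2)
}

#' Optimal mature size for a size-dependent maturation fertility
#'
#' For a fertility-rate family `q(x)` with a unique interior optimum the
#' optimal mature size maximizes the first-passage objective
#' `q(xm) (x0/xm)^theta(lambda)` over `xm`; located by one-dimensional
#' golden-section maximization.
#'
#' @param p a [TwoResourceParams-class] (drift/intensity taken from the
#'   `u = 1` resource unless `u` is given).
#' @param lambda discount (candidate fitness).
#' @param qFun fertility-rate family; default `q0 x exp(-x / xs)`.
#' @param u constant mix.
#' @param upper search bound.
#' @return list with `xm` and the objective value there.
#' @export
optimalMatureSize <- function(p, lambda, qFun = NULL, u = 1,
                              upper = 50 * p@x0) {
  mc <- mixCoefficients(p, u)
  if (is.null(qFun)) {
    q0 <- p@q; xs <- 2 * p@xm
    qFun <- function(x) q0 * x * exp(-x / xs)
  }
  obj <- function(xm) {
    qFun(xm) / p@q *
      singleResourceObjective(mc$g, sqrt(mc$s2), p@mu0, p@x0, xm, p@q, lambda)
  }
  opt <- stats::optimize(obj, c(p@x0 * (1 + 1e-8), upper), maximum = TRUE)
  list(xm = opt$maximum, value = opt$objective)
}
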