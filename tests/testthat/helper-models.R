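## Shared fixtures: reference parameter sets and small builders.

## package reference configuration (generalist semelparous species)
refParams <- function() twoResourceParams()

## faster-maturing single-resource-like configuration used for the
## cross-formulation checks (mean maturation age about 4)
corrParams <- function() {
  twoResourceParams(m1 = 0.3, m2 = 0.1, s1 = 0.2, s2 = 0.05, mu0 = 0.1,
                    x0 = 1, xm = 3, q = 2)
}

## an iteroparous configuration whose breeding-age density is J-shaped
jShapeParams <- function() {
  twoResourceParams(alpha = 0.8, b0 = 0.02, omega = 30)
}

## uncontrolled single-resource GBM life history (degenerate control box)
gbmLifeHistory <- function(g = 0.3, s = 0.2, mu0 = 0.1, x0 = 1, xm = 3,
                           q = 2, breeding = "semelparous", b0 = 0.1,
                           alpha = 0.5, omega = Inf) {
  sde <- controlledSDE(
    drift = function(x, u, a) g * x,
    diffusion = function(x, u, a) s * x,
    nNoise = 1L, controlLower = 0, controlUpper = 0, x0 = x0,
    logScale = TRUE)
  mort <- mortality(function(x, u, a) mu0)
  if (breeding == "semelparous") {
    sp <- stateSpace(x0 * exp(-12), xm,
                     boundary = c("truncation", "absorbing-maturity"))
    fert <- fertility("semelparous", function(x, a) q)
  } else {
    sp <- stateSpace(x0 * exp(-12), x0 * exp(15))
    fert <- fertility("iteroparous", function(x, a) b0 * x^alpha,
                      maxLifespan = omega)
  }
  lifeHistory(sde, mort, fert, sp)
}

## simple deterministic path on a uniform age grid
detPath <- function(horizon, dt, fn) {
  ages <- seq(0, horizon, by = dt)
  list(ages = ages, states = fn(ages))
}

## exponential ERS curve F = b0 exp(-mu0 a) on a fine grid
expErs <- function(b0, mu0, amax = 40, n = 4001L) {
  a <- seq(0, amax, length.out = n)
  ersCurve(ages = a, values = b0 * exp(-mu0 * a))
}

atomErs <- function(T, w) ersCurve(atomAges = T, atomWeights = w)

## weighted Kolmogorov-Smirnov distance of maturation ages against a cdf
weightedKs <- function(times, weights, cdf, upper) {
  o <- order(times)
  tt <- times[o]; w <- weights[o]
  emp <- cumsum(w) / sum(w)
  theo <- cdf(tt) / cdf(upper)
  max(abs(emp - theo))
}
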