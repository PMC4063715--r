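#' @import methods
#' @importFrom stats rnorm runif sd approx lm coef ecdf setNames uniroot
#' @importFrom utils head tail write.table read.table
NULL

## Central S4 containers.  A life history bundles a controlled diffusion for
## the individual state, a mortality rate, and a fertility schedule; every
## solver in the package consumes that bundle.

#' State space of a controlled life history
#'
#' Describes the domain of the individual state vector: its dimension,
#' truncation bounds, and the role of each boundary face.  Faces marked
#' `"absorbing-maturity"` make up the mature boundary where semelparous
#' reproduction happens.
#'
#' @slot dim number of state variables.
#' @slot lower,upper numeric truncation bounds per dimension; an effectively
#'   infinite face is stored as a finite truncation bound.
#' @slot boundary character vector of length `2 * dim`, faces ordered
#'   `lower1, upper1, lower2, ...`, each one of `"truncation"`,
#'   `"reflecting"`, `"absorbing-maturity"`.
#' @exportClass StateSpace
setClass("StateSpace",
  representation(dim = "integer", lower = "numeric", upper = "numeric",
                 boundary = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@dim < 1L) msg <- c(msg, "dim must be >= 1")
    if (length(object@lower) != object@dim || length(object@upper) != object@dim)
      msg <- c(msg, "lower/upper must have length dim")
    if (any(object@lower >= object@upper))
      msg <- c(msg, "lower must be < upper componentwise")
    if (length(object@boundary) != 2L * object@dim)
      msg <- c(msg, "boundary must have length 2*dim")
    ok <- c("truncation", "reflecting", "absorbing-maturity")
    if (!all(object@boundary %in% ok))
      msg <- c(msg, paste("boundary kinds must be one of:",
                          paste(ok, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
  })

#' Controlled Ito diffusion for the individual state
#'
#' The state obeys `dx = g(x,u,a) da + sigma(x,u,a) dB` with an
#' M-dimensional Brownian motion and a control `u` constrained to a box.
#'
#' @slot drift function `(x, u, a) -> numeric(dim)`.
#' @slot diffusion function `(x, u, a) -> dim x nNoise matrix` (a plain
#'   numeric vector is accepted for one state).
#' @slot nNoise number of independent noise channels M.
#' @slot controlLower,controlUpper box bounds of the compact convex control
#'   set.
#' @slot x0 common initial state, strictly inside the domain.
#' @slot logScale when `TRUE` the dynamics are multiplicative (GBM-like) and
#'   simulators/PDE solvers work on the log state to preserve positivity.
#' @exportClass ControlledSDE
setClass("ControlledSDE",
  representation(drift = "function", diffusion = "function",
                 nNoise = "integer", controlLower = "numeric",
                 controlUpper = "numeric", x0 = "numeric",
                 logScale = "logical"),
  validity = function(object) {
    msg <- NULL
    if (object@nNoise < 1L) msg <- c(msg, "nNoise must be >= 1")
    if (length(object@controlLower) != length(object@controlUpper))
      msg <- c(msg, "control box bounds must have equal length")
    if (any(object@controlLower > object@controlUpper))
      msg <- c(msg, "control set is empty")
    if (is.null(msg)) TRUE else msg
  })

#' Mortality rate
#'
#' @slot rate function `(x, u, a) -> nonnegative scalar` hazard.
#' @exportClass Mortality
setClass("Mortality", representation(rate = "function"))

#' Fertility schedule
#'
#' Semelparous fertility is a point event: a yield `q(x*)` released when the
#' state first reaches the mature boundary, after which the individual dies.
#' Iteroparous fertility is a nonnegative rate `b(x, a)` active up to the
#' maximum lifespan `omega`; with `omega = Inf` iteroparous survivorship
#' reduces to the general survivorship.
#'
#' @slot kind `"semelparous"` or `"iteroparous"`.
#' @slot rate function `(x, a) -> nonnegative scalar`; for semelparity it is
#'   evaluated on the mature boundary.
#' @slot maxLifespan maximum lifespan `omega` (iteroparous; may be `Inf`).
#' @exportClass Fertility
setClass("Fertility",
  representation(kind = "character", rate = "function",
                 maxLifespan = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@kind %in% c("semelparous", "iteroparous"))
      msg <- c(msg, "kind must be 'semelparous' or 'iteroparous'")
    if (object@maxLifespan <= 0) msg <- c(msg, "maxLifespan must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' A controlled stochastic life history
#'
#' The bundle (growth diffusion, fertility, mortality) on a common state
#' space; the object every solver in the package consumes.
#'
#' @slot sde a [ControlledSDE-class].
#' @slot mortality a [Mortality-class].
#' @slot fertility a [Fertility-class].
#' @slot space a [StateSpace-class].
#' @slot family registered model family name (e.g. `"two_resource_gbm"`) or
#'   `""` for ad-hoc models.
#' @slot params named numeric parameters of the family (empty for ad-hoc).
#' @exportClass LifeHistory
setClass("LifeHistory",
  representation(sde = "ControlledSDE", mortality = "Mortality",
                 fertility = "Fertility", space = "StateSpace",
                 family = "character", params = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@sde@x0) != object@space@dim)
      msg <- c(msg, "x0 must have length space@dim")
    if (any(object@sde@x0 <= object@space@lower) ||
        any(object@sde@x0 >= object@space@upper))
      msg <- c(msg, "x0 must lie strictly inside the state space")
    if (object@fertility@kind == "semelparous" &&
        !any(object@space@boundary == "absorbing-maturity"))
      msg <- c(msg, "semelparous life history needs an absorbing-maturity face")
    if (is.null(msg)) TRUE else msg
  })

#' Control policy
#'
#' A mapping from state (and possibly age) to a point of the control set.
#' Constant, grid-tabulated (linear interpolation in state) and closed-form
#' variants are supported; evaluations are clamped to the control box.
#'
#' @slot kind `"constant"`, `"grid"` or `"closed_form"`.
#' @slot value the control point, a `list(nodes=, controls=)` table, or a
#'   function `(x, a) -> control`.
#' @slot stationary `TRUE` when the policy ignores age (autonomous optimal
#'   transition).
#' @exportClass ControlPolicy
setClass("ControlPolicy",
  representation(kind = "character", value = "ANY", stationary = "logical"),
  validity = function(object) {
    if (!object@kind %in% c("constant", "grid", "closed_form"))
      "kind must be constant/grid/closed_form" else TRUE
  })

#' Monte-Carlo simulation settings
#'
#' @slot dt Euler-Maruyama step.
#' @slot horizon simulated age horizon.
#' @slot nPaths number of sample paths.
#' @slot seed integer seed; path chunks draw sub-seeds from it so that
#'   increasing `nPaths` appends new paths without reshuffling old ones.
#' @slot bridgeCorrection apply the Brownian-bridge crossing-probability
#'   correction for first-passage detection (reduces discretization bias of
#'   maturation times for diffusive growth); off by default.
#' @slot storeEvery thin factor for stored states.
#' @slot chunkSize paths per seeded chunk.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(dt = "numeric", horizon = "numeric", nPaths = "integer",
                 seed = "integer", bridgeCorrection = "logical",
                 storeEvery = "integer", chunkSize = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@dt <= 0 || object@horizon <= 0) msg <- c(msg, "dt, horizon > 0")
    if (object@dt > object@horizon / 10)
      msg <- c(msg, "dt must be small relative to horizon")
    if (object@nPaths < 1L) msg <- c(msg, "nPaths >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' Ensemble of simulated life-history paths
#'
#' @slot ages stored age grid (thinned by `storeEvery`).
#' @slot states `nPaths x length(ages)` matrix of the (one-dimensional)
#'   state, or an `nPaths x ages x dim` array for several states.  For
#'   semelparous histories paths are frozen at their maturation state.
#' @slot weights accumulated survivorship weight per path and stored age;
#'   non-increasing along each row.
#' @slot maturityTimes first crossing ages of the mature boundary
#'   (semelparous; `NA` when not reached within the horizon).
#' @slot maturityWeights survivorship weight at maturation.
#' @slot escaped number of paths flagged for escaping the truncation bound.
#' @slot seed,config provenance.
#' @exportClass PathEnsemble
setClass("PathEnsemble",
  representation(ages = "numeric", states = "ANY", weights = "matrix",
                 maturityTimes = "numeric", maturityWeights = "numeric",
                 escaped = "integer", seed = "integer", config = "list"))

#' Expectation of reproductive success (ERS) curve
#'
#' `F(tau)`: expected fertility times survivorship at age `tau`; the net
#' reproduction function of demography.  Semelparous reproduction is a
#' collection of point masses (maturation-age atoms with weights `q * S`),
#' iteroparous reproduction a curve on an age grid.  Both parts may be
#' present; the represented measure is their sum.
#'
#' @slot ages age grid (may be empty for purely atomic curves).
#' @slot values `F` on the grid, nonnegative.
#' @slot se optional standard errors (Monte-Carlo estimates).
#' @slot atomAges,atomWeights optional point masses.
#' @exportClass ErsCurve
setClass("ErsCurve",
  representation(ages = "numeric", values = "numeric", se = "numeric",
                 atomAges = "numeric", atomWeights = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@values) != length(object@ages))
      msg <- c(msg, "values must match ages")
    if (length(object@values) && any(object@values < -1e-12))
      msg <- c(msg, "ERS must be nonnegative")
    if (length(object@atomAges) != length(object@atomWeights))
      msg <- c(msg, "atom ages/weights must match")
    if (length(object@atomWeights) && any(object@atomWeights < 0))
      msg <- c(msg, "atom weights must be nonnegative")
    if (is.null(msg)) TRUE else msg
  })

#' Demographic solution for one life history and policy
#'
#' @slot lambda fitness: the dominant root of the Euler-Lotka equation.
#' @slot R0 basic reproductive number `phi(0)`.
#' @slot psiAges,psi breeding-age density on a grid (continuous part).
#' @slot psiAtomAges,psiAtomWeights atomic part of the breeding-age density.
#' @slot cumulants first four cumulants of breeding age in the stable
#'   population.
#' @slot diagnostics bracket, iterations, residual, normalization.
#' @exportClass DemographicSolution
setClass("DemographicSolution",
  representation(lambda = "numeric", R0 = "numeric", psiAges = "numeric",
                 psi = "numeric", psiAtomAges = "numeric",
                 psiAtomWeights = "numeric", cumulants = "numeric",
                 diagnostics = "list"))

#' Projection kernel on a one-dimensional grid
#'
#' Transition density with survivorship `k(tau; x0 -> x)` from the
#' Fokker-Planck equation.  Mass at each age equals total survivorship; for
#' semelparous histories the flux absorbed at the mature boundary is
#' recorded per age.
#'
#' @slot nodes grid nodes in the solving coordinate.
#' @slot coord `"log"` or `"natural"`.
#' @slot ages stored ages.
#' @slot density `length(nodes) x length(ages)` matrix.
#' @slot survivorship total mass per marched step age.
#' @slot massAges ages of the (unthinned) mass/flux series.
#' @slot absorbedFlux absorbed mass per step (semelparous; zero otherwise).
#' @slot info solver metadata (dt, policy, initial bump width).
#' @exportClass ProjectionKernel
setClass("ProjectionKernel",
  representation(nodes = "numeric", coord = "character", ages = "numeric",
                 density = "matrix", survivorship = "numeric",
                 massAges = "numeric", absorbedFlux = "numeric",
                 info = "list"))

#' Age-size transition matrix model
#'
#' Leslie-like block matrix: fertility blocks in the first age-row, one-step
#' size-transition blocks on the age sub-diagonal.  Column convention: entry
#' `(i, j)` is the per-step contribution of class `j` to class `i`, so the
#' population updates as `n(t + da) = M n(t)` and size-transition columns
#' sum to at most one (mortality leak).
#'
#' @slot matrix assembled sparse square matrix of order `A * S`.
#' @slot da age step; `A` age classes `[a*da, (a+1)*da)` (half-open).
#' @slot A,S numbers of age and size classes.
#' @slot edges,mids size-class edges and midpoints (natural scale; classes
#'   are indexed by midpoint).
#' @slot coord solving coordinate of the underlying kernel.
#' @slot info metadata.
#' @exportClass TransitionMatrixModel
setClass("TransitionMatrixModel",
  representation(matrix = "ANY", da = "numeric", A = "integer", S = "integer",
                 edges = "numeric", mids = "numeric", coord = "character",
                 info = "list"))

#' Value function on a state (x age) grid
#'
#' @slot nodes state grid (natural scale).
#' @slot ages age grid (length 0 for the stationary problem).
#' @slot V value function: vector (stationary) or `nodes x ages` matrix.
#' @slot policy extracted Markovian control, same shape as `V`.
#' @slot lambda discount rate used.
#' @slot residual final HJB residual (sup norm).
#' @slot iterations policy-iteration count (stationary).
#' @slot info solver metadata.
#' @exportClass ValueGrid
setClass("ValueGrid",
  representation(nodes = "numeric", ages = "numeric", V = "ANY",
                 policy = "ANY", lambda = "numeric", residual = "numeric",
                 iterations = "integer", info = "list"))

#' HJB solver settings
#'
#' @slot scheme `"policy_iteration"` (stationary) or `"backward"` (finite
#'   horizon).
#' @slot controlMode `"analytic"` (closed-form extremum of the
#'   quadratic-in-u Hamiltonian, clamped to the box) or `"grid"`.
#' @slot nControl number of control grid points in grid mode (>= 2).
#' @slot tol convergence tolerance on the value function.
#' @slot maxIter maximum policy iterations.
#' @slot damping damping factor on policy updates.
#' @slot stencil first-derivative discretization: `"hybrid"` (central
#'   below the cell Peclet limit, monotone one-sided above; the default),
#'   `"central"`, or `"upwind"`.
#' @exportClass HjbConfig
setClass("HjbConfig",
  representation(scheme = "character", controlMode = "character",
                 nControl = "integer", tol = "numeric", maxIter = "integer",
                 damping = "numeric", stencil = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@tol <= 0) msg <- c(msg, "tol must be > 0")
    if (object@controlMode == "grid" && object@nControl < 2L)
      msg <- c(msg, "grid mode needs nControl >= 2")
    if (is.null(msg)) TRUE else msg
  })

#' Parameters of the two-resource utilization model
#'
#' Body size grows as a controlled geometric Brownian motion mixing a
#' high-risk/high-return resource R1 (`m1`, `s1`) and a low-risk/low-return
#' resource R2 (`m2`, `s2`) with independent noises; the control `u` in
#' `[0, 1]` is the utilization weight on R1.
#'
#' @slot m1,m2 drift rates (per unit time), `m1 > m2`.
#' @slot s1,s2 diffusion intensities, `s1 > s2 >= 0`.
#' @slot mu0 baseline mortality rate (control-free).
#' @slot x0 initial size.
#' @slot xm mature size (semelparity).
#' @slot q fertility released at maturation (semelparity).
#' @slot b0,alpha allometric fertility `b(x) = b0 * x^alpha` with exponent
#'   in (0, 1) (iteroparity).
#' @slot omega maximum lifespan (iteroparity).
#' @exportClass TwoResourceParams
setClass("TwoResourceParams",
  representation(m1 = "numeric", m2 = "numeric", s1 = "numeric",
                 s2 = "numeric", mu0 = "numeric", x0 = "numeric",
                 xm = "numeric", q = "numeric", b0 = "numeric",
                 alpha = "numeric", omega = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!(object@m1 > object@m2)) msg <- c(msg, "need m1 > m2")
    if (!(object@s1 > object@s2 && object@s2 >= 0))
      msg <- c(msg, "need s1 > s2 >= 0")
    if (object@mu0 < 0) msg <- c(msg, "mu0 must be >= 0")
    if (!(object@xm > object@x0 && object@x0 > 0))
      msg <- c(msg, "need xm > x0 > 0")
    if (object@q < 0 || object@b0 < 0) msg <- c(msg, "q, b0 must be >= 0")
    if (object@alpha <= 0 || object@alpha >= 1)
      msg <- c(msg, "alpha must lie in (0, 1)")
    if (object@omega <= 0) msg <- c(msg, "omega must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Optimal resource mix
#'
#' @slot uStar optimal utilization weight on the risky resource R1, in
#'   `[0, 1]` (the R2 weight `1 - uStar` is reported alongside in `info`).
#' @slot lambdaStar fitness of the optimally controlled life history.
#' @slot exponent power exponent of the value function (the convexity index
#'   for semelparity, the allometric exponent for iteroparity).
#' @slot regime `"R1-specialist"`, `"generalist"` or `"R2-specialist"`.
#' @slot window generalist bounds `(n_lo, n_hi)` of the index.
#' @slot info extra quantities (unclamped mix, value-function constant,
#'   bounds).
#' @exportClass MixResult
setClass("MixResult",
  representation(uStar = "numeric", lambdaStar = "numeric",
                 exponent = "numeric", regime = "character",
                 window = "numeric", info = "list"),
  validity = function(object) {
    msg <- NULL
    if (object@uStar < 0 || object@uStar > 1)
      msg <- c(msg, "uStar must lie in [0, 1]")
    okreg <- switch(object@regime,
      "R1-specialist" = object@uStar == 1,
      "generalist" = object@uStar > 0 && object@uStar < 1,
      "R2-specialist" = object@uStar == 0, FALSE)
    if (!okreg) msg <- c(msg, "regime inconsistent with uStar")
    if (is.null(msg)) TRUE else msg
  })
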