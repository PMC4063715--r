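---
title: "Optimal life schedules under internal stochasticity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal life schedules under internal stochasticity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoclife)
```

# The model

`stoclife` treats an individual life course as a controlled Ito diffusion.
The state $x$ (body size, in the applications) evolves with age $a$ as

$$ dx = g(x, u, a)\,da + \sigma(x, u, a)\,dB_a, $$

where $u$ is a control chosen from a compact box (here $u \in [0,1]$), $B$
an $M$-dimensional Brownian motion, and the randomness is *internal*:
every individual runs its own independent realization, as opposed to
environmental (year-to-year) stochasticity, which the package does not
model.  Two further ingredients complete a life history:

* a mortality hazard $\mu(x, u, a) \ge 0$, giving the survivorship
  $S(a) = \exp(-\int_0^a \mu\,dt)$ along a path;
* a fertility schedule, which defines the breeding system.
  *Semelparity*: reproduction is a single yield $q(x^*)$ released when
  the state first reaches the mature boundary $x^*$, after which the
  individual dies.  *Iteroparity*: a nonnegative breeding rate $b(x, a)$
  is active up to a maximum lifespan $\omega$; with $\omega = \infty$
  only accidental death remains.

The demographic bridge is the **expectation of reproductive success**
(ERS), $F(\tau)$ = expected fertility times survivorship at age $\tau$
(the net reproduction function), and its Laplace transform, the
**objective function**

$$ \phi(\lambda) = \int_0^\infty e^{-\lambda \tau} F(\tau)\, d\tau. $$

$\phi$ is monotonically decreasing, $\phi(0) = R_0$, and the unique root
of the **Euler–Lotka equation** $\phi(\lambda) = 1$ is the fitness
(intrinsic rate of natural increase).  Because $\phi$ is decreasing, any
control that increases $\phi$ increases the fitness, so the optimal life
schedule can be found by maximizing $\phi$ at fixed $\lambda$ and then
closing the loop with the root condition — this is what
`optimalFitness()` does, and it is the package's central computation: an
optimal-control problem and a linear demographic model solved as one.

Four formulations of the same demography are implemented and checked
against each other:

1. **Path simulation** (`simulatePaths`, `estimateErsMC`,
   `estimateObjectiveMC`): seeded Euler–Maruyama ensembles with
   survivorship carried as a multiplicative weight.
2. **Fokker–Planck projection kernel** (`solveFokkerPlanck`,
   `ersFromKernel`): the transition density with survivorship
   $k(\tau; x_0 \to x)$, marched by implicit finite differences; its mass
   is the survivorship and, for semelparity, the flux absorbed at $x^*$
   is the maturation-age measure.
3. **Age–size transition matrix model** (`buildAgeSizeTmm`,
   `tmmFitness`): Leslie-like block matrix whose size-transition blocks
   are one-step kernels; the fitness is $\log \rho / \Delta a$ with
   $\rho$ the dominant eigenvalue.
4. **Renewal equation** (`renewalResidual`): offspring dynamics
   $B(t) = G(t) + \int F(a) B(t-a)\,da$, whose asymptotic log-slope is
   again the fitness (Sharp–Lotka–Feller behaviour).

`compareFormulations()` runs all four on one model and reports the
pairwise gaps; the gaps shrink under grid refinement, which is the
correspondence that justifies treating the path-wise formulation as a
linear demographic model.

# Optimal control: HJB equations

The value function $V(a, x)$ — the supremum over controls of the
discounted remaining reproduction — satisfies a Hamilton–Jacobi–Bellman
(HJB) equation built from the control Hamiltonian

$$ H(u) = g\,V_x + \tfrac12 \sigma^2 V_{xx} - (\lambda + \mu) V + b. $$

* **Semelparity** leads to a *stationary* Dirichlet problem:
  $\sup_u H(u) = 0$ on $(0, x^*)$ with $V(x^*) = q(x^*)$
  (`solveStationaryHjb`, Howard policy iteration).  Because mature ages
  are themselves random, the optimal policy is age-independent
  (autonomous optimal transition).
* **Iteroparity** with finite $\omega$ leads to a *terminal-value*
  problem marched backward in age from $V(\omega, \cdot) = 0$
  (`solveFiniteHorizonHjb`).

The pointwise control update exploits that the Hamiltonian of the
applications is exactly quadratic in $u$: the analytic mode fits the
quadratic through three control points, verifies it at a fourth, and
clamps the extremum to the box (falling back to a control grid with a
warning when the verification fails).  Ties break toward the smaller
control, so results are deterministic.

Numerical choices, made once and kept:

* Multiplicative (GBM-like) dynamics are solved and simulated on the log
  state, where the operator has constant coefficients and positivity is
  structural.
* The spatial operator uses a hybrid stencil: central differences where
  the cell Peclet number $|g| h / (2D)$ is at most one, monotone
  one-sided differences otherwise.  A monotone, consistent, stable
  implicit scheme converges to the viscosity solution, so no smoothness
  is assumed; a pure-central and a pure-upwind variant are available via
  `hjbConfig(stencil=)` for convergence studies.
* The lower state boundary of a degenerate diffusion ($x \to 0$ for GBM)
  is a natural boundary where the operator vanishes; the truncated
  domain imposes $V = 0$ well below the initial state (eight to twelve
  log-units).  The induced error decays exponentially into the interior;
  tests read the policy only where the value function is resolved
  (within about two log-units below $x_0$), because where $V$ is
  numerically zero the Hamiltonian no longer identifies the control.
* The Dirac initial condition of the kernel is a Gaussian surrogate of
  width twice the grid spacing, a convergence-tested standard choice.
* Policy iteration is damped (factor 0.5 by default) and raises the
  damping once if the value update grows; convergence is declared on a
  value-function fixed point.
* The outer fitness root (`optimalFitness`, `solveEulerLotka`) brackets
  by outward doubling and closes with bisection plus a secant polish; a
  divergent objective (below the abscissa of convergence) counts as
  "above one" during bracketing, and a bisection limit that still fails
  the residual check is reported as an extinction-range model rather
  than returned as a root.

# The two-resource application

The bundled application is a risk-portfolio problem in growth: size is a
GBM mixing a high-risk/high-return resource R1 $(m_1, s_1)$ and a
low-risk/low-return resource R2 $(m_2, s_2)$ with *independent* noises,

$$ dx = (u m_1 + (1-u) m_2)x\,da + u s_1 x\,dB_1 + (1-u) s_2 x\,dB_2, $$

so the variance rate of a mix is $(u^2 s_1^2 + (1-u)^2 s_2^2) x^2$ and
mortality is a constant, control-free $\mu_0$.  The convention
throughout: **u is the weight on R1**, and every result also reports the
R2 weight so no reader depends on the polarity.

For a single resource the objective has the first-passage closed form
$\phi(\lambda) = q\,(x_0/x_m)^{\theta(\lambda)}$ with $\theta$ the
principal root of
$\tfrac12 s^2\theta^2 + (g - \tfrac12 s^2)\theta - (\lambda + \mu_0) = 0$.
Writing $n = \ln q / \ln(x_m/x_0)$ — the **convexity index**, large when
fertility is high or the size ratio small — the fitness is

$$ \lambda = g\,n + \tfrac12 s^2 n(n-1) - \mu_0, $$

so internal stochasticity *lowers* fitness exactly when $n < 1$ and
*raises* it when $n > 1$ (Jensen's inequality on the power-law value
function).  For the controlled mix, the power ansatz $V = C x^\nu$
forces $\nu = n$ at the fitness root and yields the constant optimal
utilization

$$ u^* = \frac{s_2^2 + (m_1 - m_2)/(1 - n)}{s_1^2 + s_2^2}, \qquad
   \text{clamped to } [0, 1], $$

with the generalist window $n \in (0,\, 1 - (m_1 - m_2)/s_1^2)$; above
it the species is an R1 specialist, and the R2 specialist is never
selected.  Iteroparity with allometric fertility $b(x) = b_0 x^\alpha$
admits the separable ansatz $V(a, x) = f(a) x^\alpha$: the same mix
formula holds with $\alpha$ in the role of $n$ (equal indices give
identical mixes across breeding systems), the age factor is
$f(a) = b_0 (1 - e^{-(\lambda + \mu_0 - \kappa)(\omega - a)}) /
(\lambda + \mu_0 - \kappa)$ with $\kappa$ the optimized growth-exponent
rate, and the Euler–Lotka equation becomes transcendental — the exact
fitness is found numerically, increases monotonically in $\omega$, and
approaches the infinite-lifespan root
$\tilde\lambda + b_0 x_0^\alpha$ reported as `lambdaInfty`.  The
breeding-age density is exponential in age on $[0, \omega]$ with
exponent $\tilde\lambda - \lambda^*$: increasing ("J-shaped") when
positive, exactly uniform when zero.  The semelparous maturation-age
density is inverse-Gaussian on the log scale; killing at rate $\mu_0$
tilts the drift to $\sqrt{\bar g^2 + 2 s^2 \mu_0}$ and scales the mass
to $R_0/q$ (`matureAgeDensity`).

Every closed form is entered once, in `R/two_resource.R`, and tested
against its defining equation (the exponent against the Hamiltonian
algebra, the mix against a brute-force fitness grid, the density against
simulated maturation ages), so a transcription slip is caught
structurally rather than by coincidence of numbers.

```{r example}
p <- twoResourceParams()
semelparousOptimalMix(p)
```

# Reference configuration and what the generator emulates

The package's reference configuration (`twoResourceParams()` defaults)
is $m_1 = 0.2$, $m_2 = 0.1$, $s_1 = 0.5$, $s_2 = 0.2$, $\mu_0 = 0.05$,
$x_0 = 1$, $q = 2$, with $x_m$ set so the convexity index is $0.4$ —
inside the generalist window $(0, 0.6)$ — and, for iteroparity,
$b_0 = 0.1$, $\alpha = 0.4$, $\omega = 30$.  These values were chosen
once as a biologically plausible slow-growing, weakly persistent species
(fitness near zero, mean maturation age around 16 age units; all ages
share one arbitrary unit and rates are per that unit).  Sweeps move the
index by moving $x_m$ at fixed $q$, so the index is inversely
proportional to the log size ratio.

Synthetic ensembles emulate internal stochasticity only: independent
individuals, no density dependence, no environmental fluctuations, no
parameter uncertainty.  Passing tests therefore demonstrate numerical
correctness of the machinery on diffusion-driven life histories, not
that real populations satisfy the model's assumptions (constant
mortality, uncorrelated resource noise, GBM growth).

Simulation conventions: survivorship is carried as a continuous weight
rather than by killing paths (lower variance; killing remains available
through the ensemble weights); semelparous paths freeze at the first
boundary hit, with the crossing age linearly interpolated and, when
`bridgeCorrection` is on, within-step crossings detected by the
Brownian-bridge probability $\exp(-2 d_0 d_1 / (\sigma^2 dt))$ — this
removes most of the $O(\sqrt{dt})$ first-passage bias and is used by the
acceptance checks; bridge-detected crossings are timed at mid-step.  One
global seed spawns per-chunk sub-seeds (chunks of $10^4$ paths), so
enlarging an ensemble appends paths without reshuffling existing ones.

# Problem sizes and accuracy

The shipped tests and the acceptance script use: $10^5$ paths at
$dt = 0.02$ for the Monte-Carlo/first-passage comparison (agreement
within three standard errors), $2 \times 10^4$ paths plus a 281-node
kernel and a $320 \times 90$ age–size matrix for the three-way fitness
correspondence (pairwise gaps near $6 \times 10^{-3}$, converging under
refinement), 321 log-spaced nodes for the stationary HJB solve (value
error about $0.4\%$ of the supremum, policy within $10^{-4}$ of the
closed form on the resolved region), and $10^4$ paths for the
Kolmogorov–Smirnov check of the maturation-age density (distance about
$0.006$–$0.015$, bound $0.02$).  These sizes are the package's reference
resolutions; each has a refinement test demonstrating the error trend.

Known limitations: one state dimension for the PDE/HJB solvers (the
simulator accepts more); box control sets only; no control-dependent
mortality in the applications (the Hamiltonian interface admits it); no
environmental stochasticity; the transition-matrix assembly warns rather
than adapts when one-step kernel mass spills far past neighbouring size
classes.  The stochastic Maximum Principle route (co-states/backward
SDEs) is intentionally not implemented; the HJB route covers the same
solutions.
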