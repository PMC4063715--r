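## Constructors and pathwise evaluation of controlled life histories.

#' Build a state space
#'
#' @param lower,upper numeric truncation bounds per dimension.
#' @param boundary character vector of face kinds, ordered
#'   `lower1, upper1, lower2, upper2, ...`; defaults to truncation faces.
#' @return a [StateSpace-class].
#' @examples
#' stateSpace(0, 10, boundary = c("truncation", "absorbing-maturity"))
#' @export
stateSpace <- function(lower, upper,
                       boundary = rep("truncation", 2L * length(lower))) {
  new("StateSpace", dim = length(lower), lower = as.numeric(lower),
      upper = as.numeric(upper), boundary = boundary)
}

#' Build a controlled diffusion
#'
#' @param drift function `(x, u, a)` returning the drift vector.
#' @param diffusion function `(x, u, a)` returning the `dim x nNoise`
#'   diffusion matrix (numeric vector accepted for one state).
#' @param nNoise number of independent Brownian channels.
#' @param controlLower,controlUpper control box bounds.
#' @param x0 initial state.
#' @param logScale simulate/solve on the log state (multiplicative
#'   dynamics).
#' @return a [ControlledSDE-class].
#' @export
controlledSDE <- function(drift, diffusion, nNoise = 1L,
                          controlLower = 0, controlUpper = 1,
                          x0, logScale = FALSE) {
  new("ControlledSDE", drift = drift, diffusion = diffusion,
      nNoise = as.integer(nNoise), controlLower = as.numeric(controlLower),
      controlUpper = as.numeric(controlUpper), x0 = as.numeric(x0),
      logScale = isTRUE(logScale))
}

#' Build a mortality rate
#' @param rate function `(x, u, a) -> nonnegative hazard`.
#' @return a [Mortality-class].
#' @export
mortality <- function(rate) new("Mortality", rate = rate)

#' Build a fertility schedule
#'
#' @param kind `"semelparous"` or `"iteroparous"`.
#' @param rate function `(x, a)`; the maturation yield `q(x*)` for
#'   semelparity (evaluated on the mature boundary), the breeding rate
#'   `b(x, a)` for iteroparity.
#' @param maxLifespan maximum lifespan `omega` (iteroparity; default `Inf`).
#' @return a [Fertility-class].
#' @export
fertility <- function(kind = c("iteroparous", "semelparous"), rate,
                      maxLifespan = Inf) {
  new("Fertility", kind = match.arg(kind), rate = rate,
      maxLifespan = maxLifespan)
}

#' Assemble a life history
#'
#' @param sde a [ControlledSDE-class].
#' @param mortality a [Mortality-class].
#' @param fertility a [Fertility-class].
#' @param space a [StateSpace-class].
#' @param family,params optional registered model-family tag and its
#'   parameters (used by the config round-trip and fast model-aware paths).
#' @return a [LifeHistory-class].
#' @export
lifeHistory <- function(sde, mortality, fertility, space,
                        family = "", params = list()) {
  new("LifeHistory", sde = sde, mortality = mortality, fertility = fertility,
      space = space, family = family, params = params)
}

## ---- policies ----------------------------------------------------------

#' Control policies
#'
#' `constantPolicy` fixes one control point; `gridPolicy` tabulates controls
#' on state nodes with linear interpolation (optionally per age column);
#' `closedFormPolicy` wraps an evaluable mapping `(x, a) -> u`.  Every
#' evaluation is clamped to the control box of the life history it is used
#' with.
#'
#' @param u a control point.
#' @param nodes state nodes of the table.
#' @param controls control values at `nodes` (vector), or a
#'   `length(nodes) x length(ages)` matrix.
#' @param ages age grid for age-dependent tables (`NULL` for stationary).
#' @param fn function `(x, a) -> u`.
#' @param stationary whether the mapping ignores age (autonomous optimal
#'   transitions are stationary).
#' @return a [ControlPolicy-class].
#' @export
constantPolicy <- function(u) {
  new("ControlPolicy", kind = "constant", value = as.numeric(u),
      stationary = TRUE)
}

#' @rdname constantPolicy
#' @export
gridPolicy <- function(nodes, controls, ages = NULL) {
  new("ControlPolicy", kind = "grid",
      value = list(nodes = nodes, controls = controls, ages = ages),
      stationary = is.null(ages))
}

#' @rdname constantPolicy
#' @export
closedFormPolicy <- function(fn, stationary = TRUE) {
  new("ControlPolicy", kind = "closed_form", value = fn,
      stationary = isTRUE(stationary))
}

#' Evaluate a policy at states and an age
#'
#' Vectorized over a numeric vector of (one-dimensional) states; the result
#' is clamped to the control box of `lh`.
#'
#' @param policy a [ControlPolicy-class].
#' @param x numeric states.
#' @param a scalar age.
#' @param lh the [LifeHistory-class] providing the control box.
#' @return numeric controls, one per state.
#' @export
controlAt <- function(policy, x, a, lh) {
  u <- switch(policy@kind,
    constant = rep(policy@value[1L], length(x)),
    grid = {
      tab <- policy@value
      ctr <- tab$controls
      if (!is.null(tab$ages) && is.matrix(ctr)) {
        j <- findInterval(a, tab$ages, all.inside = TRUE)
        ctr <- ctr[, j]
      }
      approx(tab$nodes, ctr, xout = x, rule = 2)$y
    },
    closed_form = {
      f <- policy@value
      vapply(x, function(xi) f(xi, a), numeric(1))
    })
  pmin(pmax(u, lh@sde@controlLower[1L]), lh@sde@controlUpper[1L])
}

## ---- pathwise operations ----------------------------------------------

.checkPath <- function(path) {
  stopifnot(is.list(path), !is.null(path$ages), !is.null(path$states))
  if (path$ages[1L] != 0 || any(diff(path$ages) <= 0))
    stop("path ages must increase strictly from 0")
  invisible(path)
}

.matureFaceValue <- function(lh) {
  ## 1-D convenience: the threshold of the (single) absorbing face
  b <- lh@space@boundary
  i <- which(b == "absorbing-maturity")
  if (!length(i)) return(NULL)
  i <- i[1L]
  dim_i <- (i + 1L) %/% 2L
  side <- if (i %% 2L == 1L) "lower" else "upper"
  list(dim = dim_i, side = side,
       value = if (side == "lower") lh@space@lower[dim_i]
               else lh@space@upper[dim_i])
}

.pathStates <- function(path) {
  s <- path$states
  if (is.matrix(s)) s[, 1L] else s
}

#' Survivorship accumulated along a discretized path
#'
#' Integrates the mortality hazard along the path by the trapezoid rule and
#' returns `exp(-integral)` at the final path age, applying the iteroparous
#' hard lifespan cutoff (zero beyond `omega`) and the semelparous
#' post-maturation indicator (zero after the first boundary hit).
#'
#' @param lh a [LifeHistory-class].
#' @param path `list(ages=, states=)` with ages strictly increasing from 0.
#' @param policy a [ControlPolicy-class] (mortality may be control
#'   dependent).
#' @return survivorship in `[0, 1]`.
#' @export
survivorshipAlongPath <- function(lh, path, policy = constantPolicy(
    lh@sde@controlLower[1L])) {
  .checkPath(path)
  x <- .pathStates(path)
  a <- path$ages
  mu <- vapply(seq_along(a), function(i) {
    ui <- controlAt(policy, x[i], a[i], lh)
    lh@mortality@rate(x[i], ui, a[i])
  }, numeric(1))
  if (any(mu < 0)) stop("invalid model: negative mortality evaluation")
  S <- exp(-.trapzCum(a, mu))
  endAge <- a[length(a)]
  if (lh@fertility@kind == "iteroparous") {
    if (endAge > lh@fertility@maxLifespan) return(0)
    return(S[length(S)])
  }
  tm <- maturityTime(lh, path)
  if (!is.na(tm) && endAge > tm) return(0)
  S[length(S)]
}

## cumulative trapezoid integral of y over x, same length as x
.trapzCum <- function(x, y) {
  n <- length(x)
  if (n == 1L) return(0)
  c(0, cumsum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2))
}

#' First maturation age of a semelparous path
#'
#' Scans the path for the first crossing of an absorbing-maturity face and
#' linearly interpolates the crossing age between the bracketing grid
#' points.
#'
#' @inheritParams survivorshipAlongPath
#' @return the maturation age, or `NA` when the path does not reach the
#'   mature boundary within its horizon.
#' @export
maturityTime <- function(lh, path) {
  if (lh@fertility@kind != "semelparous")
    stop("maturityTime is defined for semelparous life histories")
  .checkPath(path)
  face <- .matureFaceValue(lh)
  x <- .pathStates(path)
  a <- path$ages
  crossed <- if (face$side == "upper") x >= face$value else x <= face$value
  i <- which(crossed)[1L]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(a[1L])
  frac <- (face$value - x[i - 1L]) / (x[i] - x[i - 1L])
  a[i - 1L] + frac * (a[i] - a[i - 1L])
}

#' Fertility evaluated along a path
#'
#' Iteroparous histories yield the breeding rate `b(x(a), a)` at each grid
#' age up to `min(horizon, omega)` (zero beyond); semelparous histories
#' yield a single point mass `q(x*)` at the maturation age.
#'
#' @inheritParams survivorshipAlongPath
#' @return a list with `ages`, `rate` (per-age values; all zero for
#'   semelparity), and for semelparous paths `atomAge` / `atomWeight`
#'   (`NULL` when the boundary is not reached).
#' @export
fertilityAlongPath <- function(lh, path, policy = NULL) {
  .checkPath(path)
  x <- .pathStates(path)
  a <- path$ages
  if (lh@fertility@kind == "iteroparous") {
    b <- vapply(seq_along(a), function(i) lh@fertility@rate(x[i], a[i]),
                numeric(1))
    if (any(b < 0)) stop("invalid model: negative fertility evaluation")
    b[a > lh@fertility@maxLifespan] <- 0
    return(list(ages = a, rate = b, atomAge = NULL, atomWeight = NULL))
  }
  tm <- maturityTime(lh, path)
  out <- list(ages = a, rate = rep(0, length(a)), atomAge = NULL,
              atomWeight = NULL)
  if (!is.na(tm)) {
    face <- .matureFaceValue(lh)
    q <- lh@fertility@rate(face$value, tm)
    if (q < 0) stop("invalid model: negative fertility evaluation")
    out$atomAge <- tm
    out$atomWeight <- q
  }
  out
}
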