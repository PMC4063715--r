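## Seeded Euler-Maruyama simulation of controlled life histories and
## Monte-Carlo estimators of the ERS, the objective and breeding ages.
##
## Multiplicative (GBM-like) families are stepped on the log state so
## positivity is structural; general dynamics are stepped in natural scale.
## Survivorship is carried as a multiplicative weight (continuous
## weighting) rather than by killing paths, which lowers the variance of
## ERS estimates; semelparous paths are frozen (weight zero) at their
## first boundary hit.

#' Monte-Carlo settings
#'
#' @param dt Euler step.
#' @param horizon simulated age span.
#' @param nPaths number of paths.
#' @param seed integer seed.  Paths are simulated in chunks of `chunkSize`
#'   whose sub-seeds derive from `seed`, so enlarging `nPaths` appends new
#'   chunks without reshuffling existing paths.
#' @param bridgeCorrection Brownian-bridge within-step crossing detection
#'   for semelparous first passage (removes most of the O(sqrt(dt))
#'   discretization bias of maturation times); default off.
#' @param storeEvery thin factor for stored states (`NULL`: about 200
#'   stored ages).
#' @param chunkSize paths per seeded chunk.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(dt, horizon, nPaths, seed, bridgeCorrection = FALSE,
                      storeEvery = NULL, chunkSize = 10000L) {
  nsteps <- round(horizon / dt)
  if (is.null(storeEvery)) storeEvery <- max(1L, as.integer(nsteps %/% 200))
  new("SimConfig", dt = dt, horizon = horizon, nPaths = as.integer(nPaths),
      seed = as.integer(seed), bridgeCorrection = isTRUE(bridgeCorrection),
      storeEvery = as.integer(storeEvery), chunkSize = as.integer(chunkSize))
}

## vectorized mortality evaluation (models often return a scalar rate)
.muVec <- function(lh, x, u, a, n) {
  mu <- lh@mortality@rate(x, u, a)
  if (length(mu) == 1L) mu <- rep(mu, n)
  if (any(mu < 0)) stop("invalid model: negative mortality evaluation")
  mu
}

#' Simulate an ensemble of controlled life-history paths
#'
#' Euler-Maruyama update
#' `x <- x + g(x,u,a) dt + sigma(x,u,a) sqrt(dt) z` with independent
#' standard normal vectors `z`; survivorship is accumulated
#' multiplicatively as `exp(-mu dt)` (trapezoid in the hazard).
#' Semelparous paths record a linearly interpolated crossing age at the
#' first hit of the mature boundary and are frozen there with weight zero
#' afterwards.  Fully reproducible from the seed.
#'
#' Evaluable mappings must be vectorized over the state (rows = paths); a
#' one-dimensional state is passed as a numeric vector, the diffusion
#' returns one column per noise channel.
#'
#' @param lh a [LifeHistory-class] (one state dimension).
#' @param policy a [ControlPolicy-class].
#' @param cfg a [SimConfig-class].
#' @param init optional vector of initial states overriding `x0`
#'   (recycled), used e.g. to restart an ensemble from attained states.
#' @return a [PathEnsemble-class].  Paths escaping the truncation bound are
#'   flagged and excluded (weight zero); more than 1 percent escaped raises
#'   a warning.
#' @export
simulatePaths <- function(lh, policy, cfg, init = NULL) {
  sde <- lh@sde
  if (lh@space@dim != 1L)
    stop("path simulation is implemented for one state dimension")
  nsteps <- round(cfg@horizon / cfg@dt)
  dt <- cfg@dt
  agesAll <- seq(0, by = dt, length.out = nsteps + 1L)
  keep <- unique(c(seq(1L, nsteps + 1L, by = cfg@storeEvery), nsteps + 1L))
  agesKeep <- agesAll[keep]
  semel <- lh@fertility@kind == "semelparous"
  face <- if (semel) .matureFaceValue(lh) else NULL
  useLog <- sde@logScale
  toSim <- function(x) if (useLog) log(x) else x
  fromSim <- function(y) if (useLog) exp(y) else y
  bSim <- if (semel) toSim(face$value) else NA_real_
  lowTrunc <- toSim(lh@space@lower[1L])
  highTrunc <- toSim(lh@space@upper[1L])
  M <- sde@nNoise

  nP <- cfg@nPaths
  chunkStarts <- seq(1L, nP, by = cfg@chunkSize)
  statesOut <- matrix(NA_real_, nP, length(keep))
  weightsOut <- matrix(0, nP, length(keep))
  matT <- rep(NA_real_, nP)
  matW <- rep(NA_real_, nP)
  escaped <- 0L

  for (ci in seq_along(chunkStarts)) {
    i0 <- chunkStarts[ci]
    i1 <- min(i0 + cfg@chunkSize - 1L, nP)
    n <- i1 - i0 + 1L
    set.seed((cfg@seed + 1000003L * ci) %% .Machine$integer.max)
    x <- if (is.null(init)) rep(sde@x0[1L], n)
         else rep_len(init, nP)[i0:i1]
    y <- toSim(x)
    W <- rep(1, n)
    alive <- rep(TRUE, n)   # not yet matured/escaped
    Tm <- rep(NA_real_, n); Wm <- rep(NA_real_, n)
    muPrev <- .muVec(lh, x, controlAt(policy, x, 0, lh), 0, n)
    Sy <- matrix(NA_real_, n, length(keep))
    Sw <- matrix(0, n, length(keep))
    ki <- 1L
    Sy[, 1L] <- y; Sw[, 1L] <- W
    if (keep[1L] == 1L) ki <- 2L
    for (s in seq_len(nsteps)) {
      a <- agesAll[s]
      idx <- which(alive)
      if (length(idx)) {
        xi <- fromSim(y[idx])
        ui <- controlAt(policy, xi, a, lh)
        g <- sde@drift(xi, ui, a)
        sig <- sde@diffusion(xi, ui, a)
        if (!is.matrix(sig)) sig <- matrix(sig, ncol = M)
        if (any(!is.finite(g)) || any(!is.finite(sig)))
          stop("invalid model: non-finite drift/diffusion evaluation")
        if (useLog) {
          v <- rowSums(sig^2)
          gS <- g / xi - v / (2 * xi^2)
          sigS <- sig / xi
        } else {
          gS <- g
          sigS <- sig
        }
        z <- matrix(rnorm(length(idx) * M), ncol = M)
        ynew <- y[idx] + gS * dt + sqrt(dt) * rowSums(sigS * z)
        ## survivorship (trapezoid hazard)
        munew <- .muVec(lh, fromSim(ynew), ui, a + dt, length(idx))
        Wnew <- W[idx] * exp(-(muPrev[idx] + munew) / 2 * dt)
        if (semel) {
          up <- face$side == "upper"
          crossed <- if (up) ynew >= bSim else ynew <= bSim
          frac <- rep(1, length(idx))
          frac[crossed] <- (bSim - y[idx][crossed]) /
            (ynew[crossed] - y[idx][crossed])
          if (cfg@bridgeCorrection) {
            vtot <- rowSums(sigS^2)   # variance rate in sim coordinate
            nc <- which(!crossed & vtot > 0)
            if (length(nc)) {
              d0 <- bSim - y[idx][nc]; d1 <- bSim - ynew[nc]
              if (!up) { d0 <- -d0; d1 <- -d1 }
              pcross <- exp(-2 * pmax(d0, 0) * pmax(d1, 0) /
                              (vtot[nc] * dt))
              hitB <- runif(length(nc)) < pcross
              crossed[nc[hitB]] <- TRUE
              frac[nc[hitB]] <- 0.5
            }
          }
          if (any(crossed)) {
            ic <- idx[crossed]
            Tm[ic] <- a + frac[crossed] * dt
            Wm[ic] <- W[ic] * exp(-muPrev[ic] * frac[crossed] * dt)
            ynew[crossed] <- bSim
            Wnew[crossed] <- 0
            alive[ic] <- FALSE
          }
        }
        ## truncation escape on non-absorbing faces
        esc <- (ynew < lowTrunc) | (ynew > highTrunc & !semel)
        if (any(esc)) {
          ie <- idx[esc]
          alive[ie] <- FALSE
          Wnew[esc] <- 0
          escaped <- escaped + sum(esc)
        }
        y[idx] <- ynew
        W[idx] <- Wnew
        muPrev[idx] <- munew
      }
      if (ki <= length(keep) && keep[ki] == s + 1L) {
        Sy[, ki] <- y; Sw[, ki] <- W
        ki <- ki + 1L
      }
    }
    statesOut[i0:i1, ] <- Sy
    weightsOut[i0:i1, ] <- Sw
    matT[i0:i1] <- Tm
    matW[i0:i1] <- Wm
  }
  if (escaped > 0.01 * nP)
    warning(escaped, " paths (", signif(100 * escaped / nP, 3),
            "%) escaped the truncation bound and were excluded")
  new("PathEnsemble", ages = agesKeep, states = fromSim(statesOut),
      weights = weightsOut,
      maturityTimes = if (semel) matT else numeric(),
      maturityWeights = if (semel) matW else numeric(),
      escaped = as.integer(escaped), seed = cfg@seed,
      config = list(dt = dt, horizon = cfg@horizon, nPaths = nP,
                    bridgeCorrection = cfg@bridgeCorrection,
                    storeEvery = cfg@storeEvery,
                    chunkSize = cfg@chunkSize))
}

#' Monte-Carlo estimate of the ERS
#'
#' Iteroparous: `F(tau)` is the path mean of fertility times survivorship
#' weight at each stored age up to `min(horizon, omega)`, with per-age
#' standard errors.  Semelparous: the weighted point-mass representation,
#' one atom per matured path at its maturation age with weight
#' `q * S / nPaths`.
#'
#' @param ensemble a [PathEnsemble-class] simulated from `lh`.
#' @param lh the [LifeHistory-class].
#' @return an [ErsCurve-class].
#' @export
estimateErsMC <- function(ensemble, lh) {
  n <- nrow(ensemble@weights)
  if (lh@fertility@kind == "semelparous") {
    face <- .matureFaceValue(lh)
    ok <- which(!is.na(ensemble@maturityTimes))
    Tm <- ensemble@maturityTimes[ok]
    q <- vapply(Tm, function(tt) lh@fertility@rate(face$value, tt),
                numeric(1))
    if (any(q < 0)) stop("invalid model: negative fertility evaluation")
    w <- q * ensemble@maturityWeights[ok] / n
    return(ersCurve(atomAges = Tm, atomWeights = w))
  }
  ages <- ensemble@ages
  om <- lh@fertility@maxLifespan
  useA <- ages <= om
  ages <- ages[useA]
  vals <- numeric(length(ages)); ses <- numeric(length(ages))
  for (j in seq_along(ages)) {
    b <- lh@fertility@rate(ensemble@states[, which(useA)[j]], ages[j])
    if (length(b) == 1L) b <- rep(b, n)
    if (any(b < 0)) stop("invalid model: negative fertility evaluation")
    fw <- b * ensemble@weights[, which(useA)[j]]
    vals[j] <- mean(fw)
    ses[j] <- sd(fw) / sqrt(n)
  }
  ersCurve(ages = ages, values = pmax(vals, 0), se = ses)
}

#' Monte-Carlo estimate of the Laplace-transform objective
#'
#' `phi(lambda)`: per-path discounted lifetime reproduction, averaged.
#' Semelparous atoms are summed exactly; iteroparous curves use the
#' trapezoid rule along each path.  A rough bound on the truncated tail
#' mass (paths still alive at the horizon) is attached; exceeding
#' `tailTol` raises a warning.
#'
#' @inheritParams estimateErsMC
#' @param lambda Laplace argument.
#' @param tailTol tolerance on the estimated truncation-bias bound.
#' @return named numeric `c(value, se)` with attribute `tailBound`.
#' @export
estimateObjectiveMC <- function(ensemble, lh, lambda, tailTol = 1e-3) {
  n <- nrow(ensemble@weights)
  H <- ensemble@config$horizon
  lastW <- ensemble@weights[, ncol(ensemble@weights)]
  if (lh@fertility@kind == "semelparous") {
    face <- .matureFaceValue(lh)
    v <- numeric(n)
    ok <- which(!is.na(ensemble@maturityTimes))
    Tm <- ensemble@maturityTimes[ok]
    q <- vapply(Tm, function(tt) lh@fertility@rate(face$value, tt),
                numeric(1))
    v[ok] <- q * ensemble@maturityWeights[ok] * exp(-lambda * Tm)
    qH <- lh@fertility@rate(face$value, H)
    tail <- mean(lastW) * qH * exp(-max(lambda, 0) * H)
  } else {
    ages <- ensemble@ages
    om <- lh@fertility@maxLifespan
    useA <- ages <= om
    disc <- exp(-lambda * ages[useA])
    v <- vapply(seq_len(n), function(i) {
      b <- lh@fertility@rate(ensemble@states[i, useA], ages[useA])
      if (length(b) == 1L) b <- rep(b, sum(useA))
      .trapz(ages[useA], disc * b * ensemble@weights[i, useA])
    }, numeric(1))
    bH <- mean(lh@fertility@rate(ensemble@states[, ncol(ensemble@states)], H))
    tail <- if (H >= om) 0 else mean(lastW) * bH * exp(-max(lambda, 0) * H) /
      max(lambda + 1e-12, 1e-12)
  }
  if (is.finite(tail) && tail > tailTol)
    warning("estimated truncation tail bound ", signif(tail, 3),
            " exceeds tolerance")
  out <- c(value = mean(v), se = sd(v) / sqrt(n))
  attr(out, "tailBound") <- tail
  out
}

#' Importance-resampled breeding ages
#'
#' Draws ages from the discounted ERS measure with weights proportional to
#' `exp(-lambda a) F(a)`; at the Euler-Lotka root this is the breeding-age
#' density of the stable population.
#'
#' @inheritParams estimateObjectiveMC
#' @param n sample size.
#' @param seed resampling seed.
#' @return numeric ages of length `n`.
#' @export
sampleBreedingAges <- function(ensemble, lh, lambda, n, seed = 1L) {
  ers <- estimateErsMC(ensemble, lh)
  ages <- c(ers@ages, ers@atomAges)
  w <- c(if (length(ers@ages)) exp(-lambda * ers@ages) * ers@values
         else numeric(),
         if (length(ers@atomAges))
           exp(-lambda * ers@atomAges) * ers@atomWeights else numeric())
  if (!any(w > 0)) stop("degenerate model: all breeding-age weights zero")
  set.seed(seed)
  sample(ages, n, replace = TRUE, prob = w)
}

#' Export / import a path ensemble
#'
#' The ensemble is written as a flat tab-delimited table (path id, age,
#' state, weight) with a JSON sidecar `<file>.json` holding the simulation
#' config and seed.
#'
#' @param ensemble a [PathEnsemble-class].
#' @param file path of the delimited file.
#' @return `writeEnsemble`: `file`, invisibly; `readEnsemble`: a
#'   [PathEnsemble-class] (maturation columns restored from the sidecar).
#' @export
writeEnsemble <- function(ensemble, file) {
  n <- nrow(ensemble@weights)
  df <- data.frame(
    path = rep(seq_len(n), times = length(ensemble@ages)),
    age = rep(ensemble@ages, each = n),
    state = as.vector(ensemble@states),
    weight = as.vector(ensemble@weights))
  write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- c(ensemble@config,
            list(seed = ensemble@seed, escaped = ensemble@escaped,
                 maturityTimes = ensemble@maturityTimes,
                 maturityWeights = ensemble@maturityWeights))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(file)
}

#' @rdname writeEnsemble
#' @export
readEnsemble <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  ages <- sort(unique(df$age))
  n <- max(df$path)
  states <- matrix(df$state, n, length(ages))
  weights <- matrix(df$weight, n, length(ages))
  mt <- meta$maturityTimes
  if (is.null(mt)) mt <- numeric() else mt <- as.numeric(mt)
  mw <- meta$maturityWeights
  if (is.null(mw)) mw <- numeric() else mw <- as.numeric(mw)
  new("PathEnsemble", ages = ages, states = states, weights = weights,
      maturityTimes = mt, maturityWeights = mw,
      escaped = as.integer(meta$escaped), seed = as.integer(meta$seed),
      config = meta[c("dt", "horizon", "nPaths", "bridgeCorrection",
                      "storeEvery", "chunkSize")])
}
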