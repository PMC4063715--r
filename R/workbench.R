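## Scenario runner and cross-formulation agreement reports tying the
## modules into reproducible analyses.

#' Define a scenario
#'
#' @param family registered model family.
#' @param params family parameters (with `breeding`).
#' @param analyses subset of `"simulate"`, `"fitness"`, `"hjb"`,
#'   `"two-resource"`, `"correspondence"`.
#' @param seed integer seed; mandatory when any stochastic analysis
#'   (`"simulate"`, `"correspondence"`) is requested.
#' @param settings optional overrides (`dt`, `horizon`, `nPaths`, grid
#'   sizes, `nSweep`).
#' @return a validated scenario object (list).
#' @export
scenario <- function(family, params, analyses, seed = NULL,
                     settings = list()) {
  analyses <- match.arg(analyses,
                        c("simulate", "fitness", "hjb", "two-resource",
                          "correspondence"), several.ok = TRUE)
  needsSeed <- any(analyses %in% c("simulate", "correspondence"))
  if (needsSeed && is.null(seed))
    stop("config error: a seed is mandatory for stochastic analyses")
  structure(list(family = family, params = params, analyses = analyses,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 settings = settings),
            class = "stoclife_scenario")
}

#' Bundled example scenarios
#'
#' `"fig2_sweep"`: sweep of the convexity index against the optimal
#' utilization and fitness (two regimes, monotone risky weight);
#' `"correspondence"`: three-way fitness agreement (Monte-Carlo,
#' Fokker-Planck, matrix model) on the reference semelparous mix.
#'
#' @param name bundled scenario name.
#' @param seed seed for stochastic analyses.
#' @return a scenario object.
#' @export
bundledScenario <- function(name = c("fig2_sweep", "correspondence"),
                            seed = 1L) {
  name <- match.arg(name)
  p <- twoResourceParams()
  pl <- twoResourceLifeHistory(p, "semelparous")@params
  switch(name,
    fig2_sweep = scenario("two_resource_gbm", pl, "two-resource",
                          settings = list(nSweep = 25L)),
    correspondence = scenario("two_resource_gbm", pl, "correspondence",
                              seed = seed))
}

#' Run a scenario
#'
#' Executes the requested analyses, writing delimited tables, figures, a
#' JSON summary and a run log into `outDir`.  Re-running with the same
#' config and seed reproduces every Monte-Carlo number bit for bit.
#'
#' @param scn a scenario from [scenario()] or [bundledScenario()].
#' @param outDir output directory (created).
#' @return the summary list, invisibly.
#' @export
runScenario <- function(scn, outDir) {
  stopifnot(inherits(scn, "stoclife_scenario"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  reg <- .familyRegistry()
  lh <- reg[[scn$family]](scn$params)
  st <- scn$settings
  summary <- list(family = scn$family, params = scn$params,
                  seed = scn$seed, analyses = scn$analyses)
  errors <- list()
  isTR <- lh@family == "two_resource_gbm"
  p <- if (isTR) do.call(twoResourceParams,
                         scn$params[c("m1", "m2", "s1", "s2", "mu0", "x0",
                                      "xm", "q", "b0", "alpha", "omega")])
       else NULL
  for (an in scn$analyses) {
    res <- tryCatch(switch(an,
      "simulate" = {
        cfg <- simConfig(dt = st$dt %||% 0.05, horizon = st$horizon %||% 80,
                         nPaths = st$nPaths %||% 4000L, seed = scn$seed,
                         bridgeCorrection = TRUE)
        u <- st$u %||% 0.5
        ens <- simulatePaths(lh, constantPolicy(u), cfg)
        writeEnsemble(ens, file.path(outDir, "ensemble.tsv"))
        list(matured = sum(!is.na(ens@maturityTimes)),
             meanMaturityAge = mean(ens@maturityTimes, na.rm = TRUE))
      },
      "fitness" = {
        u <- st$u %||% 0.5
        sol <- if (isTR && scn$params$breeding == "semelparous")
          solveEulerLotka(function(l) twoResourceObjective(p, u, l))
        else solveEulerLotka(function(l) iteroparousObjective(p, u, l))
        list(lambda = sol@lambda, R0 = sol@R0,
             cumulants = sol@cumulants,
             residual = sol@diagnostics$residual)
      },
      "hjb" = {
        grid <- grid1d(p@x0 * exp(-6), p@xm, st$nGrid %||% 241L)
        of <- optimalFitness(lh, grid)
        utils::write.table(
          data.frame(x = of$value@nodes, V = of$value@V,
                     u = of$value@policy),
          file.path(outDir, "hjb_value.tsv"), sep = "\t",
          row.names = FALSE, quote = FALSE)
        list(lambda = of$lambda, meanPolicy = mean(of$value@policy))
      },
      "two-resource" = {
        nS <- st$nSweep %||% 25L
        nGridv <- seq(0.05, 0.95, length.out = nS)
        tab <- do.call(rbind, lapply(nGridv, function(nv) {
          pp <- twoResourceParams(m1 = p@m1, m2 = p@m2, s1 = p@s1,
                                  s2 = p@s2, mu0 = p@mu0, x0 = p@x0,
                                  xm = p@x0 * p@q^(1 / nv), q = p@q)
          mx <- semelparousOptimalMix(pp)
          data.frame(n = nv, uStar = mx@uStar, lambda = mx@lambdaStar,
                     regime = mx@regime)
        }))
        utils::write.table(tab, file.path(outDir, "sweep.tsv"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
        ## qualitative contract of the sweep figure: monotone risky
        ## weight, two regimes
        stopifnot(all(diff(tab$uStar) > -1e-12),
                  length(unique(tab$regime)) >= 2L)
        grDevices::png(file.path(outDir, "sweep.png"), 640, 480)
        plot(tab$n, tab$uStar, type = "l", xlab = "convexity index n",
             ylab = "optimal weight on R1",
             main = "Optimal utilization by convexity index")
        grDevices::dev.off()
        mx <- semelparousOptimalMix(p)
        list(uStar = mx@uStar, lambdaStar = mx@lambdaStar,
             window = mx@window, sweepRows = nrow(tab))
      },
      "correspondence" = {
        rep <- compareFormulations(lh, constantPolicy(st$u %||%
          semelparousOptimalMix(p)@uStar), seed = scn$seed)
        utils::write.table(rep$table, file.path(outDir,
                                                "correspondence.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        rep[c("maxGap", "pass")]
      }), error = function(e) {
        errors[[an]] <<- conditionMessage(e)
        NULL
      })
    if (!is.null(res)) summary[[an]] <- res
  }
  summary$errors <- errors
  summary$log <- list(package = as.character(utils::packageVersion(
                        "stoclife")),
                      elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs")))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (length(errors)) {
    warning("scenario finished with errors in: ",
            paste(names(errors), collapse = ", "))
    attr(summary, "status") <- 1L
  } else attr(summary, "status") <- 0L
  invisible(summary)
}

#' Cross-formulation fitness agreement
#'
#' Computes the fitness of one (one-dimensional) life history under a
#' stationary policy by four routes: (a) Monte-Carlo ERS plus Euler-Lotka
#' root, (b) Fokker-Planck ERS plus Euler-Lotka root, (c) dominant
#' eigenvalue of the age-size transition matrix model, (d) renewal-
#' equation slope; and reports the pairwise gaps against a tolerance.
#' The agreement of (a)-(c) in the refinement limit is the correspondence
#' of the path-wise formulation with the other linear demographic models.
#'
#' @param lh a [LifeHistory-class].
#' @param policy a stationary [ControlPolicy-class].
#' @param seed Monte-Carlo seed.
#' @param nPaths,dt,horizon Monte-Carlo settings.
#' @param nGrid,S,da state-grid sizes and the matrix-model age step.
#' @param tol pass tolerance on pairwise gaps among (a)-(c).
#' @return list with `table` (route, lambda), `maxGap`, `pass`,
#'   `renewalResidual`.
#' @export
compareFormulations <- function(lh, policy, seed = 1L, nPaths = 20000L,
                                dt = 0.02, horizon = 60, nGrid = 281L,
                                S = 90L, da = 0.125, tol = 1e-2) {
  semel <- lh@fertility@kind == "semelparous"
  ## (a) Monte Carlo
  cfg <- simConfig(dt = dt, horizon = horizon, nPaths = nPaths, seed = seed,
                   bridgeCorrection = TRUE)
  ens <- simulatePaths(lh, policy, cfg)
  ersMC <- estimateErsMC(ens, lh)
  lamMC <- solveEulerLotka(ersMC, cumulants = FALSE)@lambda
  ## (b) Fokker-Planck
  top <- if (semel) .matureFaceValue(lh)$value else lh@space@upper[1L]
  lo <- lh@sde@x0[1L] * exp(-8)
  grid <- grid1d(lo, top, nGrid)
  ages <- seq(0, horizon, length.out = 241L)
  kern <- solveFokkerPlanck(lh, policy, grid, ages,
                            dt = ages[2] / 4)
  ersPD <- ersFromKernel(kern, lh)
  lamPD <- solveEulerLotka(ersPD, cumulants = FALSE)@lambda
  ## (c) matrix model (size range trimmed to where the kernel has mass)
  A <- as.integer(ceiling(horizon / da))
  tmm <- buildAgeSizeTmm(lh, policy, da = da, A = A, S = S,
                         sizeRange = c(lh@sde@x0[1L] * exp(-6), top))
  lamTMM <- as.numeric(tmmFitness(tmm))
  ## (d) renewal slope
  ren <- renewalResidual(ersPD, lamPD, horizon = horizon)
  tab <- data.frame(route = c("mc", "fokker_planck", "tmm", "renewal"),
                    lambda = c(lamMC, lamPD, lamTMM, ren$slope))
  gaps <- abs(outer(tab$lambda[1:3], tab$lambda[1:3], "-"))
  list(table = tab, maxGap = max(gaps), pass = max(gaps) < tol,
       renewalResidual = ren$residual)
}
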