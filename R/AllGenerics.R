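#' Extract the fitness (intrinsic rate of natural increase)
#'
#' @param object a [DemographicSolution-class], [MixResult-class] or
#'   [ValueGrid-class].
#' @return the scalar fitness `lambda`.
#' @export
setGeneric("fitness", function(object) standardGeneric("fitness"))

#' @rdname fitness
#' @export
setMethod("fitness", "DemographicSolution", function(object) object@lambda)

#' @rdname fitness
#' @export
setMethod("fitness", "MixResult", function(object) object@lambdaStar)

#' @rdname fitness
#' @export
setMethod("fitness", "ValueGrid", function(object) object@lambda)

#' Basic reproductive number R0
#'
#' `R0 = phi(0)`: expected total lifetime reproduction.  `R0 >= 1` if and
#' only if the fitness is nonnegative (shared root of the Euler-Lotka
#' equation at zero).
#'
#' @param object a [DemographicSolution-class].
#' @return nonnegative scalar.
#' @export
setGeneric("basicReproduction",
           function(object) standardGeneric("basicReproduction"))

#' @rdname basicReproduction
#' @export
setMethod("basicReproduction", "DemographicSolution",
          function(object) object@R0)

#' Optimal utilization weight on the risky resource
#'
#' @param object a [MixResult-class].
#' @return scalar in `[0, 1]`.
#' @export
setGeneric("optimalControl",
           function(object) standardGeneric("optimalControl"))

#' @rdname optimalControl
#' @export
setMethod("optimalControl", "MixResult", function(object) object@uStar)

#' @rdname optimalControl
#' @export
setMethod("optimalControl", "ValueGrid", function(object) object@policy)

setMethod("show", "LifeHistory", function(object) {
  cat("LifeHistory (", object@fertility@kind, ")\n", sep = "")
  cat("  states:", object@space@dim,
      " domain: [", paste(signif(object@space@lower, 4), collapse = ","),
      "] - [", paste(signif(object@space@upper, 4), collapse = ","), "]\n")
  cat("  x0:", paste(signif(object@sde@x0, 4), collapse = ", "),
      " noises:", object@sde@nNoise,
      " control box: [", paste(object@sde@controlLower, collapse = ","),
      "] - [", paste(object@sde@controlUpper, collapse = ","), "]\n")
  if (nzchar(object@family))
    cat("  family:", object@family, "\n")
  invisible(object)
})

setMethod("show", "PathEnsemble", function(object) {
  cat("PathEnsemble:", nrow(object@weights), "paths,",
      length(object@ages), "stored ages up to",
      signif(max(object@ages), 4), "\n")
  if (length(object@maturityTimes)) {
    nm <- sum(!is.na(object@maturityTimes))
    cat("  matured:", nm, "(",
        signif(100 * nm / length(object@maturityTimes), 3), "% )\n")
  }
  if (object@escaped > 0L)
    cat("  escaped paths excluded:", object@escaped, "\n")
  invisible(object)
})

setMethod("show", "ErsCurve", function(object) {
  cat("ErsCurve:")
  if (length(object@ages))
    cat(" grid of", length(object@ages), "ages, max F =",
        signif(max(object@values), 4), ";")
  if (length(object@atomAges))
    cat(" ", length(object@atomAges), "atoms, total weight",
        signif(sum(object@atomWeights), 4))
  cat("\n")
  invisible(object)
})

setMethod("show", "DemographicSolution", function(object) {
  cat("DemographicSolution\n")
  cat("  fitness lambda :", signif(object@lambda, 8), "\n")
  cat("  R0             :", signif(object@R0, 8), "\n")
  if (length(object@cumulants) >= 2L)
    cat("  breeding age   : mean", signif(object@cumulants[1], 5),
        " var", signif(object@cumulants[2], 5), "\n")
  if (!is.null(object@diagnostics$residual))
    cat("  |phi(lambda)-1|:",
        format(object@diagnostics$residual, digits = 3), "\n")
  invisible(object)
})

setMethod("show", "ProjectionKernel", function(object) {
  cat("ProjectionKernel on", length(object@nodes), object@coord,
      "nodes,", length(object@ages), "stored ages\n")
  cat("  survivorship at final age:",
      signif(tail(object@survivorship, 1), 5), "\n")
  invisible(object)
})

setMethod("show", "TransitionMatrixModel", function(object) {
  cat("TransitionMatrixModel:", object@A, "age x", object@S,
      "size classes (order", object@A * object@S, "), da =", object@da, "\n")
  invisible(object)
})

setMethod("show", "ValueGrid", function(object) {
  cat("ValueGrid:", length(object@nodes), "state nodes")
  if (length(object@ages)) cat(" x", length(object@ages), "ages")
  cat(", lambda =", signif(object@lambda, 6),
      ", residual =", format(object@residual, digits = 3), "\n")
  invisible(object)
})

setMethod("show", "MixResult", function(object) {
  cat("MixResult (", object@regime, ")\n", sep = "")
  cat("  u* (weight on R1):", signif(object@uStar, 6),
      "  [R2 weight:", signif(1 - object@uStar, 6), "]\n")
  cat("  fitness lambda*  :", signif(object@lambdaStar, 8), "\n")
  cat("  exponent         :", signif(object@exponent, 6),
      "  generalist window: (", signif(object@window[1], 4), ",",
      signif(object@window[2], 4), ")\n")
  invisible(object)
})
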