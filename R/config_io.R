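## YAML configuration round-trip for registered model families.

.familyRegistry <- function() {
  list(
    two_resource_gbm = function(params) {
      p <- twoResourceParams(
        m1 = params$m1, m2 = params$m2, s1 = params$s1, s2 = params$s2,
        mu0 = params$mu0, x0 = params$x0, xm = params$xm, q = params$q,
        b0 = params$b0, alpha = params$alpha, omega = params$omega)
      twoResourceLifeHistory(p, breeding = params$breeding)
    },
    single_resource_gbm = function(params) {
      p <- twoResourceParams(
        m1 = params$g, m2 = params$g - 1e-9, s1 = max(params$s, 1e-9),
        s2 = 0, mu0 = params$mu0, x0 = params$x0, xm = params$xm,
        q = params$q, b0 = params$b0 %||% 0.1, alpha = params$alpha %||% 0.5,
        omega = params$omega %||% Inf)
      lh <- twoResourceLifeHistory(p, breeding = params$breeding)
      ## collapse to one resource: constant-u = 1 coefficients
      lh@family <- "single_resource_gbm"
      lh@params <- params
      lh
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a life history from a YAML config
#'
#' The config names a registered model family (`two_resource_gbm` or
#' `single_resource_gbm`) plus numeric parameters, e.g.
#' \preformatted{family: two_resource_gbm
#' params:
#'   m1: 0.2
#'   ...
#'   breeding: semelparous}
#'
#' @param file path to the YAML file.
#' @return a [LifeHistory-class].
#' @export
readLifeHistoryConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  reg <- .familyRegistry()
  if (is.null(cfg$family) || !cfg$family %in% names(reg))
    stop("unknown or missing model family; registered: ",
         paste(names(reg), collapse = ", "))
  reg[[cfg$family]](cfg$params)
}

#' Write the canonical config of a registered life history
#'
#' @param lh a [LifeHistory-class] carrying a family tag.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeLifeHistoryConfig <- function(lh, file) {
  if (!nzchar(lh@family))
    stop("only registered model families can be written to a config")
  yaml::write_yaml(list(family = lh@family, params = lh@params), file)
  invisible(file)
}
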