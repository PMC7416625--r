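#' @import methods
NULL

#' Gamma model of retrotransposon insertion ages
#'
#' Holds the maximum-likelihood gamma age distribution of an LTR
#' retrotransposon family, estimated from LTR-pair mismatch counts through
#' the negative-binomial (gamma-mixed Poisson) marginal likelihood.  Ages
#' are measured in million years (Myr); the implied mean insertion age is
#' \code{shape/rate} Myr.
#'
#' @slot shape gamma shape parameter (dimensionless), > 0.
#' @slot rate gamma rate parameter, per Myr, > 0.
#' @slot mutationRate substitution rate per site per year used to convert
#'   mismatches into time.
#' @slot logLik maximized marginal log-likelihood.
#' @slot nElements number of elements used in the fit.
#' @slot boundary \code{TRUE} when the fit hit the zero-age boundary
#'   (all mismatch counts zero).
#' @exportClass TeAgeModel
setClass("TeAgeModel", representation(
  shape = "numeric", rate = "numeric", mutationRate = "numeric",
  logLik = "numeric", nElements = "integer", boundary = "logical"))

setValidity("TeAgeModel", function(object) {
  msg <- NULL
  if (length(object@shape) != 1L || !is.finite(object@shape) ||
      object@shape <= 0)
    msg <- c(msg, "'shape' must be a single positive number")
  if (length(object@rate) != 1L || !is.finite(object@rate) ||
      object@rate <= 0)
    msg <- c(msg, "'rate' must be a single positive number")
  if (object@mutationRate <= 0)
    msg <- c(msg, "'mutationRate' must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Exponential survival model for retrotransposons
#'
#' Survivorship of inserted elements is modelled as
#' \eqn{S(t) = \exp(-\delta t)} with \eqn{\delta} the genome-wide deletion
#' rate per Myr, estimated by a log-linear fit to the declining flank of
#' the element age histogram.
#'
#' @slot deletionRate deletion rate \eqn{\delta} per Myr (>= 0).
#' @slot fitWindow numeric length-2, the age window (Myr) used in the fit.
#' @slot nBinsUsed number of non-empty histogram bins entering the fit.
#' @exportClass TeSurvivalModel
setClass("TeSurvivalModel", representation(
  deletionRate = "numeric", fitWindow = "numeric", nBinsUsed = "integer"))

setValidity("TeSurvivalModel", function(object) {
  msg <- NULL
  if (length(object@deletionRate) != 1L || object@deletionRate < 0)
    msg <- c(msg, "'deletionRate' must be a single non-negative number")
  if (length(object@fitWindow) != 2L || diff(object@fitWindow) <= 0)
    msg <- c(msg, "'fitWindow' must be an increasing length-2 numeric")
  if (is.null(msg)) TRUE else msg
})

#' Exponential mixture fit for intergenic distances
#'
#' Result of fitting a K-component exponential mixture to intergenic
#' distances by EM.  Components are stored in strictly decreasing rate
#' order, so component 1 is the short-gap (intra-insular) component.
#'
#' @slot K number of components actually fitted.
#' @slot weights mixing weights, summing to 1.
#' @slot rates component rates per bp, strictly decreasing.
#' @slot logLik log-likelihood at the EM optimum.
#' @slot responsibilities n-by-K matrix of posterior component
#'   probabilities (may have zero rows when not retained).
#' @slot trace per-iteration log-likelihood of the best EM start.
#' @slot degenerate \code{TRUE} when a component collapsed (weight below
#'   1e-6) and the model was refitted with K-1 components.
#' @exportClass ExpMixtureFit
setClass("ExpMixtureFit", representation(
  K = "integer", weights = "numeric", rates = "numeric",
  logLik = "numeric", responsibilities = "matrix", trace = "numeric",
  degenerate = "logical"))

setValidity("ExpMixtureFit", function(object) {
  msg <- NULL
  if (length(object@weights) != object@K || length(object@rates) != object@K)
    msg <- c(msg, "'weights' and 'rates' must have length K")
  if (abs(sum(object@weights) - 1) > 1e-6)
    msg <- c(msg, "'weights' must sum to 1")
  if (any(object@rates <= 0))
    msg <- c(msg, "'rates' must be positive")
  if (object@K > 1L && any(diff(object@rates) >= 0))
    msg <- c(msg, "'rates' must be strictly decreasing")
  if (is.null(msg)) TRUE else msg
})

#' Marey map: smoothed genetic position as a function of physical position
#'
#' Per chromosome, the cleaned (isotonic) marker support points and the
#' smoothing parameters of the local polynomial fit of genetic position
#' (cM) on physical position (bp).  The first derivative of the fit is the
#' local recombination rate.
#'
#' @slot support named list, one data.frame (bp, cM) per chromosome, with
#'   cM non-decreasing in bp.
#' @slot bandwidth named numeric, smoothing bandwidth in bp per chromosome.
#' @slot degree polynomial degree of the local fit.
#' @slot chromLengths named numeric, chromosome lengths in bp.
#' @exportClass MareyMap
setClass("MareyMap", representation(
  support = "list", bandwidth = "numeric", degree = "integer",
  chromLengths = "numeric"))

setValidity("MareyMap", function(object) {
  msg <- NULL
  for (chr in names(object@support)) {
    s <- object@support[[chr]]
    if (!all(c("bp", "cM") %in% names(s)))
      msg <- c(msg, sprintf("support for %s lacks bp/cM columns", chr))
    else if (is.unsorted(s$cM))
      msg <- c(msg, sprintf("cM not non-decreasing on %s", chr))
  }
  if (!all(names(object@support) %in% names(object@chromLengths)))
    msg <- c(msg, "every chromosome needs a length")
  if (is.null(msg)) TRUE else msg
})
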