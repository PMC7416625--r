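#' @include AllClasses.R
NULL

#' @describeIn TeAgeModel-class gamma shape parameter.
#' @param object a model object.
#' @export
setGeneric("ageShape", function(object) standardGeneric("ageShape"))

#' @describeIn TeAgeModel-class gamma rate parameter (per Myr).
#' @export
setGeneric("ageRate", function(object) standardGeneric("ageRate"))

#' @describeIn TeAgeModel-class implied mean insertion age, shape/rate Myr.
#' @export
setGeneric("meanAge", function(object) standardGeneric("meanAge"))

#' @describeIn TeSurvivalModel-class deletion rate per Myr.
#' @param object a model object.
#' @export
setGeneric("deletionRate", function(object) standardGeneric("deletionRate"))

#' @describeIn ExpMixtureFit-class mixing weights (short-gap component
#'   first).
#' @param object a fit object.
#' @export
setGeneric("mixtureWeights", function(object) standardGeneric("mixtureWeights"))

#' @describeIn ExpMixtureFit-class component rates per bp, decreasing.
#' @export
setGeneric("mixtureRates", function(object) standardGeneric("mixtureRates"))

#' @describeIn ExpMixtureFit-class posterior component probabilities.
#' @export
setGeneric("responsibilities", function(object)
  standardGeneric("responsibilities"))

setMethod("ageShape", "TeAgeModel", function(object) object@shape)
setMethod("ageRate", "TeAgeModel", function(object) object@rate)
setMethod("meanAge", "TeAgeModel", function(object) object@shape / object@rate)
setMethod("deletionRate", "TeSurvivalModel",
          function(object) object@deletionRate)
setMethod("mixtureWeights", "ExpMixtureFit", function(object) object@weights)
setMethod("mixtureRates", "ExpMixtureFit", function(object) object@rates)
setMethod("responsibilities", "ExpMixtureFit",
          function(object) object@responsibilities)

#' @importFrom stats logLik
#' @export
setMethod("logLik", "TeAgeModel", function(object, ...) object@logLik)

#' @export
setMethod("logLik", "ExpMixtureFit", function(object, ...) object@logLik)

setMethod("show", "TeAgeModel", function(object) {
  cat("TeAgeModel (gamma insertion-age distribution)\n")
  cat(sprintf("  shape = %.4g, rate = %.4g /Myr, mean age = %.4g Myr\n",
              object@shape, object@rate, object@shape / object@rate))
  cat(sprintf("  mutation rate r = %.3g /site/year, n = %d, logLik = %.2f%s\n",
              object@mutationRate, object@nElements, object@logLik,
              if (object@boundary) " [boundary: all ages ~ 0]" else ""))
})

setMethod("show", "TeSurvivalModel", function(object) {
  cat("TeSurvivalModel: S(t) = exp(-delta t)\n")
  cat(sprintf("  delta = %.4g /Myr, fit window [%.2f, %.2f] Myr, %d bins\n",
              object@deletionRate, object@fitWindow[1], object@fitWindow[2],
              object@nBinsUsed))
})

setMethod("show", "ExpMixtureFit", function(object) {
  cat(sprintf("ExpMixtureFit with K = %d exponential component(s)%s\n",
              object@K, if (object@degenerate) " [degenerate refit]" else ""))
  for (k in seq_len(object@K))
    cat(sprintf("  comp %d: weight %.3f, rate %.4g /bp (mean gap %.0f bp)\n",
                k, object@weights[k], object@rates[k], 1 / object@rates[k]))
  cat(sprintf("  logLik = %.2f after %d EM iterations\n",
              object@logLik, length(object@trace)))
})

setMethod("show", "MareyMap", function(object) {
  cat("MareyMap (local polynomial fit of cM on bp)\n")
  for (chr in names(object@support))
    cat(sprintf("  %s: %d support points, length %.3g bp, bandwidth %.3g bp\n",
                chr, nrow(object@support[[chr]]),
                object@chromLengths[[chr]], object@bandwidth[[chr]]))
  cat(sprintf("  degree %d\n", object@degree))
})
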