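#' @importFrom stats dnbinom optim lm coef dgamma aov TukeyHSD
#'   t.test setNames
#' @importFrom graphics hist
NULL

#' Point insertion age of a single LTR retrotransposon
#'
#' The mismatch count between the two LTRs of one element, given its age
#' \eqn{Y} (years), is Poisson with mean \eqn{2 r l Y} (both LTRs
#' accumulate substitutions at rate \eqn{r} per site per year over length
#' \eqn{l}).  Inverting the mean gives the point age
#' \eqn{\hat Y = N / (2 r l)}, reported in Myr.
#'
#' @param mismatches non-negative mismatch count(s) N.
#' @param ltrLength LTR length(s) l in bp, > 0.
#' @param mutationRate substitution rate r per site per year.
#' @return age(s) in Myr.
#' @examples
#' pointAge(26, 1000)  # 1 Myr
#' @export
pointAge <- function(mismatches, ltrLength, mutationRate = 1.3e-8) {
  if (any(ltrLength <= 0)) stop("'ltrLength' must be positive")
  if (mutationRate <= 0) stop("'mutationRate' must be positive")
  if (any(mismatches < 0)) stop("'mismatches' must be non-negative")
  mismatches / (2 * mutationRate * ltrLength) / 1e6
}

## Marginal log-likelihood of mismatch counts when ages are
## gamma(shape, rate): each count is negative binomial with size = shape
## and success probability rate / (rate + exposure_i), where
## exposure_i = 2 r l_i 1e6 converts Myr to expected mismatches.
.nb_loglik <- function(logpar, N, exposure) {
  a <- exp(logpar[1]); b <- exp(logpar[2])
  sum(dnbinom(N, size = a, prob = b / (b + exposure), log = TRUE))
}

#' Fit a gamma insertion-age distribution to one TE family
#'
#' Maximizes the exact marginal likelihood of the LTR-pair mismatch
#' counts under the hierarchical model N_i | Y_i ~ Poisson(2 r l_i Y_i),
#' Y ~ gamma(shape, rate): a negative binomial with per-element exposure,
#' which reduces to a common negative binomial when all LTR lengths are
#' equal.  Optimization is in log-parameter space from three starting
#' points.
#'
#' @param elements data.frame with columns \code{mismatches} and
#'   \code{ltr_length} (as \code{\link{readTeTable}}).
#' @param mutationRate substitution rate per site per year.
#' @param minElements minimum family size accepted.
#' @return a \code{\linkS4class{TeAgeModel}}.
#' @export
fitAgeDistribution <- function(elements, mutationRate = 1.3e-8,
                               minElements = 30) {
  if (NROW(elements) == 0) stop("no elements supplied")
  if (NROW(elements) < minElements)
    stop("need at least ", minElements, " elements; got ", NROW(elements))
  N <- elements$mismatches
  l <- elements$ltr_length
  if (any(l <= 0)) stop("'ltr_length' must be positive")
  exposure <- 2 * mutationRate * l * 1e6   # expected mismatches per Myr
  if (all(N == 0)) {
    # all ages at the zero boundary: mean age -> 0; report a steep gamma
    return(new("TeAgeModel", shape = 1, rate = 1e6,
               mutationRate = mutationRate, logLik = 0,
               nElements = NROW(elements), boundary = TRUE))
  }
  ages <- N / exposure
  m <- mean(ages); v <- max(var(ages) - mean(N) / mean(exposure)^2, m^2 / 50)
  starts <- list(c(log(m^2 / v), log(m / v)),
                 c(log(2), log(2 / max(m, 1e-3))),
                 c(0, 0))
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      optim(s0, .nb_loglik, N = N, exposure = exposure,
            control = list(fnscale = -1, reltol = 1e-10, maxit = 2000)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value > best$value))
      best <- fit
  }
  if (is.null(best))
    stop("age-distribution fit failed to converge from all starts")
  new("TeAgeModel", shape = exp(best$par[1]), rate = exp(best$par[2]),
      mutationRate = mutationRate, logLik = best$value,
      nElements = NROW(elements), boundary = FALSE)
}

#' Fit exponential survival of TE elements
#'
#' Point ages are histogrammed; the log counts of the declining flank
#' (bins at and beyond the modal bin inside the fit window) are regressed
#' on bin midpoints, and the deletion rate is minus the slope, floored at
#' zero.  Under uniform insertion, thinning at rate delta makes the log
#' histogram linear with slope -delta.
#'
#' @param elements data.frame with \code{mismatches} and
#'   \code{ltr_length}.
#' @param mutationRate substitution rate per site per year.
#' @param fitWindow age window (Myr) used in the fit.
#' @param nBins number of histogram bins across the window.
#' @return a \code{\linkS4class{TeSurvivalModel}}.
#' @export
fitSurvival <- function(elements, mutationRate = 1.3e-8,
                        fitWindow = c(0, 3), nBins = 30) {
  if (length(fitWindow) != 2 || diff(fitWindow) <= 0)
    stop("'fitWindow' must be an increasing length-2 numeric")
  ages <- pointAge(elements$mismatches, elements$ltr_length, mutationRate)
  ages <- ages[ages >= fitWindow[1] & ages <= fitWindow[2]]
  if (length(ages) == 0) stop("no elements inside the fit window")
  brk <- seq(fitWindow[1], fitWindow[2], length.out = nBins + 1)
  h <- hist(ages, breaks = brk, plot = FALSE)
  keep <- h$counts > 0
  modal <- which.max(h$counts)
  keep[seq_len(modal - 1)] <- FALSE    # declining flank only
  if (sum(keep) < 3)
    stop("fewer than 3 non-empty bins on the declining flank")
  fit <- lm(log(h$counts[keep]) ~ h$mids[keep])
  delta <- max(0, -coef(fit)[[2]])
  new("TeSurvivalModel", deletionRate = delta, fitWindow = fitWindow,
      nBinsUsed = as.integer(sum(keep)))
}

#' Insertion-intensity profile of a TE family
#'
#' The insertion rate t Myr ago is the observed age density corrected
#' for survival, \eqn{g(t) / S(t)}, with g the fitted gamma density and
#' \eqn{S(t) = \exp(-\delta t)}.  With \code{normalize = TRUE} the curve
#' is scaled to unit maximum for cross-family comparison.
#'
#' @param ageModel a \code{\linkS4class{TeAgeModel}}.
#' @param survival a \code{\linkS4class{TeSurvivalModel}}.
#' @param grid evaluation ages in Myr (within [0, 3] by convention).
#' @param normalize scale the curve to unit maximum.
#' @param maxIntensity cap applied where \eqn{S(t)} underflows (with a
#'   warning).
#' @return data.frame with columns \code{time_myr}, \code{intensity}.
#' @export
insertionRateProfile <- function(ageModel, survival,
                                 grid = seq(0, 3, by = 0.01),
                                 normalize = TRUE, maxIntensity = 1e12) {
  stopifnot(is(ageModel, "TeAgeModel"), is(survival, "TeSurvivalModel"))
  g <- dgamma(grid, shape = ageModel@shape, rate = ageModel@rate)
  S <- exp(-survival@deletionRate * grid)
  intensity <- ifelse(g == 0, 0, g / pmax(S, 1e-300))
  if (any(intensity > maxIntensity)) {
    warning("survival underflow: intensity capped")
    intensity <- pmin(intensity, maxIntensity)
  }
  if (normalize && max(intensity) > 0)
    intensity <- intensity / max(intensity)
  data.frame(time_myr = grid, intensity = intensity)
}

#' Proximal versus distal mean-age contrast across TE families
#'
#' Families are split at the median of their median distances to the
#' centromere into equal proximal and distal halves, and the family mean
#' ages are compared with a two-sided two-sample t-test (pooled variance
#' by default; Welch by flag).
#'
#' @param familyStats data.frame with columns \code{family},
#'   \code{mean_age} (Myr) and \code{median_dist} (bp to centromere);
#'   even number of rows, >= 4.
#' @param welch use the Welch t-test instead of pooled variance.
#' @return list with \code{statistic}, \code{df}, \code{p.value},
#'   \code{group_means} (named: distal, proximal) and \code{groups}.
#' @export
proximalDistalAgeTest <- function(familyStats, welch = FALSE) {
  n <- NROW(familyStats)
  if (n < 4) stop("at least 4 families are required")
  if (n %% 2 != 0)
    stop("odd number of families: drop one explicitly before testing")
  o <- order(familyStats$median_dist)
  grp <- rep("proximal", n)
  grp[o[seq(n / 2 + 1, n)]] <- "distal"   # larger distance = distal half
  distal <- familyStats$mean_age[grp == "distal"]
  proximal <- familyStats$mean_age[grp == "proximal"]
  if (length(distal) < 2 || (var(distal) == 0 && var(proximal) == 0)) {
    if (isTRUE(all.equal(mean(distal), mean(proximal))))
      return(list(statistic = 0, df = n - 2, p.value = 1,
                  group_means = c(distal = mean(distal),
                                  proximal = mean(proximal)),
                  groups = grp))
  }
  tt <- t.test(distal, proximal, var.equal = !welch)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value,
       group_means = c(distal = mean(distal), proximal = mean(proximal)),
       groups = grp)
}

#' One-way ANOVA of TE distance to the centromere by family
#'
#' Tests whether TE families differ in their mean distance to the
#' centromere, followed by Tukey HSD pairwise contrasts.  Families with
#' fewer than 2 elements are dropped with a warning.
#'
#' @param elements data.frame with columns \code{family} and
#'   \code{dist_to_centromere}.
#' @return list with \code{F}, \code{p.value}, \code{tukey} (the Tukey
#'   HSD table) and \code{anova} (the fitted aov object).
#' @export
familyPositionAnova <- function(elements) {
  tabN <- table(elements$family)
  small <- names(tabN)[tabN < 2]
  if (length(small)) {
    warning("dropping families with a single element: ",
            paste(small, collapse = ", "))
    elements <- elements[!elements$family %in% small, ]
  }
  if (length(unique(elements$family)) < 2)
    stop("at least 2 families with >= 2 elements are required")
  elements$family <- factor(elements$family)
  fit <- aov(dist_to_centromere ~ family, data = elements)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], p.value = s[["Pr(>F)"]][1],
       tukey = TukeyHSD(fit)$family, anova = fit)
}
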