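#' @importFrom stats var quantile pchisq qexp
#' @useDynLib genomescapes, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Intergenic gaps of a gene annotation
#'
#' Per chromosome, the gap between consecutive genes (sorted by start) is
#' the number of bases strictly between them.  Non-positive gaps
#' (overlapping or book-ended genes) are dropped and counted.  Each gap
#' also carries its relative position along the centromere-telomere axis
#' of the arm (0 = telomere, 1 = centromere; the centromere is taken at
#' the chromosome midpoint unless given).
#'
#' @param genes a \code{GRanges} of gene loci (needs \code{seqlengths}
#'   for relative positions; falls back to the last gene end).
#' @param centromeres optional named vector of centromere positions (bp).
#' @return data.frame with columns \code{x} (gap bp), \code{chromosome},
#'   \code{rel_pos} (fraction of chromosome), \code{arm_pos} (0 telomere
#'   to 1 centromere); attribute \code{dropped} counts non-positive gaps.
#' @export
intergenicGaps <- function(genes, centromeres = NULL) {
  stopifnot(is(genes, "GRanges"))
  if (length(genes) < 2) {
    out <- data.frame(x = numeric(0), chromosome = character(0),
                      rel_pos = numeric(0), arm_pos = numeric(0))
    attr(out, "dropped") <- 0L
    return(out)
  }
  genes <- sort(genes, ignore.strand = TRUE)
  dropped <- 0L
  res <- list()
  for (chr in unique(as.character(seqnames(genes)))) {
    g <- genes[as.character(seqnames(genes)) == chr]
    if (length(g) < 2) next
    gap <- start(g)[-1] - end(g)[-length(g)] - 1
    mid <- (end(g)[-length(g)] + start(g)[-1]) / 2
    L <- seqlengths(genes)[chr]
    if (is.na(L)) L <- max(end(g))
    cen <- if (!is.null(centromeres) && chr %in% names(centromeres))
      centromeres[[chr]] else L / 2
    keep <- gap > 0
    dropped <- dropped + sum(!keep)
    armPos <- ifelse(mid <= cen, mid / cen, (L - mid) / (L - cen))
    res[[chr]] <- data.frame(x = gap[keep],
                             chromosome = rep(chr, sum(keep)),
                             rel_pos = (mid / L)[keep],
                             arm_pos = pmin(pmax(armPos[keep], 0), 1))
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  if (is.null(out) || nrow(out) == 0)
    stop("all gaps are non-positive: genes overlap everywhere")
  attr(out, "dropped") <- dropped
  out
}

#' Maximum-likelihood exponential fit to gaps
#'
#' Under homogeneously (Poisson) distributed gene starts, intergenic
#' distances are exponential with density \eqn{f(x) = \lambda
#' e^{-\lambda x}}; the MLE is \eqn{\hat\lambda = 1/\bar x}.
#'
#' @param x positive gap lengths in bp (or a data.frame from
#'   \code{\link{intergenicGaps}}).
#' @return list with \code{rate} (per bp), \code{loglik}, \code{n}.
#' @export
fitExponentialGaps <- function(x) {
  if (is.data.frame(x)) x <- x$x
  if (length(x) < 2) stop("need at least 2 gaps")
  if (any(x <= 0)) stop("gaps must be positive")
  lam <- 1 / mean(x)
  list(rate = lam, loglik = length(x) * log(lam) - lam * sum(x),
       n = length(x))
}

.em_once <- function(x, pi0, lambda0, maxIter, tol, keepResp) {
  .exp_mixture_em_cpp(x, pi0, lambda0, as.integer(maxIter), tol, keepResp)
}

#' Fit an exponential mixture to intergenic gaps by EM
#'
#' Models gaps as a K-component mixture of exponentials, the "insulae"
#' alternative to the homogeneous (single exponential) null: a fast rate
#' for short intra-insular gaps and slower rates for long inter-insular
#' gaps.  EM is run from \code{nRestarts} random quantile-anchored
#' starts; the best local optimum is kept and components are reported in
#' strictly decreasing rate order.
#'
#' @param x positive gap lengths (or a data.frame from
#'   \code{\link{intergenicGaps}}).
#' @param K number of components (>= 1).
#' @param nRestarts random EM restarts.
#' @param maxIter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param keepResponsibilities retain the n-by-K posterior matrix.
#' @return an \code{\linkS4class{ExpMixtureFit}}.
#' @export
fitExpMixture <- function(x, K = 2, nRestarts = 5, maxIter = 2000,
                          tol = 1e-9, keepResponsibilities = TRUE) {
  if (is.data.frame(x)) x <- x$x
  if (K < 1) stop("'K' must be >= 1")
  if (length(x) < 10 * K)
    stop("need at least 10 K observations; got ", length(x))
  if (any(x <= 0)) stop("gaps must be positive")
  if (K == 1) {
    f <- fitExponentialGaps(x)
    return(new("ExpMixtureFit", K = 1L, weights = 1, rates = f$rate,
               logLik = f$loglik,
               responsibilities = matrix(1, if (keepResponsibilities)
                 length(x) else 0, 1),
               trace = f$loglik, degenerate = FALSE))
  }
  best <- NULL
  for (r in seq_len(nRestarts)) {
    # anchor rates at spread quantiles of the data, jittered
    qs <- quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE)
    lam0 <- 1 / (qs * exp(runif(K, -0.5, 0.5)))
    pi0 <- rep(1 / K, K)
    fit <- .em_once(x, pi0, sort(lam0, decreasing = TRUE), maxIter, tol,
                    FALSE)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (nRestarts > 1) {
    # one hierarchical start splits a small component off the (K-1)-fit,
    # so the K-component optimum never falls below the (K-1) one
    sub <- fitExpMixture(x, K - 1, nRestarts = max(1, nRestarts - 1),
                         maxIter = maxIter, tol = tol,
                         keepResponsibilities = FALSE)
    eps <- 0.01
    fit <- .em_once(x, c(sub@weights * (1 - eps), eps),
                    c(sub@rates, max(sub@rates) * 5), maxIter, tol, FALSE)
    if (fit$loglik > best$loglik) best <- fit
  }
  fit <- if (keepResponsibilities)
    # one short pass from the winning optimum recovers responsibilities
    .em_once(x, best$weights, best$rates, maxIter, tol, TRUE)
  else best
  if (any(fit$weights < 1e-6)) {
    sub <- fitExpMixture(x, K - 1, nRestarts, maxIter, tol,
                         keepResponsibilities)
    return(new("ExpMixtureFit", K = sub@K, weights = sub@weights,
               rates = sub@rates, logLik = sub@logLik,
               responsibilities = sub@responsibilities, trace = sub@trace,
               degenerate = TRUE))
  }
  o <- order(fit$rates, decreasing = TRUE)
  resp <- if (keepResponsibilities) fit$responsibilities[, o, drop = FALSE]
  else matrix(0, 0, K)
  rates <- fit$rates[o]
  # numerically tied components: nudge apart to keep strict ordering
  for (k in seq_len(K - 1))
    if (rates[k + 1] >= rates[k]) rates[k + 1] <- rates[k] * (1 - 1e-12)
  new("ExpMixtureFit", K = as.integer(K), weights = fit$weights[o],
      rates = rates, logLik = fit$loglik, responsibilities = resp,
      trace = fit$trace, degenerate = FALSE)
}

#' Likelihood-ratio test of gene-distribution homogeneity
#'
#' Tests the null that intergenic gaps are exponential (homogeneous
#' Poisson gene placement) against a K-component exponential mixture
#' (insulae).  Because the null lies on the boundary of the mixture
#' parameter space, the null distribution of the statistic
#' \eqn{\Lambda = 2(\ell_{mix} - \ell_{exp})} is calibrated by a
#' parametric bootstrap from the fitted exponential:
#' \eqn{p = (1 + \#\{\Lambda_b \ge \Lambda\}) / (B + 1)}.
#'
#' @param x positive gap lengths (or a data.frame from
#'   \code{\link{intergenicGaps}}).
#' @param K mixture components of the alternative.
#' @param B bootstrap replicates (>= 99).
#' @param seed optional integer seed for the bootstrap.
#' @param nRestarts EM restarts, applied identically to the observed and
#'   every bootstrap fit (asymmetric optimization effort would bias the
#'   statistic's null calibration).
#' @param maxIter EM iteration cap per fit.
#' @return list with \code{statistic}, \code{p.value}, \code{B},
#'   \code{fit_null}, \code{fit_mixture}, \code{calibration}.
#' @export
lrtHomogeneity <- function(x, K = 2, B = 999, seed = NULL, nRestarts = 2,
                           maxIter = 500) {
  if (is.data.frame(x)) x <- x$x
  if (B < 99) stop("'B' must be at least 99")
  if (!is.null(seed)) set.seed(.substream(seed, "lrt_bootstrap"))
  f0 <- fitExponentialGaps(x)
  f1 <- fitExpMixture(x, K = K, nRestarts = nRestarts, maxIter = maxIter,
                      keepResponsibilities = FALSE)
  stat <- 2 * (f1@logLik - f0$loglik)
  if (!is.finite(stat))
    stop("non-finite likelihood ratio; inspect the EM fit (", f1@logLik,
         " vs ", f0$loglik, ")")
  stat <- max(stat, 0)
  n <- length(x)
  statB <- vapply(seq_len(B), function(b) {
    xb <- rexp(n, f0$rate)
    fb0 <- fitExponentialGaps(xb)
    fb1 <- fitExpMixture(xb, K = K, nRestarts = nRestarts,
                         maxIter = maxIter, keepResponsibilities = FALSE)
    max(2 * (fb1@logLik - fb0$loglik), 0)
  }, numeric(1))
  list(statistic = stat, p.value = (1 + sum(statB >= stat)) / (B + 1),
       B = B, fit_null = f0, fit_mixture = f1, calibration = "bootstrap")
}

#' Chi-square goodness of fit of the exponential gap model
#'
#' Pearson chi-square against the fitted exponential, using
#' equal-probability bins of the fitted distribution; df = bins - 2
#' (one for the estimated rate, one for the total).
#'
#' @param x positive gap lengths (or a data.frame from
#'   \code{\link{intergenicGaps}}).
#' @param fit result of \code{\link{fitExponentialGaps}}; refitted when
#'   missing.
#' @param nBins number of equal-probability bins (>= 3); expected count
#'   per bin must be >= 5.
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @export
chisqGof <- function(x, fit = NULL, nBins = 10) {
  if (is.data.frame(x)) x <- x$x
  if (nBins < 3) stop("'nBins' must be >= 3 (df = nBins - 2 > 0)")
  if (length(x) / nBins < 5)
    stop("expected count per bin below 5; reduce 'nBins'")
  if (is.null(fit)) fit <- fitExponentialGaps(x)
  brk <- qexp((0:nBins) / nBins, rate = fit$rate)
  brk[1] <- 0; brk[nBins + 1] <- Inf
  obs <- tabulate(findInterval(x, brk, rightmost.closed = TRUE),
                  nbins = nBins)
  expd <- length(x) / nBins
  stat <- sum((obs - expd)^2 / expd)
  df <- nBins - 2
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE))
}

#' Mean inter-insular gap by arm region
#'
#' Gaps whose posterior probability on the long-gap mixture component
#' exceeds 0.5 are classified inter-insular; arms are cut into distal,
#' middle and proximal thirds of the centromere-telomere axis, and the
#' mean inter-insular gap is reported per third.  Distal shortening of
#' inter-insular distances appears as a smaller distal mean.
#'
#' @param sample data.frame from \code{\link{intergenicGaps}} (needs
#'   \code{arm_pos}).
#' @param fit a K = 2 \code{\linkS4class{ExpMixtureFit}} with retained
#'   responsibilities for the same gaps.
#' @return data.frame with columns \code{region}, \code{n},
#'   \code{mean_gap} (NA for empty regions).
#' @export
interInsularShortening <- function(sample, fit) {
  stopifnot(is(fit, "ExpMixtureFit"))
  if (fit@K != 2) stop("a K = 2 mixture fit is required")
  resp <- responsibilities(fit)
  if (nrow(resp) != nrow(sample))
    stop("responsibilities do not match the gap sample")
  inter <- resp[, 2] > 0.5   # component 2 = long-gap (smaller rate)
  region <- cut(sample$arm_pos, c(0, 1 / 3, 2 / 3, 1),
                labels = c("distal", "middle", "proximal"),
                include.lowest = TRUE)
  out <- data.frame(region = c("distal", "middle", "proximal"),
                    n = NA_integer_, mean_gap = NA_real_)
  for (i in seq_len(3)) {
    sel <- inter & region == out$region[i]
    out$n[i] <- sum(sel)
    out$mean_gap[i] <- if (any(sel)) mean(sample$x[sel]) else NA_real_
  }
  out
}
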