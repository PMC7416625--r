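#' @importFrom stats isoreg approx cor.test aggregate
#' @importFrom KernSmooth locpoly
NULL

#' Build a Marey map from a genetic map
#'
#' Per chromosome, markers are sorted by physical position, duplicate bp
#' positions are averaged (with a warning), the cM sequence is made
#' non-decreasing by isotonic (pool-adjacent-violators) projection, and
#' the smoothing parameters of a local polynomial fit of cM on bp are
#' stored.  The fitted function and its first derivative (the
#' recombination rate) can then be evaluated anywhere on the chromosome.
#'
#' @param markers data.frame with columns \code{chromosome}, \code{bp},
#'   \code{cM} (see \code{\link{readGeneticMap}}).
#' @param bandwidth smoothing bandwidth in bp; default is chromosome
#'   length / 20.
#' @param degree local polynomial degree (2 by default: for derivative
#'   estimation the polynomial order should exceed the derivative order
#'   by an odd amount).
#' @param chromLengths optional named vector of chromosome lengths in
#'   bp; defaults to the last marker position per chromosome.
#' @param minMarkers minimum markers per chromosome.
#' @return a \code{\linkS4class{MareyMap}}.
#' @export
mareyMap <- function(markers, bandwidth = NULL, degree = 2,
                     chromLengths = NULL, minMarkers = 10) {
  support <- list()
  bw <- numeric(0)
  lens <- numeric(0)
  for (chr in unique(markers$chromosome)) {
    m <- markers[markers$chromosome == chr, ]
    m <- m[order(m$bp), ]
    if (anyDuplicated(m$bp)) {
      warning("duplicate bp positions on ", chr, ": cM averaged")
      m <- aggregate(cM ~ bp, data = m, FUN = mean)
    }
    if (nrow(m) < minMarkers)
      stop("chromosome ", chr, " has fewer than ", minMarkers, " markers")
    L <- if (!is.null(chromLengths) && chr %in% names(chromLengths))
      chromLengths[[chr]] else max(m$bp)
    cm <- isoreg(m$bp, m$cM)$yf
    support[[chr]] <- data.frame(bp = m$bp, cM = cm)
    bw[chr] <- if (is.null(bandwidth)) L / 20 else bandwidth
    lens[chr] <- L
  }
  new("MareyMap", support = support, bandwidth = bw,
      degree = as.integer(degree), chromLengths = lens)
}

.locpoly_eval <- function(mapfun, chr, drv, gridsize = 801) {
  s <- mapfun@support[[chr]]
  if (is.null(s)) stop("no Marey map for chromosome ", chr)
  locpoly(s$bp, s$cM, drv = drv, degree = mapfun@degree,
          bandwidth = mapfun@bandwidth[[chr]], gridsize = gridsize,
          range.x = c(0, mapfun@chromLengths[[chr]]))
}

#' Genetic position (cM) at arbitrary physical positions
#'
#' @param mapfun a \code{\linkS4class{MareyMap}}.
#' @param chromosome chromosome name.
#' @param positions physical positions in bp.
#' @return genetic positions in cM.
#' @export
geneticPosition <- function(mapfun, chromosome, positions) {
  fit <- .locpoly_eval(mapfun, chromosome, drv = 0)
  approx(fit$x, fit$y, xout = positions, rule = 2)$y
}

#' Local recombination rate (cM/Mb) at arbitrary positions
#'
#' First derivative of the Marey-map local polynomial, converted to
#' cM/Mb; negative estimates are clipped to zero.  Positions outside the
#' chromosome take the boundary value and are flagged in the
#' \code{out_of_support} attribute.
#'
#' @param mapfun a \code{\linkS4class{MareyMap}}.
#' @param chromosome chromosome name.
#' @param positions physical positions in bp.
#' @return numeric rates in cM/Mb (attribute \code{out_of_support}).
#' @export
recombinationRate <- function(mapfun, chromosome, positions) {
  fit <- .locpoly_eval(mapfun, chromosome, drv = 1)
  outside <- positions < min(fit$x) | positions > max(fit$x)
  rate <- approx(fit$x, fit$y, xout = positions, rule = 2)$y * 1e6
  rate <- pmax(rate, 0)
  attr(rate, "out_of_support") <- outside
  rate
}

#' Gene density profile in 10-Mb bins with bidirectional smoothing
#'
#' Gene (or any feature) starts are counted in fixed windows anchored at
#' the short-arm tip.  Two three-bin sliding means run in opposite
#' directions (one from each chromosome tip, truncated at the edges) and
#' are averaged per bin; raw counts are conserved exactly.
#'
#' @param positions gene start positions in bp, or a \code{GRanges}
#'   (starts are used).
#' @param chromosomeLength chromosome length in bp (>= 3 windows).
#' @param window window size in bp.
#' @return data.frame with columns \code{midpoint}, \code{raw},
#'   \code{smoothed}.
#' @export
geneDensityProfile <- function(positions, chromosomeLength,
                               window = 1e7) {
  if (is(positions, "GRanges")) positions <- start(positions)
  if (chromosomeLength < 3 * window)
    stop("chromosome shorter than 3 windows")
  nb <- ceiling(chromosomeLength / window)
  raw <- tabulate(pmin(floor(positions / window) + 1, nb), nbins = nb)
  fwd <- vapply(seq_len(nb), function(i)
    mean(raw[max(1, i - 2):i]), numeric(1))
  rev_ <- vapply(seq_len(nb), function(i)
    mean(raw[i:min(nb, i + 2)]), numeric(1))
  data.frame(midpoint = (seq_len(nb) - 0.5) * window, raw = raw,
             smoothed = (fwd + rev_) / 2)
}

#' Correlation of gene density with recombination rate
#'
#' Pearson correlation between the per-window gene density and the
#' recombination rate evaluated at the window midpoints, with the
#' two-sided p-value from the t transform.
#'
#' @param density data.frame from \code{\link{geneDensityProfile}}.
#' @param mapfun a \code{\linkS4class{MareyMap}}.
#' @param chromosome chromosome name.
#' @param useSmoothed correlate the smoothed (default) or raw counts.
#' @return list with \code{r}, \code{p.value}, \code{n}.
#' @export
densityRecombCorrelation <- function(density, mapfun, chromosome,
                                     useSmoothed = TRUE) {
  if (nrow(density) < 4) stop("need at least 4 windows")
  y <- if (useSmoothed) density$smoothed else density$raw
  rate <- recombinationRate(mapfun, chromosome, density$midpoint)
  if (var(y) == 0 || var(rate) == 0)
    stop("zero-variance input: correlation undefined")
  ct <- cor.test(y, as.numeric(rate))
  list(r = unname(ct$estimate), p.value = ct$p.value, n = nrow(density))
}

#' Multi-gene resistance-gene-analogue loci
#'
#' Chains genes of one RGA class per chromosome by single linkage with
#' link distance strictly below \code{maxGap}; chains with at least
#' \code{minCount} members form a multi-gene locus.
#'
#' @param rgaGenes data.frame with columns \code{gene}, \code{class},
#'   \code{chromosome}, \code{start}.
#' @param minCount minimum genes per locus.
#' @param maxGap maximum adjacent distance in bp (strict).
#' @return data.frame of loci: \code{class}, \code{chromosome},
#'   \code{start}, \code{end}, \code{n}, \code{genes}
#'   (comma-separated ids).
#' @export
rgaMultigeneLoci <- function(rgaGenes, minCount = 3, maxGap = 3e5) {
  out <- list()
  for (cl in unique(rgaGenes$class)) {
    for (chr in unique(rgaGenes$chromosome[rgaGenes$class == cl])) {
      g <- rgaGenes[rgaGenes$class == cl & rgaGenes$chromosome == chr, ]
      g <- g[order(g$start), ]
      grp <- cumsum(c(1, diff(g$start) >= maxGap))
      for (k in unique(grp)) {
        gg <- g[grp == k, ]
        if (nrow(gg) >= minCount)
          out[[length(out) + 1]] <- data.frame(
            class = cl, chromosome = chr, start = min(gg$start),
            end = max(gg$start), n = nrow(gg),
            genes = paste(gg$gene, collapse = ","))
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(class = character(0), chromosome = character(0),
                      start = numeric(0), end = numeric(0),
                      n = integer(0), genes = character(0)))
  do.call(rbind, out)
}

#' RGA-to-gene density ratio in sliding windows
#'
#' Ratio of RGA count to total gene count in 10-Mb windows advanced by
#' 8 Mb (2 Mb of overlap between consecutive windows), which controls
#' for the higher overall gene density of distal chromosome regions.
#' Windows without genes get ratio 0 and are flagged.
#'
#' @param rgaPositions RGA gene start positions in bp.
#' @param genePositions all gene start positions in bp.
#' @param chromosomeLength chromosome length in bp.
#' @param window,step window size and step in bp.
#' @return data.frame with \code{start}, \code{end}, \code{rga},
#'   \code{genes}, \code{ratio}, \code{empty}.
#' @export
rgaDensityRatio <- function(rgaPositions, genePositions,
                            chromosomeLength, window = 1e7, step = 8e6) {
  starts <- seq(0, max(chromosomeLength - 1, 0), by = step)
  out <- data.frame(start = starts, end = pmin(starts + window,
                                               chromosomeLength))
  out$rga <- vapply(seq_len(nrow(out)), function(i)
    sum(rgaPositions > out$start[i] & rgaPositions <= out$end[i]),
    numeric(1))
  out$genes <- vapply(seq_len(nrow(out)), function(i)
    sum(genePositions > out$start[i] & genePositions <= out$end[i]),
    numeric(1))
  out$empty <- out$genes == 0
  out$ratio <- ifelse(out$empty, 0, out$rga / pmax(out$genes, 1))
  out
}
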