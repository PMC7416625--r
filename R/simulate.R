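#' @importFrom stats rexp rnorm rpois runif rgamma rbinom
#' @importFrom Biostrings DNAStringSet
NULL

## Hierarchical seeding: every generator derives its own sub-seed from the
## global seed and a fixed label, so adding one generator to a workflow
## never perturbs the draws of another.
.substream <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 99991L
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

.maybe_seed <- function(seed, label) {
  if (!is.null(seed)) set.seed(.substream(seed, label))
  invisible(NULL)
}

#' Simulate an LTR retrotransposon cohort with known ages
#'
#' Draws insertion ages from a burst-like (truncated Gaussian), gamma, or
#' uniform age distribution, thins the cohort by exponential survival
#' \eqn{\exp(-\delta Y)}, and draws LTR-pair mismatch counts
#' \eqn{N \sim Poisson(2 r l Y)} with \eqn{Y} in years.  Ground truth
#' (all draws, including elements removed by thinning) is returned.
#'
#' @param n number of inserted elements before survival thinning (> 0).
#' @param ageDist one of \code{"burst"}, \code{"gamma"}, \code{"uniform"}.
#' @param burstCenter,burstSd centre and s.d. (Myr) of the Gaussian burst,
#'   truncated to non-negative ages.
#' @param gammaShape,gammaRate gamma age parameters (rate per Myr).
#' @param maxAge upper age (Myr) for the uniform age mode.
#' @param ltrLength LTR length(s) in bp, recycled to \code{n}.
#' @param deletionRate survival thinning rate \eqn{\delta} per Myr.
#' @param mutationRate substitution rate per site per year.
#' @param family family name stored with each element.
#' @param chromosome,chromosomeLength where elements are placed
#'   (uniformly); the centromere is taken at the chromosome midpoint for
#'   the \code{dist_to_centromere} column.
#' @param seed optional integer seed (hierarchical sub-stream).
#' @return list with \code{elements} (data.frame of surviving elements:
#'   family, chromosome, position, dist_to_centromere, ltr_length,
#'   mismatches, age_myr) and \code{truth} (all ages, retention flags and
#'   the generating parameters).
#' @export
simulateTeCohort <- function(n, ageDist = c("burst", "gamma", "uniform"),
                             burstCenter = 1.0, burstSd = 0.25,
                             gammaShape = 2, gammaRate = 2, maxAge = 3,
                             ltrLength = 1000, deletionRate = 1,
                             mutationRate = 1.3e-8, family = "RLC_fam1",
                             chromosome = "1D", chromosomeLength = 6e8,
                             seed = NULL) {
  if (n <= 0) stop("'n' must be positive")
  ageDist <- match.arg(ageDist)
  .maybe_seed(seed, "te_cohort")
  ages <- switch(ageDist,
    burst = {
      if (burstSd <= 0) rep(burstCenter, n) else {
        y <- rnorm(n, burstCenter, burstSd)
        while (any(y < 0)) y[y < 0] <- rnorm(sum(y < 0), burstCenter, burstSd)
        y
      }
    },
    gamma = rgamma(n, shape = gammaShape, rate = gammaRate),
    uniform = runif(n, 0, maxAge))
  keep <- runif(n) < exp(-deletionRate * ages)
  l <- rep_len(ltrLength, n)
  mism <- rpois(n, 2 * mutationRate * l * ages * 1e6)
  mism <- pmin(mism, l)
  pos <- round(runif(n, 1, chromosomeLength))
  elements <- data.frame(
    family = family, chromosome = chromosome, position = pos,
    dist_to_centromere = abs(pos - chromosomeLength / 2),
    ltr_length = l, mismatches = mism, age_myr = ages)[keep, ]
  rownames(elements) <- NULL
  list(elements = elements,
       truth = list(ages_inserted = ages, retained = keep,
                    params = list(ageDist = ageDist,
                                  burstCenter = burstCenter,
                                  burstSd = burstSd,
                                  gammaShape = gammaShape,
                                  gammaRate = gammaRate, maxAge = maxAge,
                                  deletionRate = deletionRate,
                                  mutationRate = mutationRate)))
}

#' Simulate gene positions along a chromosome
#'
#' Under the null, intergenic gaps are i.i.d. exponential (a homogeneous
#' Poisson process of gene starts).  Under the alternative, gaps follow a
#' two-component exponential mixture (short intra-insular and long
#' inter-insular gaps), and the inter-insular rate is increased towards
#' the chromosome ends by a distal shortening factor, making gene
#' clusters more closely spaced distally.
#'
#' @param chromosomeLength chromosome length in bp.
#' @param nullMode when \code{TRUE}, gaps are exponential(\code{lambda}).
#' @param lambda null gap rate per bp.
#' @param weightShort mixture weight of the short-gap component.
#' @param rateShort,rateLong mixture component rates per bp.
#' @param distalShortening multiplier applied to \code{rateLong} at the
#'   chromosome ends, decaying linearly to 1 at the centre; 1 disables
#'   the distal effect.
#' @param geneWidth fixed gene width in bp.
#' @param chromosome chromosome name.
#' @param seed optional integer seed.
#' @return a \code{GRanges} of genes with \code{gene_id} and
#'   \code{confidence_class} columns and the chromosome length recorded
#'   in \code{seqlengths}; empty (with a warning) when no gene fits.
#' @export
simulateGenePositions <- function(chromosomeLength, nullMode = FALSE,
                                  lambda = 1e-4, weightShort = 0.7,
                                  rateShort = 1 / 5000, rateLong = 1 / 1e5,
                                  distalShortening = 3, geneWidth = 2000,
                                  chromosome = "1D", seed = NULL) {
  stopifnot(lambda > 0, rateShort > 0, rateLong > 0,
            weightShort > 0, weightShort < 1, distalShortening >= 1)
  .maybe_seed(seed, "gene_positions")
  starts <- numeric(0)
  pos <- 0
  repeat {
    gap <- if (nullMode) rexp(1, lambda)
    else if (runif(1) < weightShort) rexp(1, rateShort)
    else {
      rel <- 2 * abs(pos / chromosomeLength - 0.5)  # 0 centre, 1 ends
      rexp(1, rateLong * (1 + (distalShortening - 1) * rel))
    }
    s <- pos + ceiling(gap) + 1
    e <- s + geneWidth - 1
    if (e > chromosomeLength) break
    starts <- c(starts, s)
    pos <- e
  }
  if (length(starts) == 0) {
    warning("chromosome too short for a single gene")
    gr <- GRanges(gene_id = character(0), confidence_class = character(0))
    return(gr)
  }
  gr <- GRanges(chromosome, IRanges(starts, width = geneWidth), strand = "+")
  mcols(gr) <- DataFrame(
    gene_id = sprintf("G%05d", seq_along(starts)),
    confidence_class = "HCC")
  seqlengths(gr) <- stats::setNames(chromosomeLength, chromosome)
  gr
}

#' Simulate a genetic map with U-shaped recombination density
#'
#' Recombination density along the chromosome is
#' \eqn{d(u) = \epsilon + (1-\epsilon)((2u-1)^2)^p} for relative position
#' \eqn{u \in [0,1]}: flat for \eqn{p = 0} and increasingly U-shaped
#' (suppressed pericentromeric recombination, elevated distal
#' recombination) as \eqn{p} grows.  Marker genetic positions are the
#' closed-form integral of the density scaled to \code{totalCM}.
#'
#' @param chromosomeLength chromosome length in bp.
#' @param nMarkers number of markers (>= 2), placed uniformly at random.
#' @param totalCM total map length in centimorgans.
#' @param uExponent U-shape exponent \eqn{p >= 0}.
#' @param densityFloor \eqn{\epsilon}, the relative density retained at
#'   the chromosome midpoint.
#' @param noiseSD optional s.d. (cM) of additive marker noise; the
#'   default 0 yields an exactly monotone map.
#' @param chromosome chromosome name.
#' @param seed optional integer seed.
#' @return list with \code{map} (data.frame marker/chromosome/bp/cM) and
#'   \code{truth} (the true rate function in cM/Mb and the cumulative cM
#'   function, both of bp).
#' @export
simulateGeneticMap <- function(chromosomeLength, nMarkers = 200,
                               totalCM = 150, uExponent = 2,
                               densityFloor = 0.02, noiseSD = 0,
                               chromosome = "1D", seed = NULL) {
  if (nMarkers < 2) stop("at least 2 markers are required")
  stopifnot(uExponent >= 0, densityFloor >= 0, densityFloor <= 1)
  .maybe_seed(seed, "genetic_map")
  p <- uExponent; eps <- densityFloor
  norm <- eps + (1 - eps) / (2 * p + 1)
  cumRel <- function(u)  # integral of the density from 0 to u, / norm
    (eps * u + (1 - eps) * ((2 * u - 1)^(2 * p + 1) + 1) /
       (2 * (2 * p + 1))) / norm
  cmFun <- function(bp) totalCM * cumRel(pmin(pmax(bp / chromosomeLength,
                                                   0), 1))
  rateFun <- function(bp) {  # true rate in cM/Mb
    u <- pmin(pmax(bp / chromosomeLength, 0), 1)
    totalCM * ((eps + (1 - eps) * ((2 * u - 1)^2)^p) / norm) /
      chromosomeLength * 1e6
  }
  bp <- sort(round(runif(nMarkers, 1, chromosomeLength)))
  cM <- cmFun(bp)
  if (noiseSD > 0) cM <- cM + rnorm(nMarkers, 0, noiseSD)
  map <- data.frame(marker = sprintf("M%04d", seq_len(nMarkers)),
                    chromosome = chromosome, bp = bp, cM = cM)
  list(map = map,
       truth = list(rateFun = rateFun, cmFun = cmFun, totalCM = totalCM,
                    uExponent = p, densityFloor = eps,
                    chromosomeLength = chromosomeLength))
}

.event_code <- function(type, size) {
  switch(type,
         inv = if (size == 2) "A" else if (size == 3) "B" else "C",
         trans = if (size == 2) "D" else if (size == 3) "E" else "F",
         iT = "iT", T = "T", dup = "Dup", del = "Del",
         stop("unknown event type: ", type))
}

#' Draw a random non-overlapping rearrangement plan
#'
#' Chooses event types, sizes and query positions such that planted
#' events (including translocation target sites) are separated by at
#' least \code{minSeparation} colinear genes.
#'
#' @param nGenes number of genes in the table the plan is for.
#' @param nEvents number of events to plant.
#' @param types event types to draw from: \code{inv} (inversion),
#'   \code{trans} (within-chromosome translocation), \code{iT}
#'   (intercalated between-chromosome translocation), \code{T} (terminal
#'   translocation), \code{dup} (segment duplication), \code{del}
#'   (segment deletion).
#' @param minSeparation minimum number of untouched genes between events.
#' @param seed optional integer seed.
#' @return data.frame with columns \code{type}, \code{at}, \code{size},
#'   \code{target} (NA except for \code{trans} and \code{dup}).
#' @export
randomRearrangementPlan <- function(nGenes, nEvents,
                                    types = c("inv", "trans", "iT", "T",
                                              "dup", "del"),
                                    minSeparation = 6, seed = NULL) {
  .maybe_seed(seed, "rearrangement_plan")
  used <- logical(nGenes)  # genes consumed by events or their margins
  claim <- function(lo, hi) {
    lo2 <- max(1, lo - minSeparation); hi2 <- min(nGenes, hi + minSeparation)
    if (any(used[lo2:hi2])) return(FALSE)
    used[lo2:hi2] <<- TRUE
    TRUE
  }
  plan <- NULL
  guard <- 0
  while (is.null(plan) || nrow(plan) < nEvents) {
    guard <- guard + 1
    if (guard > 500) stop("could not place all events; too crowded")
    type <- sample(types, 1)
    size <- switch(type,
                   inv = sample(c(2, 3, sample(4:8, 1)), 1),
                   trans = sample(c(2, 3, sample(4:8, 1)), 1),
                   iT = sample(2:8, 1), T = sample(2:8, 1),
                   dup = sample(2:5, 1), del = sample(2:5, 1))
    if (type == "T") {
      terminalAtEnd <- runif(1) < 0.5
      at <- if (terminalAtEnd) nGenes - size + 1 else 1
    } else {
      at <- sample(seq(minSeparation + 1, nGenes - size - minSeparation), 1)
    }
    if (!claim(at, at + size - 1)) next
    target <- NA_integer_
    if (type %in% c("trans", "dup")) {
      ok <- FALSE
      for (i in seq_len(50)) {
        tg <- sample(seq(minSeparation + 1, nGenes - minSeparation - 1), 1)
        if (claim(tg, tg + 1)) { target <- tg; ok <- TRUE; break }
      }
      if (!ok) { used[max(1, at - minSeparation):
                        min(nGenes, at + size - 1 + minSeparation)] <- FALSE
                 next }
    }
    plan <- rbind(plan, data.frame(type = type, at = at, size = size,
                                   target = target))
  }
  plan[order(plan$at), ]
}

#' Simulate an ortholog table with planted rearrangements
#'
#' Starts from a colinear identity order (query and subject carry the
#' same genes with realistic spacing) and applies each planted event:
#' inversions, within-chromosome translocations, between-chromosome
#' intercalated and terminal translocations, segment duplications and
#' segment deletions.  The ground truth lists each event with its
#' one-letter code (A/B/C inversions of 2/3/>3 genes, D/E/F
#' within-chromosome translocations of 2/3/>3 genes, iT, T, Dup, Del)
#' and query span.
#'
#' @param nGenes number of colinear genes in the base table.
#' @param plan rearrangement plan as from
#'   \code{\link{randomRearrangementPlan}} (may be \code{NULL} or empty
#'   for an identity table).
#' @param meanSpacing mean intergenic spacing in bp on both genomes.
#' @param queryChrom,subjectChrom,altSubjectChrom chromosome names; the
#'   alternative subject chromosome receives iT/T segments.
#' @param seed optional integer seed.
#' @return list with \code{table} (ortholog data.frame, columns as
#'   \code{\link{readOrthologTable}}) and \code{truth} (data.frame of
#'   planted events: code, type, first_row, last_row, query_start,
#'   query_end, genes).
#' @export
simulateOrthologOrders <- function(nGenes, plan = NULL, meanSpacing = 1e4,
                                   queryChrom = "q1", subjectChrom = "s1",
                                   altSubjectChrom = "s2", seed = NULL) {
  stopifnot(nGenes >= 2)
  .maybe_seed(seed, "ortholog_orders")
  if (is.null(plan)) plan <- data.frame(type = character(0), at = integer(0),
                                        size = integer(0),
                                        target = integer(0))
  if (nrow(plan) > 1) {
    spans <- cbind(plan$at, plan$at + plan$size - 1)
    o <- order(spans[, 1])
    if (any(spans[o, 1][-1] <= spans[o, 2][-nrow(spans)]))
      stop("planted events overlap")
  }
  qpos <- cumsum(1000 + round(rexp(nGenes, 1 / meanSpacing)))
  spos <- cumsum(1000 + round(rexp(nGenes, 1 / meanSpacing)))
  spos0 <- spos  # untouched base order, used for translocation targets
  schrom <- rep(subjectChrom, nGenes)
  hit <- rep(TRUE, nGenes)
  tab <- data.frame(
    query_gene_id = sprintf("Q%05d", seq_len(nGenes)),
    query_chrom = queryChrom, query_start = qpos,
    subject_gene_id = sprintf("S%05d", seq_len(nGenes)),
    subject_chrom = schrom, subject_start = spos, hit_present = hit)
  truth <- NULL
  dupRows <- list()
  for (i in seq_len(nrow(plan))) {
    ev <- plan[i, ]
    idx <- ev$at:(ev$at + ev$size - 1)
    if (ev$type == "inv") {
      tab$subject_start[idx] <- rev(tab$subject_start[idx])
    } else if (ev$type == "trans") {
      j <- ev$target
      gapNew <- spos0[j] + (spos0[j + 1] - spos0[j]) *
        seq_len(ev$size) / (ev$size + 1)
      tab$subject_start[idx] <- round(gapNew)
    } else if (ev$type %in% c("iT", "T")) {
      tab$subject_chrom[idx] <- altSubjectChrom
    } else if (ev$type == "del") {
      tab$hit_present[idx] <- FALSE
    } else if (ev$type == "dup") {
      j <- ev$target
      qNew <- qpos[j] + (qpos[j + 1] - qpos[j]) *
        seq_len(ev$size) / (ev$size + 1)
      dupRows[[length(dupRows) + 1]] <- list(
        after = j,
        rows = data.frame(
          query_gene_id = sprintf("Q%05d_dup", idx),
          query_chrom = queryChrom, query_start = round(qNew),
          subject_gene_id = tab$subject_gene_id[idx],
          subject_chrom = tab$subject_chrom[idx],
          subject_start = tab$subject_start[idx], hit_present = TRUE))
    }
    truth <- rbind(truth, data.frame(
      code = .event_code(ev$type, ev$size), type = ev$type,
      first_row = ev$at, last_row = ev$at + ev$size - 1,
      query_start = qpos[ev$at], query_end = qpos[ev$at + ev$size - 1],
      genes = ev$size, target = ev$target))
  }
  if (length(dupRows)) {
    for (d in rev(dupRows[order(vapply(dupRows, `[[`, 1, "after"))])) {
      j <- d$after
      tab <- rbind(tab[seq_len(j), ], d$rows,
                   tab[seq(j + 1, nrow(tab)), ])
    }
    tab <- tab[order(tab$query_start), ]
    rownames(tab) <- NULL
    # duplicated segments: truth span is where the copy was inserted
    for (k in seq_len(NROW(truth))) {
      if (truth$type[k] == "dup") {
        src <- sprintf("S%05d",
                       truth$first_row[k]:truth$last_row[k])
        rows <- which(grepl("_dup$", tab$query_gene_id) &
                        tab$subject_gene_id %in% src)
        truth$query_start[k] <- tab$query_start[min(rows)]
        truth$query_end[k] <- tab$query_start[max(rows)]
      }
    }
    # row indices shift once copies are inserted; recompute from positions
    truth$first_row <- match(truth$query_start, tab$query_start)
    truth$last_row <- match(truth$query_end, tab$query_start)
  }
  if (is.null(truth))
    truth <- data.frame(code = character(0), type = character(0),
                        first_row = integer(0), last_row = integer(0),
                        query_start = numeric(0), query_end = numeric(0),
                        genes = integer(0), target = integer(0))
  list(table = tab, truth = truth)
}

#' Simulate a chromosome sequence with planted features
#'
#' Generates an i.i.d. uniform A/C/G/T background and plants telomeric
#' repeat arrays (tandem TTTAGGG copies, optionally ending mid-unit),
#' perfect SSR tracts, and copies of a random organellar-like fragment.
#' Placements must lie within bounds and not overlap.
#'
#' @param chromosomeLength sequence length in bp.
#' @param telomeres data.frame(start, copies, extraBases) or NULL; starts
#'   are 1-based; \code{extraBases} leading bases of one further unit may
#'   terminate the array.
#' @param ssrs data.frame(start, motif, copies) or NULL.
#' @param organellar data.frame(start, length) or NULL; all rows copy
#'   prefixes of one fragment drawn once per simulation.
#' @param chromosome sequence name.
#' @param seed optional integer seed.
#' @return list with \code{seq} (a \code{DNAStringSet} of length 1) and
#'   \code{truth} (a \code{GRanges} of planted features, labels
#'   \code{telomere}/\code{ssr}/\code{organellar}).
#' @export
simulateSequence <- function(chromosomeLength, telomeres = NULL,
                             ssrs = NULL, organellar = NULL,
                             chromosome = "1D", seed = NULL) {
  .maybe_seed(seed, "sequence")
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, chromosomeLength, replace = TRUE)
  frag <- paste(sample(bases, 2000, replace = TRUE), collapse = "")
  starts <- integer(0); ends <- integer(0); labels <- character(0)
  plant <- function(start, txt, label) {
    end <- start + nchar(txt) - 1
    if (start < 1 || end > chromosomeLength)
      stop("planted feature outside chromosome bounds")
    if (any(pmax(start, starts) <= pmin(end, ends)))
      stop("planted features overlap")
    s[start:end] <<- strsplit(txt, "")[[1]]
    starts <<- c(starts, start); ends <<- c(ends, end)
    labels <<- c(labels, label)
  }
  unit <- "TTTAGGG"
  if (!is.null(telomeres))
    for (i in seq_len(nrow(telomeres))) {
      extra <- if ("extraBases" %in% names(telomeres))
        telomeres$extraBases[i] else 0
      txt <- paste0(strrep(unit, telomeres$copies[i]),
                    substr(unit, 1, extra))
      plant(telomeres$start[i], txt, "telomere")
    }
  if (!is.null(ssrs))
    for (i in seq_len(nrow(ssrs)))
      plant(ssrs$start[i], strrep(ssrs$motif[i], ssrs$copies[i]), "ssr")
  if (!is.null(organellar))
    for (i in seq_len(nrow(organellar)))
      plant(organellar$start[i], substr(frag, 1, organellar$length[i]),
            "organellar")
  seqs <- DNAStringSet(paste(s, collapse = ""))
  names(seqs) <- chromosome
  truth <- if (length(starts))
    GRanges(chromosome, IRanges(starts, ends), label = labels)
  else GRanges(label = character(0))
  list(seq = seqs, truth = sort(truth))
}
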