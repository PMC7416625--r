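NULL

## Colinearity is the shared order of gene starts along two genomes,
## irrespective of gene orientation.  All operations work on the
## hit-bearing subsequence of an ordered best-hit ortholog table: query
## genes without a subject hit are transparent.

#' Detect colinear gene runs in an ortholog table
#'
#' A run is a maximal set of consecutive hit-bearing query genes whose
#' subject hits lie on one subject chromosome in strictly ascending or
#' descending order of subject start, with adjacent subject gaps below
#' \code{maxGapBp}, and containing at least \code{minGenes} genes.  Runs
#' never overlap.  For self-synteny scans of a duplicated genome the
#' conventional preset is \code{minGenes = 5, maxGapBp = 5e6}.
#'
#' @param table ortholog data.frame (see
#'   \code{\link{readOrthologTable}}).
#' @param minGenes minimum genes per run (>= 2).
#' @param maxGapBp maximum adjacent subject gap in bp (strict).
#' @return data.frame of runs: \code{first_row}, \code{last_row} (row
#'   indices into \code{table}), \code{genes}, \code{direction},
#'   \code{subject_chrom}; zero rows for an empty table.
#' @export
detectRuns <- function(table, minGenes = 3, maxGapBp = 5e5) {
  if (minGenes < 2) stop("'minGenes' must be >= 2")
  empty <- data.frame(first_row = integer(0), last_row = integer(0),
                      genes = integer(0), direction = character(0),
                      subject_chrom = character(0))
  if (NROW(table) == 0) return(empty)
  idx <- which(table$hit_present)
  if (length(idx) < minGenes) return(empty)
  sc <- table$subject_chrom[idx]
  ss <- table$subject_start[idx]
  sid <- table$subject_gene_id[idx]
  # strict order with subject_gene_id as tie-break
  cmp <- function(i, j) {
    if (ss[i] != ss[j]) sign(ss[j] - ss[i]) else sign((sid[j] > sid[i]) -
                                                       (sid[j] < sid[i]))
  }
  runs <- list()
  i <- 1L
  n <- length(idx)
  while (i < n) {
    j <- i
    dir <- 0L
    while (j < n) {
      if (sc[j + 1] != sc[j]) break
      if (abs(ss[j + 1] - ss[j]) >= maxGapBp) break
      d <- cmp(j, j + 1)
      if (d == 0L) break                       # exact tie: flagged break
      if (dir == 0L) dir <- d else if (d != dir) break
      j <- j + 1L
    }
    if (j - i + 1L >= minGenes)
      runs[[length(runs) + 1L]] <- data.frame(
        first_row = idx[i], last_row = idx[j], genes = j - i + 1L,
        direction = if (dir >= 0L) "ascending" else "descending",
        subject_chrom = sc[i])
    i <- j + 1L
  }
  if (length(runs) == 0) return(empty)
  do.call(rbind, runs)
}

#' Percentage of colinear genes and its 50-gene profile
#'
#' Overall colinearity is the number of genes inside runs expressed as a
#' percentage of all hit-bearing query genes (or of all query genes with
#' \code{denominator = "all"}).  The profile gives the same percentage in
#' consecutive windows of \code{windowGenes} hit-bearing genes.
#'
#' @param table ortholog data.frame.
#' @param runs result of \code{\link{detectRuns}} on the same table.
#' @param denominator \code{"hit"} (hit-bearing genes) or \code{"all"}.
#' @param windowGenes genes per profile window.
#' @return list with \code{overall} (percent) and \code{profile}
#'   (data.frame window, first_row, last_row, percent).
#' @export
colinearityPercent <- function(table, runs, denominator = c("hit", "all"),
                               windowGenes = 50) {
  denominator <- match.arg(denominator)
  inRun <- logical(NROW(table))
  for (k in seq_len(NROW(runs)))
    inRun[runs$first_row[k]:runs$last_row[k]] <- TRUE
  hitIdx <- which(table$hit_present)
  denom <- if (denominator == "hit") length(hitIdx) else NROW(table)
  overall <- if (denom == 0) 0 else 100 * sum(inRun[hitIdx]) / denom
  win <- ceiling(seq_along(hitIdx) / windowGenes)
  prof <- do.call(rbind, lapply(unique(win), function(w) {
    rows <- hitIdx[win == w]
    data.frame(window = w, first_row = rows[1],
               last_row = rows[length(rows)],
               percent = 100 * mean(inRun[rows]))
  }))
  list(overall = overall, profile = prof)
}

#' Collapse tandem-duplicate subject hits
#'
#' When one query gene carries several candidate hits forming a tandem
#' pair on the subject (same chromosome, neighbouring positions), only
#' the copy consistent with the surrounding colinear trend is kept: the
#' copy bracketed by the subject positions of the flanking single-hit
#' rows.  Without a bracketing context the first copy is kept and the
#' row is flagged in the \code{tandem_flagged} attribute.
#'
#' @param table ortholog data.frame, possibly with several rows per
#'   \code{query_gene_id}.
#' @return the collapsed table (one row per query gene), ordered by
#'   query position.
#' @export
tandemCollapse <- function(table) {
  counts <- table(table$query_gene_id)
  multi <- names(counts)[counts > 1]
  if (length(multi) == 0) {
    attr(table, "tandem_flagged") <- character(0)
    return(table)
  }
  flagged <- character(0)
  keep <- rep(TRUE, NROW(table))
  singles <- !table$query_gene_id %in% multi & table$hit_present
  for (g in multi) {
    rows <- which(table$query_gene_id == g)
    prevS <- which(singles & seq_len(NROW(table)) < min(rows) &
                     table$subject_chrom == table$subject_chrom[rows[1]])
    nextS <- which(singles & seq_len(NROW(table)) > max(rows) &
                     table$subject_chrom == table$subject_chrom[rows[1]])
    chosen <- NA_integer_
    if (length(prevS) && length(nextS)) {
      lo <- table$subject_start[max(prevS)]
      hi <- table$subject_start[min(nextS)]
      brk <- sort(c(lo, hi))
      inside <- rows[table$subject_start[rows] > brk[1] &
                       table$subject_start[rows] < brk[2]]
      if (length(inside)) chosen <- inside[1]
    }
    if (is.na(chosen)) {
      chosen <- rows[1]
      flagged <- c(flagged, g)
    }
    keep[setdiff(rows, chosen)] <- FALSE
  }
  out <- table[keep, ]
  out <- out[order(out$query_chrom, out$query_start), ]
  rownames(out) <- NULL
  attr(out, "tandem_flagged") <- flagged
  out
}

## Strip segmentation: over the hit-bearing rows, the subject-order rank
## sequence is cut into maximal stretches with constant rank step +1 or
## -1 on one subject chromosome.  On a table that differs from identity
## only by well-separated rearrangements, the strips that do not belong
## to the maximum-weight ascending chain (the colinear frame) are the
## rearranged segments.
.build_strips <- function(rowIdx, chrom, rank) {
  n <- length(rowIdx)
  if (n == 0) return(NULL)
  stripId <- integer(n)
  sid <- 1L
  stripId[1] <- sid
  step <- NA_integer_
  for (i in seq_len(n - 1)) {
    d <- if (chrom[i + 1] == chrom[i]) rank[i + 1] - rank[i] else NA
    newStrip <- is.na(d) || abs(d) != 1 ||
      (!is.na(step) && d != step)
    if (newStrip) { sid <- sid + 1L; step <- NA_integer_ }
    else step <- d
    stripId[i + 1] <- sid
  }
  strips <- lapply(split(seq_len(n), stripId), function(ii) {
    list(rows = rowIdx[ii], chrom = chrom[ii[1]],
         lo = min(rank[ii]), hi = max(rank[ii]), n = length(ii),
         descending = length(ii) > 1 && rank[ii[2]] < rank[ii[1]])
  })
  unname(strips)
}

.frame_chain <- function(strips, mainChrom) {
  # maximum-weight chain of ascending main-chromosome strips with
  # increasing rank intervals; weight = strip size
  cand <- which(vapply(strips, function(s)
    s$chrom == mainChrom && !s$descending, logical(1)))
  if (length(cand) == 0) return(integer(0))
  m <- length(cand)
  w <- vapply(strips[cand], `[[`, numeric(1), "n")
  lo <- vapply(strips[cand], `[[`, numeric(1), "lo")
  hi <- vapply(strips[cand], `[[`, numeric(1), "hi")
  best <- w
  prev <- rep(0L, m)
  for (i in seq_len(m)) for (j in seq_len(i - 1))
    if (hi[j] < lo[i] && best[j] + w[i] > best[i]) {
      best[i] <- best[j] + w[i]
      prev[i] <- j
    }
  i <- which.max(best)
  chain <- integer(0)
  while (i > 0L) { chain <- c(i, chain); i <- prev[i] }
  cand[chain]
}

#' Classify chromosome rearrangement events in an ortholog table
#'
#' Segments the hit-bearing rows into maximal monotone same-chromosome
#' blocks and classifies every block that falls outside the dominant
#' colinear frame: a reversed block sitting in place is an inversion
#' (codes A/B/C for 2/3/>3 genes); a displaced block on the same subject
#' chromosome is a within-chromosome translocation (D/E/F); a block on
#' another subject chromosome is an intercalated (iT) or, at a query
#' terminus, terminal (T) translocation; a block whose subject interval
#' repeats another block's is a duplication (Dup, >= 2 genes); a run of
#' \code{delThreshold} or more consecutive query genes without subject
#' hits is a deletion (Del).
#'
#' @param table ortholog data.frame (see
#'   \code{\link{readOrthologTable}}).
#' @param delThreshold minimum consecutive missing hits called Del.
#' @return data.frame of events: \code{code}, \code{first_row},
#'   \code{last_row}, \code{query_start}, \code{query_end},
#'   \code{genes}, \code{note}; zero rows for a colinear table.
#' @export
classifyEvents <- function(table, delThreshold = 2) {
  empty <- data.frame(code = character(0), first_row = integer(0),
                      last_row = integer(0), query_start = numeric(0),
                      query_end = numeric(0), genes = integer(0),
                      note = character(0))
  events <- empty
  addEvent <- function(code, rows, note = "") {
    events <<- rbind(events, data.frame(
      code = code, first_row = min(rows), last_row = max(rows),
      query_start = table$query_start[min(rows)],
      query_end = table$query_start[max(rows)],
      genes = length(rows), note = note))
  }

  ## deletions: consecutive hit-less query genes
  miss <- rle(!table$hit_present)
  at <- cumsum(c(1, miss$lengths))
  for (k in seq_along(miss$lengths))
    if (miss$values[k] && miss$lengths[k] >= delThreshold)
      addEvent("Del", seq(at[k], length.out = miss$lengths[k]))

  hitIdx <- which(table$hit_present)
  if (length(hitIdx) < 2) return(events)
  chrom <- table$subject_chrom[hitIdx]
  spos <- table$subject_start[hitIdx]

  ## duplications: >= 2-gene blocks whose (chrom, position) keys repeat
  key <- paste(chrom, spos)
  dupKey <- key %in% key[duplicated(key)]
  dupRows <- integer(0)
  if (any(dupKey)) {
    r <- rle(dupKey)
    ends <- cumsum(r$lengths)
    blocks <- list()
    for (k in seq_along(r$lengths))
      if (r$values[k] && r$lengths[k] >= 2)
        blocks[[length(blocks) + 1]] <-
          seq(ends[k] - r$lengths[k] + 1, ends[k])
    sig <- vapply(blocks, function(b)
      paste(sort(key[b]), collapse = ";"), character(1))
    for (s in unique(sig[duplicated(sig)])) {
      grp <- blocks[sig == s]
      inPlace <- vapply(grp, function(b) {
        lo <- min(spos[b]); hi <- max(spos[b])
        p <- if (min(b) > 1) spos[min(b) - 1] else NA
        q <- if (max(b) < length(hitIdx)) spos[max(b) + 1] else NA
        isTRUE(p < lo && hi < q) || isTRUE(p > hi && lo > q)
      }, logical(1))
      orig <- if (any(inPlace)) which(inPlace)[1] else 1L
      for (g in seq_along(grp))
        if (g != orig) {
          addEvent("Dup", hitIdx[grp[[g]]])
          dupRows <- c(dupRows, grp[[g]])
        }
    }
  }
  if (length(dupRows)) {
    keepPos <- setdiff(seq_along(hitIdx), dupRows)
    hitIdx <- hitIdx[keepPos]
    chrom <- chrom[keepPos]
    spos <- spos[keepPos]
  }

  ## strips over subject-order ranks per chromosome
  rnk <- integer(length(hitIdx))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    rnk[sel] <- rank(spos[sel], ties.method = "first")
  }
  strips <- .build_strips(seq_along(hitIdx), chrom, rnk)
  if (is.null(strips)) return(events)
  mainChrom <- names(sort(table(chrom), decreasing = TRUE))[1]
  frame <- .frame_chain(strips, mainChrom)
  leftover <- setdiff(seq_along(strips), frame)

  codeBySize <- function(base, n)
    c(base[1], base[2], base[3])[pmin(n - 1, 3)]
  for (si in leftover) {
    s <- strips[[si]]
    rows <- hitIdx[s$rows]
    if (s$chrom != mainChrom) {
      terminal <- si == 1L || si == length(strips)
      addEvent(if (terminal) "T" else "iT", rows)
    } else if (s$descending) {
      prevF <- frame[frame < si]
      nextF <- frame[frame > si]
      okLeft <- length(prevF) == 0 ||
        strips[[max(prevF)]]$hi == s$lo - 1
      okRight <- length(nextF) == 0 ||
        strips[[min(nextF)]]$lo == s$hi + 1
      if (okLeft && okRight)
        addEvent(codeBySize(c("A", "B", "C"), s$n), rows)
      else
        addEvent(codeBySize(c("D", "E", "F"), s$n), rows,
                 note = "inverted and displaced")
    } else {
      addEvent(codeBySize(c("D", "E", "F"), s$n), rows)
    }
  }
  events <- events[order(events$first_row), ]
  rownames(events) <- NULL
  events
}

#' Assign rearrangement events to phylogenetic branches by parsimony
#'
#' Each event is a binary character: the query's (derived) gene order is
#' either shared or not shared with each subject genome.  On the fixed
#' four-taxon topology (((query, Bd), Os), Sb) the minimal set of edges
#' explaining the pattern is found by exhaustive Fitch parsimony; a
#' unique minimal edge names the branch, ties give "unassigned",
#' patterns needing two changes are flagged "homoplasy", and events seen
#' against no subject are "none".
#'
#' @param presence data.frame or matrix of logicals, one row per event,
#'   columns named after \code{subjects}: TRUE when the event (the
#'   derived order) is observed in the comparison against that subject.
#' @param subjects subject genome names in tree order (sister, middle,
#'   outgroup).
#' @param query query genome name.
#' @return character vector of branch labels, one per event:
#'   the query name, a subject name, \code{"<query>+<sister>_ancestor"},
#'   \code{"unassigned"}, \code{"homoplasy"} or \code{"none"}.
#' @export
assignBranch <- function(presence, subjects = c("Bd", "Os", "Sb"),
                         query = "Aet") {
  presence <- as.data.frame(presence)
  if (!all(subjects %in% names(presence)))
    stop("'presence' must contain columns ", paste(subjects, collapse = ", "))
  edgeNames <- c(query, subjects[1],
                 paste0(query, "+", subjects[1], "_ancestor"),
                 subjects[2], subjects[3])
  vapply(seq_len(nrow(presence)), function(i) {
    seen <- as.logical(presence[i, subjects])
    if (!any(seen)) return("none")
    # leaf states: 1 = query's derived order
    leaf <- c(1L, ifelse(seen, 0L, 1L))   # query, sister, middle, outgroup
    best <- Inf
    changedSets <- list()
    for (a in 0:1) for (b in 0:1) {
      changed <- c(leaf[1] != a, leaf[2] != a, a != b,
                   leaf[3] != b, leaf[4] != b)
      cost <- sum(changed)
      if (cost < best) { best <- cost; changedSets <- list(changed) }
      else if (cost == best)
        changedSets[[length(changedSets) + 1]] <- changed
    }
    if (best >= 2) return("homoplasy")
    common <- Reduce(`&`, changedSets)
    if (sum(common) == 1) edgeNames[which(common)] else "unassigned"
  }, character(1))
}
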