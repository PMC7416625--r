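#' @importFrom Biostrings matchPattern reverseComplement DNAString
#'   readDNAStringSet writeXStringSet
#' @importFrom IRanges reduce findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

.as_char_seqs <- function(seqs) {
  if (is(seqs, "DNAStringSet")) {
    out <- as.character(seqs)
    if (is.null(names(out))) names(out) <- as.character(seq_along(out))
    return(out)
  }
  if (is.character(seqs)) {
    if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
    return(toupper(seqs))
  }
  stop("'seqs' must be a DNAStringSet or named character vector")
}

.scan_unit_arrays <- function(v, unit, minCopies, maxIntraGap) {
  lu <- nchar(unit)
  u <- strsplit(unit, "")[[1]]
  n <- length(v)
  s <- paste(v, collapse = "")
  m <- matchPattern(unit, DNAString(s))
  if (length(m) < minCopies) return(NULL)
  st <- start(m)
  en <- end(m)
  gap <- st[-1] - en[-length(en)] - 1
  grp <- cumsum(c(1, gap > maxIntraGap))
  out <- NULL
  for (g in unique(grp)) {
    sel <- which(grp == g)
    if (length(sel) < minCopies) next
    a <- st[sel[1]]; b <- en[sel[length(sel)]]
    # an array may end mid-unit: extend forwards while position b+1
    # continues the unit phase (b + 1 - a) mod lu
    while (b < n && v[b + 1] == u[(b + 1 - a) %% lu + 1]) b <- b + 1
    matched <- length(sel) * lu + (b - en[sel[length(sel)]])
    out <- rbind(out, data.frame(start = a, end = b,
                                 copies = length(sel),
                                 identity = matched / (b - a + 1)))
  }
  out
}

#' Scan for telomeric repeat arrays
#'
#' Finds tandem arrays of the plant telomeric unit TTTAGGG (and its
#' reverse complement, reported on the minus strand) by exact unit
#' matching: matches separated by at most \code{maxIntraGap} bases are
#' chained, chains of at least \code{minCopies} units are reported, and
#' an array may end mid-unit (trailing partial unit bases are included).
#' Ambiguous bases break chains.  Identity is matched bases over span.
#'
#' @param seqs a \code{DNAStringSet} or named character vector.
#' @param unit repeat unit (default TTTAGGG).
#' @param minCopies minimum full units per array.
#' @param maxIntraGap maximum unmatched bases between chained units.
#' @return a \code{GRanges} with columns \code{copies}, \code{identity};
#'   strand records the unit orientation.
#' @export
scanTelomereArrays <- function(seqs, unit = "TTTAGGG", minCopies = 5,
                               maxIntraGap = 7) {
  cs <- .as_char_seqs(seqs)
  res <- GRanges(copies = integer(0), identity = numeric(0))
  for (nm in names(cs)) {
    v <- strsplit(cs[[nm]], "")[[1]]
    for (strand_ in c("+", "-")) {
      un <- if (strand_ == "+") unit
      else as.character(reverseComplement(DNAString(unit)))
      hits <- .scan_unit_arrays(v, un, minCopies, maxIntraGap)
      if (!is.null(hits)) {
        gr <- GRanges(nm, IRanges(hits$start, hits$end), strand = strand_,
                      copies = hits$copies, identity = hits$identity)
        res <- c(res, gr)
      }
    }
  }
  sort(res, ignore.strand = TRUE)
}

.min_rotation <- function(motif) {
  u <- nchar(motif)
  rots <- vapply(seq_len(u), function(i)
    paste0(substr(motif, i, u), substr(motif, 1, i - 1)), character(1))
  min(rots)
}

.is_compound_unit <- function(motif) {
  u <- nchar(motif)
  for (p in seq_len(u - 1))
    if (u %% p == 0 && motif == strrep(substr(motif, 1, p), u / p))
      return(TRUE)
  FALSE
}

#' Scan for microsatellites (SSRs)
#'
#' Finds maximal perfect tandem tracts of unit size 1-6 bp with total
#' tract length of at least \code{minLen} bp; maximality is symmetric,
#' so a tract may begin or end mid-unit.
#' Tracts whose unit is itself a repetition of a smaller unit are
#' reported once, at the smallest unit; the motif is the
#' lexicographically minimal rotation.
#'
#' @param seqs a \code{DNAStringSet} or named character vector.
#' @param minLen minimum tract length in bp.
#' @param unitRange unit sizes scanned.
#' @return a \code{GRanges} with columns \code{motif}, \code{unit},
#'   \code{copies} (full unit copies).
#' @export
scanSsrs <- function(seqs, minLen = 15, unitRange = 1:6) {
  cs <- .as_char_seqs(seqs)
  recs <- list()
  for (nm in names(cs)) {
    v <- strsplit(cs[[nm]], "")[[1]]
    n <- length(v)
    for (u in unitRange) {
      if (n <= u) next
      eq <- v[(1 + u):n] == v[seq_len(n - u)] & v[(1 + u):n] %in%
        c("A", "C", "G", "T")
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      for (k in seq_along(r$lengths)) {
        if (!r$values[k]) next
        m <- r$lengths[k]
        a <- ends[k] - m + 1           # first position with v[a+u] == v[a]
        len <- m + u
        if (len < minLen || m < u) next
        motif <- paste(v[a:(a + u - 1)], collapse = "")
        if (.is_compound_unit(motif)) next
        recs[[length(recs) + 1]] <- data.frame(
          chrom = nm, start = a, end = a + len - 1,
          motif = .min_rotation(motif), unit = u,
          copies = len %/% u)
      }
    }
  }
  if (length(recs) == 0)
    return(GRanges(motif = character(0), unit = integer(0),
                   copies = integer(0)))
  d <- do.call(rbind, recs)
  sort(GRanges(d$chrom, IRanges(d$start, d$end), motif = d$motif,
               unit = d$unit, copies = d$copies), ignore.strand = TRUE)
}

#' k-mer uniqueness ratio
#'
#' The percentage of genome positions covered by at least one
#' forward-strand k-mer that occurs exactly once in the genome: a
#' repetitiveness measure that is non-decreasing in k (every unique
#' k-mer extends to a unique (k+1)-mer covering the same positions).
#' With \code{convention = "start"}, only k-mer start positions count
#' as covered.
#'
#' @param seqs a \code{DNAStringSet} or named character vector.
#' @param k k-mer length (>= 1, at most the longest sequence).
#' @param convention \code{"overlap"} (a position is covered by any
#'   overlapping unique k-mer) or \code{"start"}.
#' @return percentage in [0, 100].
#' @export
kmerUniquenessRatio <- function(seqs, k,
                                convention = c("overlap", "start")) {
  convention <- match.arg(convention)
  cs <- .as_char_seqs(seqs)
  lens <- nchar(cs)
  if (k < 1) stop("'k' must be >= 1")
  if (k > max(lens)) stop("'k' exceeds every sequence length")
  km <- list(); where <- list()
  for (i in seq_along(cs)) {
    n <- lens[i]
    if (n < k) next
    km[[i]] <- substring(cs[[i]], seq_len(n - k + 1), k:n)
    where[[i]] <- data.frame(seq = i, pos = seq_len(n - k + 1))
  }
  allk <- unlist(km)
  w <- do.call(rbind, where)
  dup <- duplicated(allk) | duplicated(allk, fromLast = TRUE)
  covered <- 0
  for (i in seq_along(cs)) {
    pos <- w$pos[w$seq == i & !dup]
    if (length(pos) == 0) next
    covered <- covered +
      if (convention == "start") length(pos)
      else sum(width(reduce(IRanges(pos, pos + k - 1))))
  }
  100 * covered / sum(lens)
}

#' Merge nearby alignment hit intervals
#'
#' Applies the post-alignment interval rules used for organellar
#' insertions: hits encompassed by other hits are removed, then hits
#' within \code{mergeDist} bases of one another (gap at most
#' \code{mergeDist}, or strictly below with \code{inclusive = FALSE})
#' are merged into single intervals.  The operation is idempotent.
#'
#' @param hits a \code{GRanges} of alignment hits on one chromosome and
#'   from one source.
#' @param mergeDist merge distance in bases.
#' @param inclusive merge at gap == mergeDist (default TRUE).
#' @return a sorted, non-overlapping \code{GRanges}.
#' @export
mergeOrganellarHits <- function(hits, mergeDist = 200, inclusive = TRUE) {
  stopifnot(is(hits, "GRanges"))
  if (length(hits) == 0) return(hits)
  ov <- findOverlaps(hits, hits, type = "within")
  qh <- queryHits(ov); sh <- subjectHits(ov)
  strictly <- qh != sh & width(hits)[qh] < width(hits)[sh]
  dupEqual <- qh != sh & width(hits)[qh] == width(hits)[sh] & qh > sh
  contained <- unique(qh[strictly | dupEqual])
  pruned <- if (length(contained)) hits[-contained] else hits
  maxGap <- if (inclusive) mergeDist else mergeDist - 1
  out <- reduce(sort(pruned), min.gapwidth = maxGap + 1)
  mcols(out) <- NULL
  out
}

#' Feature density profile in sliding windows
#'
#' The same bidirectional 10-Mb windowing used for genes (see
#' \code{\link{geneDensityProfile}}) applied to any feature set.
#'
#' @param features a \code{GRanges} or numeric start positions.
#' @param chromosomeLength chromosome length in bp.
#' @param window window size in bp.
#' @return data.frame with \code{midpoint}, \code{raw}, \code{smoothed}.
#' @export
featureDensityWindows <- function(features, chromosomeLength,
                                  window = 1e7) {
  geneDensityProfile(features, chromosomeLength, window = window)
}
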