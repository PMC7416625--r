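# Independent oracles used to check the scanners: deliberately written
# with regex / brute-force enumeration, sharing no code with the package
# implementations.

# brute-force k-mer uniqueness on a single string
kmer_oracle <- function(s, k, convention = "overlap") {
  n <- nchar(s)
  if (n < k) return(0)
  kms <- vapply(seq_len(n - k + 1), function(i) substr(s, i, i + k - 1),
                character(1))
  cnt <- table(kms)
  covered <- rep(FALSE, n)
  for (i in seq_along(kms)) {
    if (cnt[[kms[i]]] == 1L) {
      if (convention == "overlap") covered[i:(i + k - 1)] <- TRUE
      else covered[i] <- TRUE
    }
  }
  100 * sum(covered) / n
}

# regex-based SSR tract finder (perfect tandems, unit 1-6, partial tail
# included, smallest-unit rule, min length)
ssr_oracle <- function(s, minLen = 15, units = 1:6) {
  recs <- NULL
  n <- nchar(s)
  for (u in units) {
    m <- gregexpr(sprintf("([ACGT]{%d})\\1+", u), s, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (j in seq_along(m)) {
      a <- m[j]
      b <- a + attr(m, "match.length")[j] - 1
      while (b < n && substr(s, b + 1, b + 1) ==
               substr(s, b + 1 - u, b + 1 - u))
        b <- b + 1
      while (a > 1 && substr(s, a - 1, a - 1) ==
               substr(s, a - 1 + u, a - 1 + u))
        a <- a - 1
      motif <- substr(s, a, a + u - 1)
      compound <- FALSE
      for (p in seq_len(u - 1))
        if (u %% p == 0 && motif == strrep(substr(motif, 1, p), u / p))
          compound <- TRUE
      if (compound) next
      if (b - a + 1 >= minLen)
        recs <- rbind(recs, data.frame(start = a, end = b, unit = u))
    }
  }
  recs
}

# regex-based telomeric array finder (>= minCopies tandem units, partial
# trailing unit included), forward strand unit and its reverse complement
telomere_oracle <- function(s, unit = "TTTAGGG", minCopies = 5) {
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  n <- nchar(s)
  out <- NULL
  for (un in c(unit, rc(unit))) {
    m <- gregexpr(sprintf("(%s){%d,}", un, minCopies), s, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (j in seq_along(m)) {
      a <- m[j]
      b <- a + attr(m, "match.length")[j] - 1
      lu <- nchar(un)
      while (b < n && substr(s, b + 1, b + 1) ==
               substr(un, (b + 1 - a) %% lu + 1, (b + 1 - a) %% lu + 1))
        b <- b + 1
      out <- rbind(out, data.frame(start = a, end = b))
    }
  }
  out
}

# quick GRanges gene builder for gap tests (1-based inclusive)
makeGenes <- function(starts, ends, chrom = "1D", L = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                               strand = "+")
  gr$gene_id <- sprintf("G%03d", seq_along(starts))
  gr$confidence_class <- "HCC"
  if (!is.null(L))
    GenomeInfoDb::seqlengths(gr) <- stats::setNames(L, chrom)
  gr
}

# match classified events against planted truth: an event matches when
# the code is identical and the row spans overlap
matchEvents <- function(events, truth) {
  matched <- logical(NROW(events))
  hits <- 0L
  for (i in seq_len(NROW(truth))) {
    j <- which(!matched & events$code == truth$code[i] &
                 events$first_row <= truth$last_row[i] &
                 events$last_row >= truth$first_row[i])
    if (length(j)) {
      hits <- hits + 1L
      matched[j[1]] <- TRUE
    }
  }
  list(recall_hits = hits, false_pos = sum(!matched),
       n_truth = NROW(truth), n_events = NROW(events))
}
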