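test_that("telomeric arrays obey the copy cut-off and may end mid-unit", {
  set.seed(151)
  sim <- simulateSequence(
    8000, telomeres = data.frame(start = 2001, copies = 20,
                                 extraBases = 1), seed = 151)
  tel <- scanTelomereArrays(sim$seq)
  expect_equal(length(tel), 1L)
  expect_gte(width(tel), 141)   # 20 units + 1 partial base (by construction)
  hit <- GenomicRanges::findOverlaps(tel, sim$truth, type = "equal")
  # span matches the truth record unless background chance-extends it
  expect_equal(start(tel), 2001)
  expect_equal(tel$copies, 20L)

  # below the cut-off: nothing
  sim4 <- simulateSequence(3000, telomeres = data.frame(
    start = 1001, copies = 4, extraBases = 0), seed = 152)
  expect_length(scanTelomereArrays(sim4$seq), 0L)

  # reverse-complement arrays are found on the minus strand
  rcseq <- Biostrings::DNAStringSet(paste0(
    strrep("A", 200), strrep("CCCTAAA", 8), strrep("A", 200)))
  names(rcseq) <- "chr"
  telrc <- scanTelomereArrays(rcseq)
  expect_equal(length(telrc), 1L)
  expect_equal(as.character(strand(telrc)), "-")
  expect_equal(telrc$copies, 8L)
})

test_that("SSR scanning respects the 15-bp rule and the smallest-unit rule", {
  pad <- function(x, seed = 7) {
    set.seed(seed)     # non-repetitive flanks that cannot extend a tract
    left <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    right <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    s <- paste0(left, "CC", x, "CC", right)
    stats::setNames(s, "chr")
  }
  hit <- scanSsrs(pad(strrep("AG", 10)))
  expect_equal(length(hit), 1L)
  expect_equal(hit$motif, "AG")
  expect_equal(width(hit), 20)
  expect_equal(hit$copies, 10L)

  expect_length(scanSsrs(pad(strrep("AG", 7))), 0L)   # 14 bp < 15

  # (A)20: single record at unit 1, never at unit 2+
  arun <- scanSsrs(pad(strrep("A", 20)))
  expect_equal(length(arun), 1L)
  expect_equal(arun$unit, 1L)
  expect_equal(width(arun), 20)
})

test_that("SSR and telomere scanners agree with the regex oracles", {
  set.seed(161)
  agree <- 0L; total <- 0L
  for (i in 1:120) {
    sim <- simulateSequence(
      10000,
      telomeres = data.frame(start = 501, copies = 5 + i %% 6,
                             extraBases = i %% 7),
      ssrs = data.frame(start = c(3001, 6001),
                        motif = c(c("A", "AG", "AGC", "AGAT", "ACGTC",
                                    "AATGCC")[i %% 6 + 1], "TC"),
                        copies = c(20, 10)),
      seed = i)
    s <- as.character(sim$seq)[[1]]
    mine <- scanSsrs(sim$seq)
    orc <- ssr_oracle(s)
    key1 <- sort(paste(start(mine), end(mine)))
    key2 <- if (is.null(orc)) character(0)
    else sort(paste(orc$start, orc$end))
    total <- total + max(length(key1), length(key2))
    agree <- agree + length(intersect(key1, key2))
    tmine <- scanTelomereArrays(sim$seq)
    torc <- telomere_oracle(s)
    tk1 <- sort(paste(start(tmine), end(tmine)))
    tk2 <- if (is.null(torc)) character(0)
    else sort(paste(torc$start, torc$end))
    total <- total + max(length(tk1), length(tk2))
    agree <- agree + length(intersect(tk1, tk2))
  }
  expect_gte(agree / total, 0.99)
})

test_that("k-mer uniqueness matches brute force and is monotone in k", {
  # hand-checkable extremes
  expect_equal(kmerUniquenessRatio(c(x = "AAAAAAAA"), 4), 0)
  expect_equal(kmerUniquenessRatio(c(x = "ACGTACGTT"), 5), 100)
  expect_error(kmerUniquenessRatio(c(x = "ACGT"), 10), "exceeds")
  expect_error(kmerUniquenessRatio(c(x = "ACGT"), 0), ">= 1")

  set.seed(171)
  for (i in 1:40) {
    n <- sample(10:60, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                      prob = c(.4, .1, .1, .4)), collapse = "")
    k <- sample(1:8, 1)
    expect_equal(kmerUniquenessRatio(stats::setNames(s, "x"), k),
                 kmer_oracle(s, k), info = paste(s, k))
    expect_equal(
      kmerUniquenessRatio(stats::setNames(s, "x"), k, convention = "start"),
      kmer_oracle(s, k, convention = "start"))
  }
  set.seed(172)
  s <- paste(sample(c("A", "C"), 400, replace = TRUE), collapse = "")
  ks <- c(2, 4, 6, 8, 12, 16, 24)
  ratios <- vapply(ks, function(k)
    kmerUniquenessRatio(stats::setNames(s, "x"), k), numeric(1))
  expect_true(all(diff(ratios) >= 0))
})

test_that("organellar hit merging prunes containment and merges close hits", {
  h <- GRanges("c", IRanges(c(101, 551), c(400, 900)))
  m <- mergeOrganellarHits(h)                       # gap 150 <= 200
  expect_equal(length(m), 1L)
  expect_equal(start(m), 101)
  expect_equal(end(m), 900)

  h2 <- GRanges("c", IRanges(c(101, 200), c(400, 300)))
  m2 <- mergeOrganellarHits(h2)                     # inner removed
  expect_equal(length(m2), 1L)
  expect_equal(width(m2), 300)

  h3 <- GRanges("c", IRanges(c(101, 602), c(400, 900)))
  m3 <- mergeOrganellarHits(h3)                     # gap 201: kept apart
  expect_equal(length(m3), 2L)
  m3s <- mergeOrganellarHits(h3, inclusive = FALSE) # strict reading
  expect_equal(length(m3s), 2L)

  # idempotence
  set.seed(181)
  st <- sort(sample.int(1e5, 50))
  h4 <- GRanges("c", IRanges(st, st + sample.int(500, 50)))
  m4 <- mergeOrganellarHits(h4)
  expect_identical(GenomicRanges::granges(mergeOrganellarHits(m4)),
                   GenomicRanges::granges(m4))
})

test_that("feature density windows reuse the gene windowing contract", {
  set.seed(191)
  pos <- runif(2000, 1, 1e8)
  expect_equal(featureDensityWindows(pos, 1e8),
               geneDensityProfile(pos, 1e8))
})
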