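test_that("generators are deterministic given a seed", {
  a <- simulateTeCohort(500, seed = 3)
  b <- simulateTeCohort(500, seed = 3)
  expect_identical(a, b)
  m1 <- simulateGeneticMap(1e8, nMarkers = 50, seed = 4)$map
  m2 <- simulateGeneticMap(1e8, nMarkers = 50, seed = 4)$map
  expect_identical(m1, m2)
  s1 <- simulateSequence(5000, ssrs = data.frame(start = 100, motif = "AT",
                                                 copies = 10), seed = 5)
  s2 <- simulateSequence(5000, ssrs = data.frame(start = 100, motif = "AT",
                                                 copies = 10), seed = 5)
  expect_identical(as.character(s1$seq), as.character(s2$seq))
  o1 <- simulateOrthologOrders(100, randomRearrangementPlan(100, 2, seed = 6),
                               seed = 7)
  o2 <- simulateOrthologOrders(100, randomRearrangementPlan(100, 2, seed = 6),
                               seed = 7)
  expect_identical(o1, o2)
})

test_that("TE cohort mismatches follow the 2rlY Poisson mean", {
  # degenerate burst at 1 Myr, no deletion: every element retained and
  # E[N] = 2 * 1.3e-8 * 1000 * 1e6 = 26
  sim <- simulateTeCohort(4000, burstCenter = 1, burstSd = 0,
                          deletionRate = 0, seed = 11)
  expect_equal(nrow(sim$elements), 4000)
  expect_true(all(sim$truth$retained))
  se <- sqrt(26 / 4000)
  expect_lt(abs(mean(sim$elements$mismatches) - 26), 4 * se)
  expect_error(simulateTeCohort(0), "positive")
})

test_that("survival thinning retains exp(-delta t) of each age class", {
  sim <- simulateTeCohort(40000, ageDist = "uniform", maxAge = 3,
                          deletionRate = 1.5, seed = 12)
  ages <- sim$truth$ages_inserted
  kept <- sim$truth$retained
  for (bin in list(c(0, 0.5), c(0.5, 1), c(1, 1.5))) {
    sel <- ages >= bin[1] & ages < bin[2]
    p <- mean(kept[sel])
    expected <- mean(exp(-1.5 * ages[sel]))
    se <- sqrt(expected * (1 - expected) / sum(sel))
    expect_lt(abs(p - expected), 4 * se + 1e-9)
  }
})

test_that("gene position generator matches its gap distributions", {
  g <- simulateGenePositions(3e8, nullMode = TRUE, lambda = 1e-4, seed = 21)
  gaps <- start(g)[-1] - end(g)[-length(g)] - 1
  expect_lt(abs(mean(gaps) - 1e4) / 1e4, 0.05)

  g2 <- simulateGenePositions(6e8, distalShortening = 1, seed = 22)
  gaps2 <- start(g2)[-1] - end(g2)[-length(g2)] - 1
  mixMean <- 0.7 * 5000 + 0.3 * 1e5
  expect_lt(abs(mean(gaps2) - mixMean) / mixMean, 0.1)

  expect_warning(g0 <- simulateGenePositions(10, seed = 23), "too short")
  expect_length(g0, 0L)
})

test_that("genetic map generator is monotone, conserves cM and is U-shaped", {
  sim <- simulateGeneticMap(2e8, nMarkers = 100, totalCM = 150,
                            uExponent = 0, densityFloor = 0, seed = 31)
  # flat limit: cM exactly linear in bp
  expect_lt(max(abs(sim$map$cM - sim$map$bp / 2e8 * 150)), 1e-8)

  sim2 <- simulateGeneticMap(2e8, nMarkers = 100, totalCM = 150,
                             uExponent = 2, seed = 32)
  expect_true(!is.unsorted(sim2$map$cM))
  expect_equal(sim2$truth$cmFun(2e8), 150)
  r <- sim2$truth$rateFun
  expect_lt(r(1e8), r(1e6))
  expect_lt(r(1e8), r(1.99e8))
  expect_error(simulateGeneticMap(1e8, nMarkers = 1), "2 markers")
})

test_that("ortholog generator plants events exactly as coded", {
  id <- simulateOrthologOrders(50, NULL, seed = 41)
  expect_equal(nrow(id$truth), 0L)
  expect_true(all(diff(id$table$subject_start) > 0))

  plan <- data.frame(type = "inv", at = 10, size = 2, target = NA)
  sim <- simulateOrthologOrders(50, plan, seed = 42)
  base <- simulateOrthologOrders(50, NULL, seed = 42)$table
  expect_equal(sim$table$subject_start[10:11],
               rev(base$subject_start[10:11]))
  expect_equal(sim$table$subject_start[-(10:11)],
               base$subject_start[-(10:11)])
  expect_equal(sim$truth$code, "A")

  del <- simulateOrthologOrders(
    50, data.frame(type = "del", at = 20, size = 3, target = NA), seed = 43)
  expect_equal(sum(del$table$hit_present), 47L)
  expect_equal(del$truth$code, "Del")

  expect_error(simulateOrthologOrders(
    50, data.frame(type = c("inv", "inv"), at = c(10, 11), size = c(3, 3),
                   target = NA), seed = 44), "overlap")
})

test_that("sequence generator plants features with exact truth records", {
  sim <- simulateSequence(
    6000,
    telomeres = data.frame(start = 1001, copies = 20, extraBases = 1),
    ssrs = data.frame(start = 3001, motif = "AG", copies = 10),
    seed = 51)
  tr <- sim$truth
  expect_equal(length(tr), 2L)
  tel <- tr[tr$label == "telomere"]
  expect_equal(width(tel), 141)   # 20 units + 1 base
  ssr <- tr[tr$label == "ssr"]
  expect_equal(width(ssr), 20)
  # truth intervals never overlap
  expect_equal(length(IRanges::reduce(GenomicRanges::ranges(tr))),
               length(tr))

  none <- simulateSequence(2000, seed = 52)
  expect_length(none$truth, 0L)
  expect_equal(nchar(as.character(none$seq)[[1]]), 2000)

  expect_error(simulateSequence(
    1000, ssrs = data.frame(start = c(10, 15), motif = "AG",
                            copies = c(10, 10)), seed = 53), "overlap")
})
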