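identityTable <- function(n, seed = 1) {
  simulateOrthologOrders(n, NULL, seed = seed)$table
}

test_that("run detection finds maximal monotone runs and breaks at thresholds", {
  tab <- identityTable(100)
  runs <- detectRuns(tab)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$genes, 100L)
  expect_equal(runs$direction, "ascending")

  # swap two subject positions: runs break, the 2-gene descending
  # stretch is not a run at minGenes = 3
  tab2 <- tab
  tab2$subject_start[10:11] <- rev(tab2$subject_start[10:11])
  runs2 <- detectRuns(tab2, minGenes = 3)
  expect_gt(nrow(runs2), 1L)
  expect_false(any(runs2$direction == "descending"))
  expect_true(all(runs2$genes >= 3))

  # a subject gap at the threshold splits a run
  tab3 <- identityTable(50)
  tab3$subject_start[26:50] <- tab3$subject_start[26:50] + 6e5
  runs3 <- detectRuns(tab3, maxGapBp = 5e5)
  expect_equal(nrow(runs3), 2L)
  expect_equal(detectRuns(data.frame(
    query_gene_id = character(0), query_chrom = character(0),
    query_start = numeric(0), subject_gene_id = character(0),
    subject_chrom = character(0), subject_start = numeric(0),
    hit_present = logical(0))) |> nrow(), 0L)
})

test_that("colinearity percentage is 100 on identity, low on shuffles, direction-blind", {
  tab <- identityTable(200)
  runs <- detectRuns(tab)
  cp <- colinearityPercent(tab, runs)
  expect_equal(cp$overall, 100)
  expect_true(all(cp$profile$percent == 100))

  set.seed(101)
  shuf <- identityTable(1000, seed = 2)
  shuf$subject_start <- sample(shuf$subject_start)
  cps <- colinearityPercent(shuf, detectRuns(shuf))
  expect_lt(cps$overall, 5)

  # one big inverted block still counts: descending runs are runs
  inv <- tab
  inv$subject_start[50:150] <- rev(inv$subject_start[50:150])
  cpi <- colinearityPercent(inv, detectRuns(inv))
  expect_gt(cpi$overall, 95)

  # invariance under global query-order reversal
  revTab <- tab[rev(seq_len(nrow(tab))), ]
  revTab$query_start <- max(tab$query_start) + 1 - rev(tab$query_start)
  revTab <- revTab[order(revTab$query_start), ]
  rownames(revTab) <- NULL
  cpr <- colinearityPercent(revTab, detectRuns(revTab))
  expect_equal(cpr$overall, cp$overall)
})

test_that("tandem duplicate hits collapse onto the colinear copy", {
  tab <- identityTable(20)
  extra <- tab[10, ]
  extra$subject_start <- tab$subject_start[10] + 1000   # tandem copy
  extra$subject_gene_id <- "S_dup"
  tab2 <- rbind(tab[1:10, ], extra, tab[11:20, ])
  out <- tandemCollapse(tab2)
  expect_equal(nrow(out), 20L)
  expect_equal(out$subject_start[10], tab$subject_start[10])
  expect_length(attr(out, "tandem_flagged"), 0L)

  # unchanged when no duplicates
  out2 <- tandemCollapse(tab)
  expect_equal(nrow(out2), nrow(tab))

  # no bracketing context: first copy kept and flagged
  lone <- tab2[9:11, ]
  out3 <- tandemCollapse(lone)
  expect_equal(nrow(out3), 2L)
  expect_equal(attr(out3, "tandem_flagged"), tab$query_gene_id[10])
})

test_that("each planted event type is classified with its exact code", {
  cases <- list(
    list(type = "inv", size = 2, code = "A"),
    list(type = "inv", size = 3, code = "B"),
    list(type = "inv", size = 6, code = "C"),
    list(type = "trans", size = 2, code = "D"),
    list(type = "trans", size = 3, code = "E"),
    list(type = "trans", size = 5, code = "F"),
    list(type = "iT", size = 4, code = "iT"),
    list(type = "del", size = 3, code = "Del"),
    list(type = "dup", size = 3, code = "Dup"))
  for (cs in cases) {
    plan <- data.frame(type = cs$type, at = 40, size = cs$size,
                       target = if (cs$type %in% c("trans", "dup")) 70
                       else NA)
    sim <- simulateOrthologOrders(100, plan, seed = 7)
    ev <- classifyEvents(sim$table)
    expect_equal(nrow(ev), 1L, info = cs$code)
    expect_equal(ev$code, cs$code, info = cs$code)
    expect_equal(ev$first_row, sim$truth$first_row, info = cs$code)
    expect_equal(ev$last_row, sim$truth$last_row, info = cs$code)
  }
  # terminal translocation at the chromosome end
  planT <- data.frame(type = "T", at = 96, size = 5, target = NA)
  simT <- simulateOrthologOrders(100, planT, seed = 8)
  evT <- classifyEvents(simT$table)
  expect_equal(evT$code, "T")

  expect_equal(nrow(classifyEvents(identityTable(100))), 0L)
})

test_that("event classification is independent of row storage order", {
  plan <- randomRearrangementPlan(300, 4, seed = 17)
  sim <- simulateOrthologOrders(300, plan, seed = 18)
  ev1 <- classifyEvents(sim$table)
  perm <- sim$table[sample(nrow(sim$table)), ]
  perm <- perm[order(perm$query_chrom, perm$query_start), ]
  rownames(perm) <- NULL
  ev2 <- classifyEvents(perm)
  expect_equal(ev1, ev2)
})

test_that("parsimony assigns events to the expected branches", {
  pres <- data.frame(Bd = c(FALSE, TRUE, FALSE, TRUE, TRUE),
                     Os = c(TRUE, TRUE, FALSE, FALSE, TRUE),
                     Sb = c(TRUE, TRUE, FALSE, TRUE, FALSE))
  br <- assignBranch(pres)
  # seen vs Os+Sb only: change on the branch joining query and sister
  expect_equal(br[1], "Aet+Bd_ancestor")
  # seen vs all three: the query terminal branch
  expect_equal(br[2], "Aet")
  # seen vs none: no event
  expect_equal(br[3], "none")
  # seen vs Bd and Sb but not Os: two changes needed
  expect_equal(br[4], "homoplasy")
  # seen vs Bd and Os but not Sb: also homoplasy on this topology
  expect_equal(br[5], "homoplasy")
  # seen only vs one subject: that subject's terminal branch
  expect_equal(assignBranch(data.frame(Bd = TRUE, Os = FALSE, Sb = FALSE)),
               "Bd")
  expect_equal(assignBranch(data.frame(Bd = FALSE, Os = FALSE, Sb = TRUE)),
               "Sb")
})
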