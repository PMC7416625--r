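test_that("point ages invert the Poisson mismatch mean", {
  expect_equal(pointAge(0, 1000), 0)
  expect_equal(pointAge(26, 1000, 1.3e-8), 1)     # 26 / (2 * 1.3e-8 * 1e3) yr
  expect_equal(pointAge(13, 2000, 1.3e-8), pointAge(26, 2000, 1.3e-8) / 2)
  expect_equal(pointAge(10, 2000), pointAge(10, 1000) / 2)
  expect_error(pointAge(5, 0), "positive")
  expect_error(pointAge(-1, 100), "non-negative")
})

test_that("the negative-binomial marginal is a proper pmf", {
  # the exposure parametrization must keep the marginal normalized
  for (par in list(c(2, 2, 26), c(0.5, 1, 10), c(5, 3, 60))) {
    p <- par[2] / (par[2] + par[3])
    expect_lt(abs(sum(dnbinom(0:5000, size = par[1], prob = p)) - 1), 1e-8)
  }
})

test_that("gamma age fitting recovers parameters and improves with n", {
  errAt <- function(n, seed) {
    sim <- simulateTeCohort(n, ageDist = "gamma", gammaShape = 2,
                            gammaRate = 2, deletionRate = 0, seed = seed)
    m <- fitAgeDistribution(sim$elements)
    c(abs(ageShape(m) - 2) / 2, abs(ageRate(m) - 2) / 2,
      logLik(m) - genomescapes:::.nb_loglik(
        log(c(2, 2)), sim$elements$mismatches,
        2 * 1.3e-8 * sim$elements$ltr_length * 1e6))
  }
  e5000 <- sapply(1:5, function(s) errAt(5000, s))
  expect_true(all(e5000[1:2, ] < 0.10))
  # MLE property: fitted loglik >= loglik at the truth
  expect_true(all(e5000[3, ] >= -1e-6))
  e500 <- sapply(1:5, function(s) errAt(500, s + 100))
  expect_lt(mean(e5000[1:2, ]), mean(e500[1:2, ]))
})

test_that("degenerate inputs to the age fit are handled", {
  expect_error(fitAgeDistribution(data.frame()), "no elements")
  few <- data.frame(mismatches = rep(5, 10), ltr_length = 1000)
  expect_error(fitAgeDistribution(few), "at least")
  zero <- data.frame(mismatches = rep(0, 100), ltr_length = 1000)
  m0 <- fitAgeDistribution(zero)
  expect_true(m0@boundary)
  expect_lt(meanAge(m0), 1e-3)
  # identical counts: gamma degenerates, implied dispersion ~ Poisson
  same <- data.frame(mismatches = rep(26, 200), ltr_length = 1000)
  m1 <- fitAgeDistribution(same)
  mu <- 26 * ageShape(m1) / ageRate(m1) / 26   # mean mismatches / exposure
  vmr <- 1 + 26 / ageShape(m1)                 # NB variance-to-mean
  expect_lt(vmr, 1.2)
})

test_that("exponential survival fitting recovers the deletion rate", {
  sim <- simulateTeCohort(30000, ageDist = "uniform", maxAge = 3,
                          deletionRate = 1.5, seed = 61)
  sv <- fitSurvival(sim$elements)
  expect_lt(abs(deletionRate(sv) - 1.5) / 1.5, 0.15)

  # no thinning: near-zero estimate on an interior window (point-age
  # smear at the uniform support edge would otherwise mimic decline)
  sim0 <- simulateTeCohort(20000, ageDist = "uniform", maxAge = 3,
                           deletionRate = 0, seed = 62)
  sv0 <- fitSurvival(sim0$elements, fitWindow = c(0, 2.5))
  expect_lt(deletionRate(sv0), 0.1)

  one <- data.frame(mismatches = rep(26, 50), ltr_length = 1000)
  expect_error(fitSurvival(one), "non-empty bins|declining")
  expect_error(fitSurvival(sim$elements, fitWindow = c(2, 1)), "increasing")
})

test_that("insertion intensity is g/S, normalized, and exceeds g when delta > 0", {
  m <- new("TeAgeModel", shape = 2, rate = 2, mutationRate = 1.3e-8,
           logLik = 0, nElements = 100L, boundary = FALSE)
  s0 <- new("TeSurvivalModel", deletionRate = 0, fitWindow = c(0, 3),
            nBinsUsed = 10L)
  s1 <- new("TeSurvivalModel", deletionRate = 1, fitWindow = c(0, 3),
            nBinsUsed = 10L)
  grid <- seq(0, 3, by = 0.05)
  p0 <- insertionRateProfile(m, s0, grid, normalize = FALSE)
  expect_equal(p0$intensity, dgamma(grid, 2, 2))   # S == 1
  p1 <- insertionRateProfile(m, s1, grid, normalize = FALSE)
  expect_true(all(p1$intensity >= p0$intensity))
  expect_true(all(p1$intensity[-1] > p0$intensity[-1]))
  pn <- insertionRateProfile(m, s1, grid, normalize = TRUE)
  expect_equal(max(pn$intensity), 1)
})

test_that("proximal-distal age contrast behaves as a two-sample t-test", {
  eq <- data.frame(family = letters[1:6], mean_age = 1,
                   median_dist = 1:6)
  r <- proximalDistalAgeTest(eq)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)

  # planted contrast: distal 0.8 vs proximal 1.4 Myr, sd 0.2, 11 + 11
  set.seed(71)
  hits <- replicate(40, {
    fs <- data.frame(
      family = sprintf("f%02d", 1:22),
      mean_age = c(rnorm(11, 1.4, 0.2), rnorm(11, 0.8, 0.2)),
      median_dist = c(runif(11, 0, 5e7), runif(11, 2e8, 3e8)))
    proximalDistalAgeTest(fs)$p.value < 0.01
  })
  expect_gte(mean(hits), 0.95)

  expect_error(proximalDistalAgeTest(eq[1:3, ]), "4 families|odd")
  expect_error(proximalDistalAgeTest(eq[1:5, ]), "odd")
})

test_that("family position ANOVA is calibrated and flags shifted families", {
  set.seed(81)
  rej <- replicate(100, {
    el <- data.frame(family = rep(letters[1:5], each = 30),
                     dist_to_centromere = runif(150, 0, 3e8))
    familyPositionAnova(el)$p.value < 0.05
  })
  expect_gte(mean(rej), 0.005)
  expect_lte(mean(rej), 0.12)

  set.seed(82)
  el <- data.frame(family = rep(c("a", "b", "c"), each = 40),
                   dist_to_centromere = c(runif(80, 0, 1e8),
                                          runif(40, 0, 1e8) + 5e7))
  r <- familyPositionAnova(el)
  expect_lt(r$p.value, 0.01)
  cshift <- grepl("c", rownames(r$tukey))
  expect_true(all(r$tukey[cshift, "p adj"] < 0.05))

  expect_error(familyPositionAnova(
    data.frame(family = "a", dist_to_centromere = 1:5)), "2 families")
  expect_warning(familyPositionAnova(
    data.frame(family = c(rep("a", 5), rep("b", 5), "c"),
               dist_to_centromere = runif(11))), "single element")
})
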