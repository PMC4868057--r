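test_that("intercept tuning hits the target prevalence exactly", {
  # no effects: closed form logit(prevalence)
  hap <- data.frame(L1 = c("L1*01:01", "L1*02:01"), freq = c(0.1, 0.9))
  spec <- simulationSpec("L1", hap, prevalence = 0.01, nCases = 10,
                         nControls = 10)
  expect_equal(tuneIntercept(spec), stats::qlogis(0.01), tolerance = 1e-9)

  # one allele, freq 0.1, OR 2: check against direct enumeration over the
  # three genotype classes
  spec <- simulationSpec("L1", hap,
                         data.frame(locus = "L1", allele = "L1*01:01",
                                    log_or = log(2)),
                         prevalence = 0.01, nCases = 10, nControls = 10)
  b0 <- tuneIntercept(spec)
  geno_p <- c(0.9^2, 2 * 0.1 * 0.9, 0.1^2)
  prev <- sum(geno_p * stats::plogis(b0 + 0:2 * log(2)))
  expect_equal(prev, 0.01, tolerance = 1e-6)

  expect_error(simulationSpec("L1", hap, prevalence = 0.5, nCases = 1,
                              nControls = 1))
})

test_that("the same seed reproduces a cohort byte-identically", {
  spec <- demoSimulationSpec(nCases = 50, nControls = 80, prevalence = 0.01,
                             seed = 123)
  a <- simulateCohort(spec)
  b <- simulateCohort(spec)
  expect_identical(subjects(a), subjects(b))
  c <- simulateCohort(spec, seed = 124)
  expect_false(identical(subjects(a), subjects(c)))
  # the private stream leaves the global RNG state alone
  set.seed(555); before <- .Random.seed
  simulateCohort(spec)
  expect_identical(before, .Random.seed)
})

test_that("null effects give matched case and control frequencies", {
  # aggregate over seeds: every common allele within 3 SE
  accA <- 0; n <- 0
  for (i in 1:30) {
    spec <- twoLocusSpec(pA = 0.2, nCases = 250, nControls = 250,
                         prevalence = 0.05, seed = 800 + i)
    coh <- simulateCohort(spec)
    ca <- countsFromCohort(coh, "AL", "MPA", "allele")
    accA <- accA + alleleCounts(ca)[["AL*01:01"]]
    n <- n + countTotal(ca)
  }
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(accA / n - 0.2), 3 * se)
})

test_that("control frequencies converge to the spec margins at large n", {
  spec <- demoSimulationSpec(nCases = 5, nControls = 100000,
                             prevalence = 0.01, seed = 99)
  spec@alleleLogOR$log_or <- 0
  coh <- simulateCohort(spec)
  tab <- countsFromCohort(coh, "DRB1", "control", "allele")
  f <- alleleCounts(tab) / countTotal(tab)
  marg <- tapply(spec@hapFreqs$freq, spec@hapFreqs$DRB1, sum)
  for (al in names(f))
    expect_lt(abs(f[[al]] - marg[[al]]), 0.005)
})

test_that("case enrichment always follows the sign of the log OR", {
  spec <- drb1OnlySpec(logOR = c("DRB1*09:01" = log(1.57),
                                 "DRB1*13:02" = log(0.42)),
                       nCases = 2000, nControls = 2000, prevalence = 0.05,
                       seed = 17)
  coh <- simulateCohort(spec)
  case <- countsFromCohort(coh, "DRB1", "MPO-AAV", "allele")
  ctrl <- countsFromCohort(coh, "DRB1", "control", "allele")
  fr <- function(t, al) alleleCounts(t)[[al]] / countTotal(t)
  expect_gt(fr(case, "DRB1*09:01"), fr(ctrl, "DRB1*09:01"))
  expect_lt(fr(case, "DRB1*13:02"), fr(ctrl, "DRB1*13:02"))
})

test_that("an unattainable case target errors out", {
  hap <- data.frame(L1 = c("L1*01:01", "L1*02:01"), freq = c(0.1, 0.9))
  spec <- simulationSpec("L1", hap, prevalence = 1e-4, nCases = 5000,
                         nControls = 10, seed = 1)
  expect_error(simulateCohort(spec, maxAttempts = 0.001), "unattainable")
})

test_that("pair-LD haplotype construction honours margins and target r2", {
  fA <- c(a1 = 0.09, a2 = 0.51, a3 = 0.4)
  fB <- c(b1 = 0.06, b2 = 0.94)
  hap <- pairLDHaplotypeFreqs(fA, fB, c("X", "Y"), "a1", "b1", r2 = 0.44)
  expect_equal(sum(hap$freq), 1, tolerance = 1e-12)
  expect_equal(as.numeric(tapply(hap$freq, hap$X, sum)[names(fA)]),
               unname(fA), tolerance = 1e-12)
  expect_equal(as.numeric(tapply(hap$freq, hap$Y, sum)[names(fB)]),
               unname(fB), tolerance = 1e-12)
  expect_equal(analyticR2(hap, c("X", "Y"), "a1", "b1"), 0.44,
               tolerance = 1e-12)
  expect_error(pairLDHaplotypeFreqs(fA, fB, c("X", "Y"), "a1", "b1",
                                    r2 = 0.99), "too large")
})

test_that("normal-approximation power behaves like the exact test", {
  alpha <- bonferroniAlpha(30, 5)
  expect_equal(powerTwoProportions(0.15, 1, 754, 1192, alpha), alpha,
               tolerance = alpha)
  # monotone in n and effect size
  p1 <- powerTwoProportions(0.15, 1.6, 400, 600, alpha)
  p2 <- powerTwoProportions(0.15, 1.6, 754, 1192, alpha)
  p3 <- powerTwoProportions(0.15, 2.2, 754, 1192, alpha)
  expect_true(p1 < p2 && p2 < p3)
  p4 <- powerTwoProportions(0.15, 0.45, 754, 1192, alpha)
  expect_gt(p4, p2)  # |ln 0.45| > |ln 1.6|

  # empirical check by Fisher-test simulation at the study's MPO-AAV size
  set.seed(424242)
  odds <- 1.6 * 0.15 / 0.85
  p1sim <- odds / (1 + odds)
  hits <- 0
  for (i in 1:2000) {
    a <- stats::rbinom(1, 754, p1sim)
    c <- stats::rbinom(1, 1192, 0.15)
    hits <- hits + (fisherTwoSided(a, 754 - a, c, 1192 - c) < alpha)
  }
  expect_lt(abs(powerTwoProportions(0.15, 1.6, 754, 1192, alpha) -
                  hits / 2000), 0.03)
})
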