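test_that("allele dosage counts copies and respects missingness", {
  coh <- tinyCohort()
  d <- alleleDosage(coh, "DRB1", "DRB1*09:01")
  expect_equal(unname(d), c(2, 1, 0))
  expect_length(alleleDosage(coh, "DPB1", "DPB1*04:01"), 2)  # one untyped
})

test_that("dosage sums equal allele-kind counts for every allele and group", {
  spec <- twoLocusSpec(pA = 0.25, r2 = 0.2, nCases = 300, nControls = 300,
                       seed = 5)
  coh <- simulateCohort(spec)
  for (grp in c("MPA", "control")) {
    tab <- countsFromCohort(coh, "AL", grp, "allele")
    pred <- subsetPredicate(grp)
    sel <- pred(subjects(coh))
    for (al in names(alleleCounts(tab))) {
      d <- alleleDosage(coh, "AL", al)
      ids <- subjects(coh)$subject_id[sel]
      expect_equal(sum(d[names(d) %in% ids]), alleleCounts(tab)[[al]])
    }
  }
})

test_that("additive fit recovers a known effect with honest CIs", {
  covered <- 0
  for (i in 1:100) {
    spec <- twoLocusSpec(pA = 0.3, logORA = log(2), nCases = 2000,
                         nControls = 2000, prevalence = 0.05, seed = 400 + i)
    coh <- simulateCohort(spec)
    fit <- fitAdditive(caseIndicator(coh), alleleDosage(coh, "AL", "AL*01:01"))
    t <- fitTerms(fit)
    covered <- covered + (t$ci_low <= 2 && 2 <= t$ci_high)
  }
  expect_gte(covered, 93)
})

test_that("degenerate predictors and one-class outcomes are rejected", {
  y <- rep(c(0, 1), 50)
  expect_error(fitAdditive(y, rep(1, 100)), "degenerate")
  expect_error(fitAdditive(rep(1, 100), rbinom(100, 2, 0.3)), "both cases")
})

test_that("complete separation is flagged, not silently reported", {
  y <- rep(c(0, 1), each = 50)
  d <- c(rep(0, 50), rep(2, 50))
  fit <- fitAdditive(y, d)
  expect_false(isConverged(fit))
})

test_that("conditioning on an independent predictor leaves a null term null", {
  set.seed(77)
  drifts <- replicate(20, {
    spec <- twoLocusSpec(pA = 0.3, pB = 0.2, r2 = 0, logORA = log(1.8),
                         logORB = 0, nCases = 1000, nControls = 1000,
                         prevalence = 0.05, seed = sample.int(1e6, 1))
    coh <- simulateCohort(spec)
    y <- caseIndicator(coh)
    dA <- alleleDosage(coh, "AL", "AL*01:01")
    dB <- alleleDosage(coh, "BL", "BL*01:01")
    alone <- fitTerms(fitAdditive(y, dB, "B"))
    joint <- fitTerms(fitAdditive(y, list(dA, dB), c("A", "B")))
    abs(joint$beta[2] - alone$beta[1]) / alone$se[1]
  })
  expect_true(all(drifts < 3))
})

test_that("conditional pair on an LD-free cohort leaves estimates unchanged", {
  spec <- twoLocusSpec(pA = 0.3, pB = 0.2, r2 = 0, logORA = log(0.5),
                       logORB = log(1.5), nCases = 1500, nControls = 1500,
                       prevalence = 0.05, seed = 909)
  coh <- simulateCohort(spec)
  cp <- conditionalPair(coh, "MPA", "AL*01:01", "BL*01:01")
  for (al in c("AL*01:01", "BL*01:01")) {
    un <- cp[cp$allele == al & cp$conditioned_on == "none", ]
    cd <- cp[cp$allele == al & cp$conditioned_on != "none", ]
    se <- (log(un$ci_high) - log(un$or)) / stats::qnorm(0.975)
    expect_lt(abs(log(cd$or) - log(un$or)), se)
  }
})

test_that("mutually masking LD-linked effects both sharpen under conditioning", {
  # opposite-direction causal alleles in LD: conditioning unmasks both
  hits <- 0
  for (i in 1:20) {
    spec <- twoLocusSpec(pA = 0.15, pB = 0.15, r2 = 0.4, logORA = log(0.45),
                         logORB = log(2.2), nCases = 1000, nControls = 1000,
                         prevalence = 0.05, seed = 5500 + i)
    coh <- simulateCohort(spec)
    cp <- conditionalPair(coh, "MPA", "AL*01:01", "BL*01:01")
    ok <- TRUE
    for (al in c("AL*01:01", "BL*01:01")) {
      un <- cp[cp$allele == al & cp$conditioned_on == "none", ]
      cd <- cp[cp$allele == al & cp$conditioned_on != "none", ]
      ok <- ok && abs(log(cd$or)) > abs(log(un$or))
    }
    hits <- hits + ok
  }
  expect_gte(hits, 18)
})

test_that("genotype categories are assigned and measured correctly", {
  coh <- tinyCohort()
  g <- genotypeCategoryAssoc(coh, "MPO-AAV", "DRB1*09:01", "DRB1*13:02")
  expect_setequal(
    g$genotype, c("N/N", "risk/N", "risk/risk", "risk/protective",
                  "protective/N", "protective/protective"))
  # s1 is 09:01/09:01 (risk/risk), s2 is 09:01/13:02 (risk/protective)
  expect_equal(g$n_case[g$genotype == "risk/risk"], 1)
  expect_equal(g$n_ctrl[g$genotype == "risk/protective"], 1)
  expect_equal(g$or[g$genotype == "N/N"], 1)
})

test_that("genotype-category ORs recover multiplicative allele effects", {
  spec <- drb1OnlySpec(logOR = c("DRB1*09:01" = log(1.6),
                                 "DRB1*13:02" = log(0.45)),
                       nCases = 2000, nControls = 2000, prevalence = 0.05,
                       seed = 31)
  coh <- simulateCohort(spec)
  g <- genotypeCategoryAssoc(coh, "MPO-AAV", "DRB1*09:01", "DRB1*13:02")
  rN <- g[g$genotype == "risk/N", ]
  pN <- g[g$genotype == "protective/N", ]
  # true category OR vs N/N equals the per-allele OR under the logistic model
  expect_true(rN$ci_low < 1.6 && 1.6 < rN$ci_high)
  expect_true(pN$ci_low < 0.45 && 0.45 < pN$ci_high)
  expect_gt(rN$or, 1); expect_lt(pN$or, 1)
})

test_that("null genotype-category scans keep their CIs around 1", {
  hit <- 0; tot <- 0
  for (i in 1:25) {
    spec <- drb1OnlySpec(logOR = c("DRB1*09:01" = 0), nCases = 400,
                         nControls = 400, prevalence = 0.05, seed = 600 + i)
    coh <- simulateCohort(spec)
    g <- genotypeCategoryAssoc(coh, "MPO-AAV", "DRB1*09:01", "DRB1*13:02")
    g <- g[g$genotype != "N/N" & g$n_case + g$n_ctrl > 0 & !g$haldane, ]
    tot <- tot + nrow(g)
    hit <- hit + sum(g$ci_low <= 1 & 1 <= g$ci_high)
  }
  expect_gte(hit / tot, 0.9)
})
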