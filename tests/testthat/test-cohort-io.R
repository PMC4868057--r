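test_that("cohort TSV parsing preserves missingness and rejects malformed rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCohort(tinyCohort(), path)
  coh <- readCohort(path)
  expect_s4_class(coh, "HLACohort")
  expect_equal(nrow(subjects(coh)), 3)
  expect_equal(sum(!is.na(subjects(coh)$DPB1_1)), 2)

  # allele token without a colon
  bad <- subjects(tinyCohort())
  bad$DRB1_1[2] <- "DRB1*0901"
  utils::write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  expect_error(readCohort(path), "row\\(s\\) 2")

  # half-typed locus
  bad <- subjects(tinyCohort())
  bad$DPB1_2[1] <- NA
  utils::write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  expect_error(readCohort(path), "half-typed.*row\\(s\\) 1")

  # duplicated ids
  bad <- subjects(tinyCohort())
  bad$subject_id <- c("s1", "s1", "s3")
  utils::write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  expect_error(readCohort(path), "duplicate subject_id")
})

test_that("write -> read round-trips a simulated cohort exactly", {
  spec <- twoLocusSpec(nCases = 50, nControls = 50, seed = 11)
  spec@missingRate <- c(AL = 0, BL = 0.1)
  coh <- simulateCohort(spec)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCohort(coh, path)
  back <- readCohort(path)
  expect_identical(subjects(back), subjects(coh))
  expect_identical(cohortLoci(back), cohortLoci(coh))
})

test_that("allele and carrier counting follow the chromosome and carrier rules", {
  coh <- makeCohort(data.frame(
    subject_id = c("a", "b"), emea_class = "MPA", mpo_anca = "positive",
    pr3_anca = "negative",
    DRB1_1 = c("DRB1*01:01", "DRB1*01:01"),
    DRB1_2 = c("DRB1*01:01", "DRB1*04:05")))
  al <- countsFromCohort(coh, "DRB1", "MPA", "allele")
  expect_equal(alleleCounts(al), c("DRB1*01:01" = 3, "DRB1*04:05" = 1))
  expect_equal(countTotal(al), 4)
  ca <- countsFromCohort(coh, "DRB1", "MPA", "carrier")
  expect_equal(alleleCounts(ca), c("DRB1*01:01" = 2, "DRB1*04:05" = 1))
  expect_equal(countTotal(ca), 2)

  # missing locus excluded from numerator and denominator
  al <- countsFromCohort(tinyCohort(), "DPB1", "control", "allele")
  expect_equal(countTotal(al), 2)
  expect_equal(sum(alleleCounts(al)), 2)
  expect_error(countsFromCohort(tinyCohort(), "DRB1", "GPA"), "empty group")
})

test_that("counting invariants hold on simulated cohorts", {
  spec <- twoLocusSpec(pA = 0.3, nCases = 200, nControls = 200, seed = 3)
  spec@missingRate <- c(AL = 0.05, BL = 0)
  coh <- simulateCohort(spec)
  for (grp in c("MPA", "control")) {
    al <- countsFromCohort(coh, "AL", grp, "allele")
    ca <- countsFromCohort(coh, "AL", grp, "carrier")
    expect_equal(countTotal(al), 2 * countTotal(ca))
    shared <- names(alleleCounts(ca))
    expect_true(all(alleleCounts(ca)[shared] <= alleleCounts(al)[shared]))
    expect_true(all(alleleCounts(al)[shared] <= 2 * alleleCounts(ca)[shared]))
  }
  # disjoint-group additivity
  all_ <- countsFromCohort(coh, "AL", function(s) rep(TRUE, nrow(s)), "allele")
  mpa <- countsFromCohort(coh, "AL", "MPA", "allele")
  ctl <- countsFromCohort(coh, "AL", "control", "allele")
  expect_equal(countTotal(all_), countTotal(mpa) + countTotal(ctl))
  for (al in names(alleleCounts(all_)))
    expect_equal(alleleCounts(all_)[[al]],
                 sum(alleleCounts(mpa)[al], alleleCounts(ctl)[al], na.rm = TRUE))
})

test_that("observed allele frequencies track generating frequencies (3 SE)", {
  spec <- twoLocusSpec(pA = 0.2, nCases = 10, nControls = 5000,
                       prevalence = 0.05, seed = 21)
  coh <- simulateCohort(spec)
  tab <- countsFromCohort(coh, "AL", "control", "allele")
  phat <- alleleCounts(tab)[["AL*01:01"]] / countTotal(tab)
  se <- sqrt(0.2 * 0.8 / countTotal(tab))
  expect_lt(abs(phat - 0.2), 3 * se)
})

test_that("control-frequency filter reproduces the study's common-allele sets", {
  expect_length(filterCommonAlleles(aavAlleleCounts("DRB1", "HC")), 21)
  expect_length(filterCommonAlleles(aavAlleleCounts("DPB1", "HC")), 9)
  expect_length(filterCommonAlleles(aavAlleleCounts("DRB1", "HC"), 1.0), 0)
  expect_error(
    filterCommonAlleles(countTable("X", "g", c("X*01:01" = 5), 10, "carrier")),
    "allele-kind")
})

test_that("count tables read back from TSV equal the originals", {
  tabs <- aavAlleleCounts()
  expect_length(tabs, 12)
  mpo <- aavAlleleCounts("DRB1", "MPO-AAV")
  expect_equal(countTotal(mpo), 754)
  expect_equal(alleleCounts(mpo)[["DRB1*09:01"]], 166)
  expect_equal(countKind(mpo), "allele")
})
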