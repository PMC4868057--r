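# Shared fixtures, built in code.

# tiny hand-checkable cohort: 3 subjects, one missing DPB1
tinyCohort <- function() {
  makeCohort(data.frame(
    subject_id = c("s1", "s2", "s3"),
    emea_class = c("MPA", "control", "control"),
    mpo_anca = c("positive", "negative", "unknown"),
    pr3_anca = c("negative", "negative", "unknown"),
    DRB1_1 = c("DRB1*09:01", "DRB1*09:01", "DRB1*13:02"),
    DRB1_2 = c("DRB1*09:01", "DRB1*13:02", "DRB1*15:01"),
    DPB1_1 = c("DPB1*05:01", NA, "DPB1*04:01"),
    DPB1_2 = c("DPB1*02:01", NA, "DPB1*04:01")))
}

# single-locus simulation spec over the packaged control DRB1 frequencies
# (renormalised to the 21 listed alleles so every allele is covered by the
# packaged protein table)
drb1OnlySpec <- function(logOR = c("DRB1*13:02" = log(0.42)),
                         nCases = 377, nControls = 596,
                         prevalence = 0.01, seed = 1L) {
  hc <- aavAlleleCounts("DRB1", "HC")
  f <- alleleCounts(hc) / countTotal(hc)
  f <- f / sum(f)
  eff <- data.frame(locus = "DRB1", allele = names(logOR),
                    log_or = unname(logOR))
  simulationSpec("DRB1", data.frame(DRB1 = names(f), freq = as.numeric(f)),
                 eff, prevalence = prevalence, nCases = nCases,
                 nControls = nControls, seed = seed)
}

# two biallelic-style loci with tunable LD between A1 and B1
twoLocusSpec <- function(pA = 0.2, pB = 0.15, r2 = 0, logORA = 0, logORB = 0,
                         nCases = 500, nControls = 500, prevalence = 0.05,
                         seed = 1L) {
  fA <- c("AL*01:01" = pA, "AL*02:01" = 1 - pA)
  fB <- c("BL*01:01" = pB, "BL*02:01" = 1 - pB)
  hap <- pairLDHaplotypeFreqs(fA, fB, c("AL", "BL"), "AL*01:01", "BL*01:01",
                              r2 = r2)
  eff <- data.frame(locus = c("AL", "BL"),
                    allele = c("AL*01:01", "BL*01:01"),
                    log_or = c(logORA, logORB))
  simulationSpec(c("AL", "BL"), hap, eff, prevalence = prevalence,
                 nCases = nCases, nControls = nControls, seed = seed)
}

countTable <- function(locus, group, counts, total, kind = "allele") {
  new("AlleleCountTable", locus = locus, group = group, counts = counts,
      total = total, kind = kind)
}

caseIndicator <- function(cohort) subjects(cohort)$emea_class != "control"

# independent brute-force two-sided Fisher: enumerate all tables with the
# observed margins via choose(), point-probability rule
bruteFisher <- function(a, b, c, d) {
  k <- a + b; m <- a + c; n <- b + d
  lo <- max(0, k - n); hi <- min(k, m)
  pr <- vapply(lo:hi, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), numeric(1))
  pobs <- pr[a - lo + 1]
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# profile-likelihood oracle for two-locus r2: fix the observed allele
# frequencies, optimise the multinomial genotype likelihood over the one
# free haplotype frequency (an algorithm independent of EM)
gridR2 <- function(gA, gB) {
  n <- length(gA)
  pA <- sum(gA) / (2 * n); pB <- sum(gB) / (2 * n)
  tab <- table(factor(gA, 0:2), factor(gB, 0:2))
  ll <- function(hAB) {
    h <- c(AB = hAB, Ab = pA - hAB, aB = pB - hAB, ab = 1 - pA - pB + hAB)
    if (any(h < 0)) return(-Inf)
    probs <- matrix(c(h["ab"]^2, 2 * h["ab"] * h["aB"], h["aB"]^2,
                      2 * h["ab"] * h["Ab"],
                      2 * (h["AB"] * h["ab"] + h["Ab"] * h["aB"]),
                      2 * h["AB"] * h["aB"], h["Ab"]^2, 2 * h["AB"] * h["Ab"],
                      h["AB"]^2), 3, 3, byrow = TRUE)
    sum(tab[tab > 0] * log(probs[tab > 0]))
  }
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-12)
  D <- opt$maximum - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# qualitative conditional-dissection pattern of a causal protective allele
# (A) and an LD-linked null allele (B): B's evidence weakens or vanishes
# under conditioning while A's protective association persists
conditionalPatternHolds <- function(cp, alleleA, alleleB) {
  a_cd <- cp[cp$allele == alleleA & cp$conditioned_on != "none", ]
  b_un <- cp[cp$allele == alleleB & cp$conditioned_on == "none", ]
  b_cd <- cp[cp$allele == alleleB & cp$conditioned_on != "none", ]
  (b_cd$p > 0.05 || b_cd$p > b_un$p) && a_cd$p < 0.05 && a_cd$or < 1
}
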