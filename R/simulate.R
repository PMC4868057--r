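#' Construct a simulation specification
#'
#' @param loci locus names.
#' @param hapFreqs data.frame with one allele column per locus plus
#'   \code{freq} (summing to 1). Cross-locus LD is encoded here; haplotypes
#'   are drawn independently per individual (HWE).
#' @param alleleLogOR data.frame(locus, allele, log_or); alleles not listed
#'   have no effect.
#' @param prevalence baseline population prevalence (default 1e-4; the
#'   disease modelled is rare).
#' @param nCases,nControls target sample sizes.
#' @param missingRate named per-locus missingness probabilities.
#' @param seed RNG seed.
#' @return a \linkS4class{SimulationSpec}.
#' @export
simulationSpec <- function(loci, hapFreqs, alleleLogOR = NULL,
                           prevalence = 1e-4, nCases, nControls,
                           missingRate = NULL, seed = 1L) {
  if (is.null(alleleLogOR))
    alleleLogOR <- data.frame(locus = character(), allele = character(),
                              log_or = numeric())
  if (is.null(missingRate)) missingRate <- setNames(rep(0, length(loci)), loci)
  new("SimulationSpec", loci = loci, hapFreqs = hapFreqs,
      alleleLogOR = alleleLogOR, prevalence = prevalence,
      nCases = as.integer(nCases), nControls = as.integer(nControls),
      missingRate = missingRate, seed = as.integer(seed))
}

# log-odds contribution of one haplotype
.hapScores <- function(spec) {
  h <- spec@hapFreqs
  sc <- numeric(nrow(h))
  eff <- spec@alleleLogOR
  for (i in seq_len(nrow(eff)))
    sc <- sc + eff$log_or[i] * (h[[eff$locus[i]]] == eff$allele[i])
  sc
}

#' Intercept matching a target population prevalence
#'
#' Solves for the logistic intercept beta0 such that the population
#' prevalence — the exact sum of \code{plogis(beta0 + s_i + s_j)} over all
#' ordered haplotype pairs weighted by their frequencies — equals the spec's
#' baseline prevalence, by monotone root finding. Accurate to 1e-6 of
#' prevalence.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @return intercept beta0 (log odds).
#' @export
tuneIntercept <- function(spec) {
  f <- spec@hapFreqs$freq
  sc <- .hapScores(spec)
  # collapse to the distribution of diplotype scores
  ss <- outer(sc, sc, "+")
  pp <- outer(f, f)
  agg <- tapply(as.vector(pp), round(as.vector(ss), 12), sum)
  svals <- as.numeric(names(agg)); pvals <- as.numeric(agg)
  prev <- function(b0) sum(pvals * stats::plogis(b0 + svals)) - spec@prevalence
  stats::uniroot(prev, c(-60, 60), tol = 1e-12)$root
}

# run expr with a private RNG stream; global .Random.seed untouched
.withSeed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env)) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = env)
    else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  expr
}

#' Simulate a case-control cohort
#'
#' Draws two cross-locus haplotypes per individual from the spec's haplotype
#' frequencies, assigns disease by the logistic liability
#' \code{logit P = beta0 + sum(dosage x log OR)} with beta0 tuned to the
#' baseline prevalence, and retains individuals by rejection until the
#' target numbers of cases and controls are reached (retrospective
#' sampling from one generative population model, under which odds ratios
#' are sampling-design invariant). Per-locus missingness is applied last.
#' The same seed yields a byte-identical cohort.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @param seed optional override of the spec's seed.
#' @param caseClass EMEA class label given to simulated cases.
#' @param caseANCA \code{"MPO"} or \code{"PR3"}: which ANCA is positive in
#'   cases.
#' @param maxAttempts cap on population draws, as a multiple of the draws
#'   expected to be needed; exceeding it is an error.
#' @return an \linkS4class{HLACohort}.
#' @export
simulateCohort <- function(spec, seed = spec@seed, caseClass = "MPA",
                           caseANCA = c("MPO", "PR3"), maxAttempts = 20) {
  caseANCA <- match.arg(caseANCA)
  b0 <- tuneIntercept(spec)
  h <- spec@hapFreqs
  sc <- .hapScores(spec)
  nH <- nrow(h)
  .withSeed(seed, {
    caseIdx <- NULL; ctrlIdx <- NULL   # rows = haplotype index pairs
    needCase <- spec@nCases; needCtrl <- spec@nControls
    expDraws <- needCase / spec@prevalence + needCtrl / (1 - spec@prevalence)
    drawn <- 0
    chunk <- max(1000, min(2e6, ceiling(expDraws / 4)))
    while (needCase > 0 || needCtrl > 0) {
      if (drawn > maxAttempts * expDraws)
        stop("case count unattainable under this spec (prevalence too low ",
             "for the requested sample); giving up after ", drawn, " draws")
      h1 <- sample.int(nH, chunk, replace = TRUE, prob = h$freq)
      h2 <- sample.int(nH, chunk, replace = TRUE, prob = h$freq)
      drawn <- drawn + chunk
      pr <- stats::plogis(b0 + sc[h1] + sc[h2])
      isCase <- stats::rbinom(chunk, 1, pr) == 1
      if (needCase > 0 && any(isCase)) {
        take <- which(isCase)[seq_len(min(needCase, sum(isCase)))]
        caseIdx <- rbind(caseIdx, cbind(h1[take], h2[take]))
        needCase <- spec@nCases - NROW(caseIdx)
      }
      if (needCtrl > 0 && any(!isCase)) {
        take <- which(!isCase)[seq_len(min(needCtrl, sum(!isCase)))]
        ctrlIdx <- rbind(ctrlIdx, cbind(h1[take], h2[take]))
        needCtrl <- spec@nControls - NROW(ctrlIdx)
      }
    }
    ids <- c(sprintf("case%05d", seq_len(spec@nCases)),
             sprintf("ctrl%05d", seq_len(spec@nControls)))
    s <- data.frame(
      subject_id = ids,
      emea_class = c(rep(caseClass, spec@nCases), rep("control", spec@nControls)),
      mpo_anca = c(rep(if (caseANCA == "MPO") "positive" else "negative",
                       spec@nCases), rep("negative", spec@nControls)),
      pr3_anca = c(rep(if (caseANCA == "PR3") "positive" else "negative",
                       spec@nCases), rep("negative", spec@nControls)))
    idx <- rbind(caseIdx, ctrlIdx)
    for (loc in spec@loci) {
      a1 <- h[[loc]][idx[, 1]]; a2 <- h[[loc]][idx[, 2]]
      mr <- if (loc %in% names(spec@missingRate)) spec@missingRate[[loc]] else 0
      if (mr > 0) {
        miss <- stats::runif(nrow(s)) < mr
        a1[miss] <- NA; a2[miss] <- NA
      }
      s[[paste0(loc, "_1")]] <- a1; s[[paste0(loc, "_2")]] <- a2
    }
    makeCohort(s, spec@loci)
  })
}

#' Two-locus haplotype frequencies with LD between one allele pair
#'
#' Builds a cross-locus haplotype frequency table whose single-locus margins
#' equal the supplied allele frequency vectors and whose only LD is a
#' coupling D between one target allele pair (all other combinations stay
#' proportional). Used to encode, e.g., the moderate LD between a DRB1 and
#' a DPB1 allele while leaving the rest of both loci in equilibrium.
#'
#' @param freqsA,freqsB named allele frequency vectors for the two loci
#'   (each summing to 1).
#' @param lociNames names of the two loci.
#' @param alleleA,alleleB the coupled allele pair (names in the vectors).
#' @param d coupling coefficient D (must keep all frequencies non-negative).
#' @param r2 alternatively, the target r-squared (sign of D positive);
#'   ignored when \code{d} is given.
#' @return data.frame with the two locus columns and \code{freq}.
#' @export
pairLDHaplotypeFreqs <- function(freqsA, freqsB, lociNames, alleleA, alleleB,
                                 d = NULL, r2 = NULL) {
  stopifnot(abs(sum(freqsA) - 1) < 1e-9, abs(sum(freqsB) - 1) < 1e-9,
            alleleA %in% names(freqsA), alleleB %in% names(freqsB))
  fA <- freqsA[[alleleA]]; fB <- freqsB[[alleleB]]
  if (is.null(d)) {
    stopifnot(!is.null(r2))
    d <- sqrt(r2 * fA * (1 - fA) * fB * (1 - fB))
  }
  grid <- expand.grid(a = names(freqsA), b = names(freqsB),
                      stringsAsFactors = FALSE)
  f <- freqsA[grid$a] * freqsB[grid$b]
  inA <- grid$a == alleleA; inB <- grid$b == alleleB
  f[inA & inB] <- f[inA & inB] + d
  f[inA & !inB] <- f[inA & !inB] * (1 - d / (fA * (1 - fB)))
  f[!inA & inB] <- f[!inA & inB] * (1 - d / ((1 - fA) * fB))
  f[!inA & !inB] <- f[!inA & !inB] * (1 + d / ((1 - fA) * (1 - fB)))
  if (any(f < -1e-12)) stop("d too large for these margins")
  out <- data.frame(grid$a, grid$b, freq = pmax(0, unname(f)))
  names(out)[1:2] <- lociNames
  out
}

#' Analytic r-squared implied by a haplotype frequency table
#'
#' @param hapFreqs data.frame as in \linkS4class{SimulationSpec}.
#' @param lociNames the two locus columns.
#' @param alleleA,alleleB the allele pair.
#' @return r-squared of the collapsed 2x2 haplotype distribution.
#' @export
analyticR2 <- function(hapFreqs, lociNames, alleleA, alleleB) {
  fAB <- sum(hapFreqs$freq[hapFreqs[[lociNames[1]]] == alleleA &
                             hapFreqs[[lociNames[2]]] == alleleB])
  fA <- sum(hapFreqs$freq[hapFreqs[[lociNames[1]]] == alleleA])
  fB <- sum(hapFreqs$freq[hapFreqs[[lociNames[2]]] == alleleB])
  D <- fAB - fA * fB
  D^2 / (fA * (1 - fA) * fB * (1 - fB))
}

#' Demonstration spec mirroring the packaged study's design
#'
#' DRB1/DPB1 marginal control frequencies are taken from the packaged
#' healthy-control count tables (rare unlisted chromosomes pooled into a
#' catch-all allele per locus), with moderate LD (r2 = 0.44) between
#' DRB1*13:02 and DPB1*04:01, effect sizes at the study's headline odds
#' ratios (DRB1*09:01 OR 1.57, DRB1*13:02 OR 0.42, DPB1*04:01 null — its
#' marginal association arises through LD), baseline prevalence 1e-4 and
#' the study's sample sizes (377 cases, 596 controls).
#'
#' @param nCases,nControls sample sizes.
#' @param prevalence baseline prevalence.
#' @param seed RNG seed.
#' @return a \linkS4class{SimulationSpec}.
#' @export
demoSimulationSpec <- function(nCases = 377, nControls = 596,
                               prevalence = 1e-4, seed = 1L) {
  drb1 <- aavAlleleCounts("DRB1", "HC"); dpb1 <- aavAlleleCounts("DPB1", "HC")
  fA <- alleleCounts(drb1) / countTotal(drb1)
  fA <- c(fA, setNames(1 - sum(fA), "DRB1*99:99"))
  fB <- alleleCounts(dpb1) / countTotal(dpb1)
  fB <- c(fB, setNames(1 - sum(fB), "DPB1*99:99"))
  hap <- pairLDHaplotypeFreqs(fA, fB, c("DRB1", "DPB1"),
                              "DRB1*13:02", "DPB1*04:01", r2 = 0.44)
  eff <- data.frame(locus = c("DRB1", "DRB1"),
                    allele = c("DRB1*09:01", "DRB1*13:02"),
                    log_or = log(c(1.57, 0.42)))
  simulationSpec(c("DRB1", "DPB1"), hap, eff, prevalence = prevalence,
                 nCases = nCases, nControls = nControls,
                 missingRate = c(DRB1 = 0, DPB1 = 0.005), seed = seed)
}

#' Approximate power for a two-proportion allele-frequency comparison
#'
#' Normal-approximation power for detecting an allele-frequency difference
#' between case and control chromosome pools at unequal sizes: the case
#' frequency is the control frequency moved by the odds ratio, and the test
#' statistic uses the pooled null standard error with a continuity
#' correction (Fleiss), approximating exact-test power calculators.
#'
#' @param pCtrl control allele frequency.
#' @param or effect odds ratio.
#' @param nCase2n,nCtrl2n chromosome counts (2n) in cases and controls.
#' @param alpha two-sided significance level.
#' @param continuity apply the continuity correction (default TRUE).
#' @return power in [0, 1].
#' @export
powerTwoProportions <- function(pCtrl, or, nCase2n, nCtrl2n,
                                alpha = bonferroniAlpha(30, 5),
                                continuity = TRUE) {
  stopifnot(pCtrl > 0, pCtrl < 1, or > 0)
  odds <- or * pCtrl / (1 - pCtrl)
  pCase <- odds / (1 + odds)
  diff <- abs(pCase - pCtrl)
  if (continuity) diff <- max(0, diff - (1 / nCase2n + 1 / nCtrl2n) / 2)
  pbar <- (pCase * nCase2n + pCtrl * nCtrl2n) / (nCase2n + nCtrl2n)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / nCase2n + 1 / nCtrl2n))
  se1 <- sqrt(pCase * (1 - pCase) / nCase2n + pCtrl * (1 - pCtrl) / nCtrl2n)
  za <- stats::qnorm(1 - alpha / 2)
  stats::pnorm((diff - za * se0) / se1) +
    stats::pnorm((-diff - za * se0) / se1)
}
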