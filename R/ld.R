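#' Two-locus r-squared by EM haplotype-frequency estimation
#'
#' Collapses each locus to presence/absence of the target allele per
#' chromosome and estimates the four pseudo-biallelic haplotype frequencies
#' from unphased genotypes by EM over the double-heterozygote phase
#' ambiguity, initialised at linkage equilibrium, until the log-likelihood
#' improves by less than \code{tol}. D is the coupling coefficient and
#' r2 = D^2 / (pA (1-pA) pB (1-pB)).
#'
#' @param cohort an \linkS4class{HLACohort}.
#' @param group subset name (default \code{"control"}, matching estimation
#'   in healthy controls) or predicate; use \code{"all"} for every subject.
#' @param alleleA,alleleB full allele names at two different loci.
#' @param tol log-likelihood convergence tolerance (default 1e-10).
#' @param maxIter iteration cap (default 1000).
#' @return an \linkS4class{LDResult}.
#' @export
emR2 <- function(cohort, group = "control", alleleA, alleleB,
                 tol = 1e-10, maxIter = 1000) {
  pa <- .parseAllele(alleleA); pb <- .parseAllele(alleleB)
  stopifnot(pa$locus != pb$locus)
  s <- subjects(cohort)
  if (identical(group, "all")) {
    keep <- rep(TRUE, nrow(s))
  } else {
    pred <- if (is.function(group)) group else subsetPredicate(group)
    keep <- pred(s)
  }
  keep <- keep & !is.na(s[[paste0(pa$locus, "_1")]]) &
    !is.na(s[[paste0(pb$locus, "_1")]])
  if (sum(keep) < 2) stop("fewer than two subjects typed at both loci")
  sub <- makeCohort(s[keep, , drop = FALSE], cohortLoci(cohort))
  gA <- alleleDosage(sub, pa$locus, pa$allele)
  gB <- alleleDosage(sub, pb$locus, pb$allele)
  n <- length(gA)
  pA <- sum(gA) / (2 * n); pB <- sum(gB) / (2 * n)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("monomorphic allele in group; r2 undefined")
  # genotype table n[gA, gB], gA/gB in 0:2
  tab <- table(factor(gA, 0:2), factor(gB, 0:2))
  em <- .emHaplo2(tab, pA, pB, tol, maxIter)
  D <- em$h["AB"] - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  new("LDResult", alleleA = pa$allele, alleleB = pb$allele,
      hapFreqs = em$h[c("ab", "aB", "Ab", "AB")], d = unname(D),
      r2 = unname(min(1, max(0, r2))), nSubjects = as.integer(n),
      iterations = em$iter)
}

# EM on a 3x3 dosage table for two pseudo-biallelic loci. Haplotypes:
# AB (both target alleles), Ab, aB, ab. Only the (1,1) double-heterozygote
# cell has ambiguous phase: AB/ab vs Ab/aB.
.emHaplo2 <- function(tab, pA, pB, tol, maxIter) {
  n <- sum(tab)
  h <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  loglik <- function(h) {
    probs <- matrix(0, 3, 3)
    probs[1, 1] <- h["ab"]^2;        probs[1, 2] <- 2 * h["ab"] * h["aB"]
    probs[1, 3] <- h["aB"]^2;        probs[2, 1] <- 2 * h["ab"] * h["Ab"]
    probs[2, 2] <- 2 * (h["AB"] * h["ab"] + h["Ab"] * h["aB"])
    probs[2, 3] <- 2 * h["AB"] * h["aB"]; probs[3, 1] <- h["Ab"]^2
    probs[3, 2] <- 2 * h["AB"] * h["Ab"]; probs[3, 3] <- h["AB"]^2
    sum(tab[tab > 0] * log(probs[tab > 0]))
  }
  ll <- loglik(h)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step: split the double heterozygotes by phase posterior
    num <- h["AB"] * h["ab"]
    den <- num + h["Ab"] * h["aB"]
    w <- if (den > 0) num / den else 0.5
    nAB <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3] + w * tab[2, 2]
    nAb <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1] + (1 - w) * tab[2, 2]
    naB <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3] + (1 - w) * tab[2, 2]
    nab <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1] + w * tab[2, 2]
    h <- c(AB = nAB, Ab = nAb, aB = naB, ab = nab) / (2 * n)
    names(h) <- c("AB", "Ab", "aB", "ab")
    llNew <- loglik(h)
    if (abs(llNew - ll) < tol || iter >= maxIter) break
    ll <- llNew
  }
  list(h = h, iter = iter)
}
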