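#' Per-subject dosage of an allele
#'
#' Number of copies (0, 1 or 2) of \code{allele} carried by each subject
#' typed at \code{locus}; untyped subjects are dropped.
#'
#' @param cohort an \linkS4class{HLACohort}.
#' @param locus locus name.
#' @param allele full allele name, e.g. \code{"DRB1*13:02"}.
#' @return named numeric vector (names = subject ids) with values in 0:2.
#' @export
alleleDosage <- function(cohort, locus, allele) {
  stopifnot(locus %in% cohortLoci(cohort))
  s <- subjects(cohort)
  a1 <- s[[paste0(locus, "_1")]]; a2 <- s[[paste0(locus, "_2")]]
  typed <- !is.na(a1)
  d <- (a1[typed] == allele) + (a2[typed] == allele)
  names(d) <- s$subject_id[typed]
  d
}

#' Additive-dosage logistic regression
#'
#' Maximum-likelihood logistic fit of a case indicator on one or more dosage
#' vectors (with intercept); Wald tests and Woolf-style CIs per term. A fit
#' that does not converge or shows the signature of complete separation
#' (unbounded coefficients / exploding standard errors) is returned with
#' \code{converged = FALSE} rather than silently reported.
#'
#' @param y 0/1 case indicator (or logical), one element per subject.
#' @param dosages a single dosage vector, a list of them, or a matrix with
#'   one column per predictor.
#' @param labels term labels; defaults to list/column names.
#' @param conf confidence level for the ORs.
#' @return a \linkS4class{LogisticFit}.
#' @export
fitAdditive <- function(y, dosages, labels = NULL, conf = 0.95) {
  if (is.list(dosages)) dosages <- do.call(cbind, dosages)
  dosages <- as.matrix(dosages)
  if (is.null(labels)) labels <- colnames(dosages)
  if (is.null(labels)) labels <- paste0("term", seq_len(ncol(dosages)))
  colnames(dosages) <- labels
  y <- as.integer(y)
  stopifnot(length(y) == nrow(dosages))
  if (length(unique(y)) < 2) stop("outcome must contain both cases and controls")
  degen <- apply(dosages, 2, function(x) length(unique(x)) < 2)
  if (any(degen))
    stop("degenerate (constant) dosage predictor: ",
         paste(labels[degen], collapse = ", "))
  dat <- data.frame(y = y, dosages, check.names = FALSE)
  fml <- stats::as.formula(paste("y ~", paste(sprintf("`%s`", labels), collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(), data = dat))
  cf <- summary(fit)$coefficients
  idx <- match(sprintf("`%s`", labels), rownames(cf))
  idx[is.na(idx)] <- match(labels, rownames(cf))[is.na(idx)]
  beta <- cf[idx, 1]; se <- cf[idx, 2]; p <- cf[idx, 4]
  z <- stats::qnorm(1 - (1 - conf) / 2)
  separated <- !fit$converged || any(abs(cf[, 1]) > 15) || any(cf[, 2] > 100)
  new("LogisticFit",
      terms = data.frame(term = labels, beta = unname(beta), se = unname(se),
                         p = unname(p), or = exp(unname(beta)),
                         ci_low = exp(unname(beta) - z * unname(se)),
                         ci_high = exp(unname(beta) + z * unname(se))),
      nUsed = nrow(dat), converged = !separated)
}

.parseAllele <- function(x) {
  if (length(x) == 2) return(list(locus = x[1], allele = paste(x, collapse = "*")))
  locus <- sub("\\*.*", "", x)
  list(locus = locus, allele = x)
}

#' Conditional logistic dissection of two LD-linked alleles
#'
#' For a disease subset versus controls, fits each allele's dosage alone and
#' then both together ("conditioning" = cross-locus dosage adjustment in the
#' same fit, not matched-set conditional likelihood). The four fits mirror
#' the layout of a published conditional analysis: unconditioned P/OR per
#' allele and P/OR adjusted for the other allele.
#'
#' @param cohort an \linkS4class{HLACohort}.
#' @param subset subset name or predicate (cases); controls are the
#'   \code{emea_class == "control"} records.
#' @param alleleA,alleleB full allele names (\code{"DRB1*13:02"}) or
#'   \code{c(locus, allele)} pairs.
#' @return data.frame with one row per allele x conditioning combination:
#'   allele, conditioned_on, p, or, ci_low, ci_high, converged, n.
#' @export
conditionalPair <- function(cohort, subset, alleleA, alleleB) {
  pa <- .parseAllele(alleleA); pb <- .parseAllele(alleleB)
  s <- subjects(cohort)
  pred <- if (is.function(subset)) subset else subsetPredicate(subset)
  isCase <- pred(s); isCtrl <- s$emea_class == "control"
  if (!any(isCase)) stop("empty disease subset")
  keep <- (isCase | isCtrl) &
    !is.na(s[[paste0(pa$locus, "_1")]]) & !is.na(s[[paste0(pb$locus, "_1")]])
  sub <- makeCohort(s[keep, , drop = FALSE], cohortLoci(cohort))
  y <- pred(subjects(sub))
  dA <- alleleDosage(sub, pa$locus, pa$allele)
  dB <- alleleDosage(sub, pb$locus, pb$allele)
  one <- function(fit, allele, conditioning) {
    t <- fitTerms(fit); r <- t[t$term == allele, ]
    data.frame(allele = allele, conditioned_on = conditioning, p = r$p,
               or = r$or, ci_low = r$ci_low, ci_high = r$ci_high,
               converged = isConverged(fit), n = fit@nUsed)
  }
  fitA <- fitAdditive(y, dA, pa$allele)
  fitB <- fitAdditive(y, dB, pb$allele)
  fitAB <- fitAdditive(y, list(dA, dB), c(pa$allele, pb$allele))
  rbind(one(fitA, pa$allele, "none"),
        one(fitAB, pa$allele, pb$allele),
        one(fitB, pb$allele, "none"),
        one(fitAB, pb$allele, pa$allele))
}

#' Genotype-category association at one locus
#'
#' Classifies every subject's genotype at the locus of the two named alleles
#' into risk/risk, risk/protective, risk/N, protective/protective,
#' protective/N and N/N ("N" = any other, neutral allele), then reports each
#' category's OR (Haldane's modification on zero cells), 95\% CI and
#' two-sided Fisher P against the N/N referent.
#'
#' @param cohort an \linkS4class{HLACohort}.
#' @param subset disease subset name or predicate.
#' @param riskAllele,protectiveAllele two distinct alleles at one locus.
#' @return data.frame: genotype, n_case, n_ctrl, or, ci_low, ci_high, p,
#'   haldane (the N/N referent row carries OR 1 and P NA).
#' @export
genotypeCategoryAssoc <- function(cohort, subset, riskAllele, protectiveAllele) {
  pr <- .parseAllele(riskAllele); pp <- .parseAllele(protectiveAllele)
  stopifnot(pr$locus == pp$locus, pr$allele != pp$allele)
  locus <- pr$locus
  s <- subjects(cohort)
  pred <- if (is.function(subset)) subset else subsetPredicate(subset)
  isCase <- pred(s); isCtrl <- s$emea_class == "control"
  keep <- (isCase | isCtrl) & !is.na(s[[paste0(locus, "_1")]])
  s <- s[keep, , drop = FALSE]; isCase <- isCase[keep]
  r <- (s[[paste0(locus, "_1")]] == pr$allele) + (s[[paste0(locus, "_2")]] == pr$allele)
  p <- (s[[paste0(locus, "_1")]] == pp$allele) + (s[[paste0(locus, "_2")]] == pp$allele)
  cat_of <- function(r, p)
    if (r == 2) "risk/risk" else if (r == 1 && p == 1) "risk/protective" else
    if (r == 1) "risk/N" else if (p == 2) "protective/protective" else
    if (p == 1) "protective/N" else "N/N"
  g <- mapply(cat_of, r, p)
  lev <- c("N/N", "risk/N", "risk/risk", "risk/protective", "protective/N",
           "protective/protective")
  refCase <- sum(isCase & g == "N/N"); refCtrl <- sum(!isCase & g == "N/N")
  rows <- lapply(lev, function(cat) {
    a <- sum(isCase & g == cat); c <- sum(!isCase & g == cat)
    if (cat == "N/N")
      return(data.frame(genotype = cat, n_case = a, n_ctrl = c, or = 1,
                        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                        haldane = FALSE))
    w <- oddsRatioWoolf(a, refCase, c, refCtrl)
    data.frame(genotype = cat, n_case = a, n_ctrl = c, or = w$or,
               ci_low = w$ci_low, ci_high = w$ci_high,
               p = fisherTwoSided(a, refCase, c, refCtrl),
               haldane = w$haldane_used)
  })
  do.call(rbind, rows)
}
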