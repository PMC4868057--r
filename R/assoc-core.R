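#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Point-probability convention: the two-sided P is the sum of the
#' hypergeometric probabilities of all tables with the observed margins
#' whose point probability does not exceed that of the observed table
#' (ties recognised within a relative tolerance of 1e-7, the convention of
#' mainstream statistical software). A zero margin gives P = 1.
#'
#' @param a,b,c,d cell counts: cases with / without the allele, controls
#'   with / without.
#' @return two-sided P value.
#' @export
fisherTwoSided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  if (lo == hi) return(1)
  dens <- stats::dhyper(lo:hi, m, n, k)
  min(1, sum(dens[dens <= dens[a - lo + 1] * (1 + 1e-7)]))
}

#' Odds ratio with Woolf confidence interval and Haldane's modification
#'
#' OR = ad/bc with the Woolf logit interval
#' \eqn{\exp(\ln OR \pm z \sqrt{1/a + 1/b + 1/c + 1/d})}, z = 1.959964 for
#' 95\%. When any cell is zero and \code{haldaneOnZero} is TRUE, 0.5 is added
#' to every cell before computing both the OR and the interval.
#'
#' @param a,b,c,d cell counts.
#' @param haldaneOnZero apply Haldane's modification when a cell is zero.
#' @param conf confidence level.
#' @return list with \code{or}, \code{ci_low}, \code{ci_high},
#'   \code{haldane_used}.
#' @export
oddsRatioWoolf <- function(a, b, c, d, haldaneOnZero = TRUE, conf = 0.95) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  haldane <- any(c(a, b, c, d) == 0)
  if (haldane) {
    if (!haldaneOnZero) {
      if (b * c == 0) stop("odds ratio undefined (bc = 0) without Haldane's modification")
    } else {
      a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    }
  }
  or <- (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  s <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci_low = or * exp(-z * s), ci_high = or * exp(z * s),
       haldane_used = haldane && haldaneOnZero)
}

#' Bonferroni-corrected significance level
#'
#' \code{familyAlpha / (nTests * nSubsets)}; e.g. 30 alleles in 5 subsets at
#' family level 0.05 gives 3.3e-4, and 57 positions in 2 subsets gives
#' 4.4e-4.
#'
#' @param nTests number of alleles (or positions) tested.
#' @param nSubsets number of disease subsets scanned.
#' @param familyAlpha family-wise error level.
#' @return corrected alpha.
#' @export
bonferroniAlpha <- function(nTests, nSubsets = 1, familyAlpha = 0.05) {
  stopifnot(nTests >= 1, nSubsets >= 1)
  familyAlpha / (nTests * nSubsets)
}

#' Per-allele association scan at one locus
#'
#' Each allele passing the control-frequency filter is tested against all
#' other chromosomes (b = case total - a, d = control total - c) with the
#' two-sided Fisher exact test; ORs and 95\% CIs use the Woolf interval with
#' Haldane's modification on zero cells. Works identically on carrier-kind
#' tables (dominant model), in which case the common-allele filter must be
#' supplied via \code{commonAlleles} because it is defined on allele counts.
#'
#' @param caseCounts,ctrlCounts \linkS4class{AlleleCountTable}s of the same
#'   locus and kind.
#' @param alpha significance level for the \code{significant} flag.
#' @param freqThreshold control allele-frequency filter (default 0.01).
#' @param commonAlleles optional explicit allele list overriding the filter.
#' @return data.frame with one row per tested allele: allele, model, the
#'   2x2 cells a/b/c/d, freq_case, freq_ctrl, or, ci_low, ci_high, p,
#'   haldane, significant.
#' @export
scanLocus <- function(caseCounts, ctrlCounts, alpha = bonferroniAlpha(30, 5),
                      freqThreshold = 0.01, commonAlleles = NULL) {
  stopifnot(is(caseCounts, "AlleleCountTable"), is(ctrlCounts, "AlleleCountTable"))
  if (caseCounts@locus != ctrlCounts@locus)
    stop("case and control tables are for different loci")
  if (countKind(caseCounts) != countKind(ctrlCounts))
    stop("case and control tables have different count kinds")
  if (is.null(commonAlleles)) {
    commonAlleles <- filterCommonAlleles(ctrlCounts, freqThreshold)
  }
  ka <- alleleCounts(caseCounts); kc <- alleleCounts(ctrlCounts)
  ta <- countTotal(caseCounts); tc <- countTotal(ctrlCounts)
  model <- if (countKind(caseCounts) == "allele") "allele" else "dominant"
  rows <- lapply(commonAlleles, function(al) {
    a <- unname(ifelse(al %in% names(ka), ka[al], 0))
    c <- unname(ifelse(al %in% names(kc), kc[al], 0))
    b <- ta - a; d <- tc - c
    w <- oddsRatioWoolf(a, b, c, d)
    p <- fisherTwoSided(a, b, c, d)
    data.frame(allele = al, model = model, a = a, b = b, c = c, d = d,
               freq_case = a / ta, freq_ctrl = c / tc, or = w$or,
               ci_low = w$ci_low, ci_high = w$ci_high, p = p,
               haldane = w$haldane_used, significant = p < alpha)
  })
  do.call(rbind, rows)
}

#' Display formatting used in the association reports
#'
#' ORs and CI bounds print to two decimals; P values to two significant
#' figures, switching to scientific \code{x.yE-0z} notation below 1e-3.
#'
#' @param p numeric P value(s).
#' @return character.
#' @export
formatP <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    x <- signif(x, 2)
    if (x < 1e-3) {
      e <- floor(log10(x))
      sprintf("%.1fE-%02d", x / 10^e, -e)
    } else if (x == round(x)) {
      sprintf("%.1f", x)
    } else {
      sub("0+$", "", sprintf("%.10f", x))
    }
  }, character(1))
}

#' @rdname formatP
#' @param or numeric odds ratio(s) or CI bound(s).
#' @export
formatOR <- function(or) sprintf("%.2f", or)
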