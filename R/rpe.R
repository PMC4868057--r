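#' One round of a relative predispositional effects analysis
#'
#' Removes the chromosomes carrying the excluded alleles from both case and
#' control totals and re-tests each eligible allele against the reduced
#' totals: a = allele count, b = (case total - sum of excluded case counts)
#' - a, likewise for controls. With an empty exclusion set this is exactly
#' the unconditioned scan.
#'
#' @param caseCounts,ctrlCounts allele-kind \linkS4class{AlleleCountTable}s.
#' @param excluded character vector of already-excluded alleles.
#' @param eligible alleles to test this round (disjoint from
#'   \code{excluded}); defaults to the control-frequency-filtered alleles
#'   minus \code{excluded}.
#' @param alpha significance level for the flag.
#' @param freqThreshold control allele-frequency filter for the default
#'   eligible set.
#' @return association data.frame as from \code{\link{scanLocus}}.
#' @export
rpeRound <- function(caseCounts, ctrlCounts, excluded = character(),
                     eligible = NULL, alpha = 0.05, freqThreshold = 0.01) {
  stopifnot(countKind(caseCounts) == "allele", countKind(ctrlCounts) == "allele")
  if (is.null(eligible))
    eligible <- setdiff(filterCommonAlleles(ctrlCounts, freqThreshold), excluded)
  if (length(intersect(eligible, excluded)))
    stop("eligible and excluded allele sets overlap")
  ka <- alleleCounts(caseCounts); kc <- alleleCounts(ctrlCounts)
  getc <- function(k, al) sum(k[names(k) %in% al])
  ta <- countTotal(caseCounts) - getc(ka, excluded)
  tc <- countTotal(ctrlCounts) - getc(kc, excluded)
  if (ta <= 0 || tc <= 0) stop("exclusion removed an entire group")
  redCase <- new("AlleleCountTable", locus = caseCounts@locus,
                 group = caseCounts@group,
                 counts = ka[!names(ka) %in% excluded], total = ta,
                 kind = "allele")
  redCtrl <- new("AlleleCountTable", locus = ctrlCounts@locus,
                 group = ctrlCounts@group,
                 counts = kc[!names(kc) %in% excluded], total = tc,
                 kind = "allele")
  scanLocus(redCase, redCtrl, alpha = alpha, commonAlleles = eligible)
}

#' Iterative RPE exclusion scan
#'
#' Round 0 is the unconditioned per-allele scan. Each subsequent round
#' excludes the allele with the smallest P value of the previous round
#' (ties break toward the larger |ln OR|, then lexicographically) and
#' re-tests the remainder on the reduced totals. The scan stops when the
#' smallest P value reaches \code{stopThreshold}, when a single eligible
#' allele remains, or at \code{maxRounds} exclusions.
#'
#' @inheritParams rpeRound
#' @param stopThreshold stop when no allele has P below this (default 0.05).
#' @param maxRounds cap on exclusion rounds (default unlimited;
#'   \code{maxRounds = 1} reproduces a single published exclusion round).
#' @return an \linkS4class{RPETrace}.
#' @export
rpeScan <- function(caseCounts, ctrlCounts, stopThreshold = 0.05,
                    maxRounds = Inf, alpha = 0.05, freqThreshold = 0.01) {
  eligible <- filterCommonAlleles(ctrlCounts, freqThreshold)
  if (length(eligible) < 2) stop("need at least two eligible alleles")
  excluded <- character()
  rounds <- list()
  reason <- NULL
  repeat {
    res <- rpeRound(caseCounts, ctrlCounts, excluded = excluded,
                    eligible = setdiff(eligible, excluded), alpha = alpha)
    ka <- alleleCounts(caseCounts); kc <- alleleCounts(ctrlCounts)
    rounds[[length(rounds) + 1]] <- list(
      excluded_allele = if (length(excluded)) excluded[length(excluded)] else NA_character_,
      case_total = as.integer(countTotal(caseCounts) - sum(ka[names(ka) %in% excluded])),
      ctrl_total = as.integer(countTotal(ctrlCounts) - sum(kc[names(kc) %in% excluded])),
      results = res)
    if (min(res$p) >= stopThreshold) { reason <- "no_p_below_threshold"; break }
    if (length(excluded) >= maxRounds) { reason <- "max_rounds"; break }
    if (nrow(res) <= 2) { reason <- "single_allele_left"; break }
    ord <- order(res$p, -abs(log(res$or)), res$allele)
    excluded <- c(excluded, res$allele[ord[1]])
  }
  new("RPETrace", locus = caseCounts@locus, rounds = rounds, stopReason = reason)
}
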