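#' @import methods
NULL

ALLELE_PATTERN <- "^[A-Z0-9]+\\*[0-9]{2,3}:[0-9]{2,3}$"
EMEA_LEVELS <- c("MPA", "GPA", "EGPA", "unclassifiable", "control")
ANCA_LEVELS <- c("positive", "negative", "unknown")

#' Subject-level HLA case-control cohort
#'
#' Holds one row per subject with phenotype labels (EMEA clinical class and
#' MPO-/PR3-ANCA status) and an unordered pair of four-digit HLA alleles per
#' locus. A locus is either fully typed (both alleles present) or wholly
#' missing for a subject; half-typed loci are rejected.
#'
#' @slot subjects data.frame with columns \code{subject_id},
#'   \code{emea_class}, \code{mpo_anca}, \code{pr3_anca} and, per locus
#'   \code{L}, allele columns \code{L_1} and \code{L_2} (\code{NA} when the
#'   locus is untyped for that subject).
#' @slot loci character vector of locus names present.
#' @export
setClass("HLACohort",
         representation(subjects = "data.frame", loci = "character"))

setValidity("HLACohort", function(object) {
  s <- object@subjects
  need <- c("subject_id", "emea_class", "mpo_anca", "pr3_anca")
  if (!all(need %in% names(s)))
    return(paste("missing columns:", paste(setdiff(need, names(s)), collapse = ", ")))
  if (anyDuplicated(s$subject_id))
    return("duplicate subject_id values")
  if (!all(s$emea_class %in% EMEA_LEVELS))
    return("emea_class outside {MPA, GPA, EGPA, unclassifiable, control}")
  if (!all(s$mpo_anca %in% ANCA_LEVELS) || !all(s$pr3_anca %in% ANCA_LEVELS))
    return("ANCA status outside {positive, negative, unknown}")
  ctrl <- s$emea_class == "control"
  if (any(ctrl & (s$mpo_anca == "positive" | s$pr3_anca == "positive")))
    return("control records must not be ANCA positive")
  for (loc in object@loci) {
    c1 <- s[[paste0(loc, "_1")]]; c2 <- s[[paste0(loc, "_2")]]
    if (is.null(c1) || is.null(c2))
      return(paste0("allele columns for locus ", loc, " absent"))
    if (any(is.na(c1) != is.na(c2)))
      return(paste0("half-typed genotypes at locus ", loc))
    typed <- !is.na(c1)
    ok <- grepl(ALLELE_PATTERN, c1[typed]) & grepl(ALLELE_PATTERN, c2[typed]) &
      startsWith(c1[typed], paste0(loc, "*")) &
      startsWith(c2[typed], paste0(loc, "*"))
    if (!all(ok))
      return(paste0("malformed allele names at locus ", loc))
  }
  TRUE
})

#' Per-locus allele or carrier counts for one group
#'
#' The machine form of a published allele-frequency table column: a named
#' count per allele plus the group total. For \code{kind = "allele"} the
#' total is the number of typed chromosomes (2n) and each subject contributes
#' two; for \code{kind = "carrier"} the total is the number of typed subjects
#' and each subject contributes at most one per allele.
#'
#' @slot locus locus name, e.g. \code{"DRB1"}.
#' @slot group group label, e.g. \code{"MPO-AAV"} or \code{"HC"}.
#' @slot counts named non-negative integer vector, one entry per allele.
#' @slot total total chromosomes (allele kind) or subjects (carrier kind).
#' @slot kind \code{"allele"} or \code{"carrier"}.
#' @export
setClass("AlleleCountTable",
         representation(locus = "character", group = "character",
                        counts = "numeric", total = "numeric",
                        kind = "character"))

setValidity("AlleleCountTable", function(object) {
  if (!object@kind %in% c("allele", "carrier"))
    return("kind must be 'allele' or 'carrier'")
  k <- object@counts
  if (is.null(names(k)) || any(!nzchar(names(k))))
    return("counts must be named by allele")
  if (any(k < 0) || any(k != round(k))) return("counts must be non-negative integers")
  if (object@total <= 0) return("total must be positive")
  if (any(k > object@total)) return("a count exceeds the group total")
  cap <- if (object@kind == "allele") object@total else 2 * object@total
  if (sum(k) > cap) return("counts sum exceeds the group total")
  TRUE
})

#' Trace of a relative predispositional effects (RPE) analysis
#'
#' Ordered rounds of an exclusion scan: round 0 is the unconditioned
#' per-allele scan; each later round removes the previously most strongly
#' associated allele from cases and controls and re-tests the remainder
#' against the reduced chromosome totals.
#'
#' @slot locus locus name.
#' @slot rounds list; each element has \code{excluded_allele} (\code{NA} for
#'   round 0), \code{case_total}, \code{ctrl_total} and \code{results}
#'   (the per-allele association data.frame of that round).
#' @slot stopReason one of \code{"no_p_below_threshold"},
#'   \code{"max_rounds"}, \code{"single_allele_left"}.
#' @export
setClass("RPETrace",
         representation(locus = "character", rounds = "list",
                        stopReason = "character"))

#' Additive-dosage logistic regression fit
#'
#' Term-wise Wald summary of a maximum-likelihood logistic fit of
#' case/control status on allele (or residue) dosages, with an honest
#' convergence flag: complete separation is reported, never silently
#' returned as a finite estimate.
#'
#' @slot terms data.frame with columns \code{term}, \code{beta}, \code{se},
#'   \code{p}, \code{or}, \code{ci_low}, \code{ci_high} (intercept excluded).
#' @slot nUsed number of subjects entering the fit.
#' @slot converged FALSE when the IRLS did not converge or the fit is
#'   separated (unbounded estimates).
#' @export
setClass("LogisticFit",
         representation(terms = "data.frame", nUsed = "integer",
                        converged = "logical"))

#' Allele-to-protein-residue lookup table
#'
#' One-letter amino-acid residue per allele per mature-protein position,
#' used to translate allele dosages into residue dosages for fine-mapping.
#'
#' @slot locus locus name.
#' @slot residues character matrix, rows = alleles, columns = positions
#'   (column names are the integer positions); every allele covers every
#'   position.
#' @export
setClass("AlleleProteinTable",
         representation(locus = "character", residues = "matrix"))

setValidity("AlleleProteinTable", function(object) {
  m <- object@residues
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("residue matrix needs allele rownames and position colnames")
  if (anyNA(suppressWarnings(as.integer(colnames(m)))))
    return("positions must be integers")
  if (anyNA(m) || any(nchar(m) != 1))
    return("every allele must have a single-letter residue at every position")
  TRUE
})

#' Two-locus linkage disequilibrium estimate
#'
#' EM haplotype-frequency estimate for a pair of alleles at different loci,
#' collapsed to presence/absence per chromosome, with the coupling
#' coefficient D and r-squared.
#'
#' @slot alleleA,alleleB the two alleles, as \code{"LOCUS*dd:dd"}.
#' @slot hapFreqs named length-4 haplotype frequency vector
#'   (\code{ab}, \code{aB}, \code{Ab}, \code{AB}; capital = allele present).
#' @slot d coupling coefficient D.
#' @slot r2 squared allele correlation, in [0, 1].
#' @slot nSubjects subjects typed at both loci.
#' @slot iterations EM iterations used.
#' @export
setClass("LDResult",
         representation(alleleA = "character", alleleB = "character",
                        hapFreqs = "numeric", d = "numeric", r2 = "numeric",
                        nSubjects = "integer", iterations = "integer"))

setValidity("LDResult", function(object) {
  if (abs(sum(object@hapFreqs) - 1) > 1e-6) return("haplotype freqs must sum to 1")
  if (object@r2 < -1e-12 || object@r2 > 1 + 1e-12) return("r2 outside [0, 1]")
  TRUE
})

#' Specification of a synthetic case-control cohort
#'
#' Generative truth for the simulator: cross-locus haplotype frequencies
#' (LD lives here; haplotypes are drawn independently per individual, i.e.
#' HWE), per-allele log odds ratios on a logistic liability, the population
#' baseline prevalence, target sample sizes and per-locus missingness.
#'
#' @slot loci locus names.
#' @slot hapFreqs data.frame with one column per locus (allele names) and a
#'   \code{freq} column summing to 1.
#' @slot alleleLogOR data.frame with columns \code{locus}, \code{allele},
#'   \code{log_or}; absent alleles have effect 0.
#' @slot prevalence baseline population disease prevalence, in (0, 0.5).
#' @slot nCases,nControls target sample sizes.
#' @slot missingRate named per-locus probability that a subject is untyped.
#' @slot seed integer RNG seed making the cohort reproducible.
#' @export
setClass("SimulationSpec",
         representation(loci = "character", hapFreqs = "data.frame",
                        alleleLogOR = "data.frame", prevalence = "numeric",
                        nCases = "integer", nControls = "integer",
                        missingRate = "numeric", seed = "integer"))

setValidity("SimulationSpec", function(object) {
  h <- object@hapFreqs
  if (!all(c(object@loci, "freq") %in% names(h)))
    return("hapFreqs needs one column per locus plus 'freq'")
  if (abs(sum(h$freq) - 1) > 1e-9) return("haplotype frequencies must sum to 1")
  if (any(h$freq < 0)) return("negative haplotype frequency")
  if (object@prevalence <= 0 || object@prevalence >= 0.5)
    return("prevalence must lie in (0, 0.5)")
  if (object@nCases < 1 || object@nControls < 1) return("sample sizes must be positive")
  if (length(object@missingRate) &&
      (any(object@missingRate < 0) || any(object@missingRate > 1)))
    return("missing rates must lie in [0, 1]")
  TRUE
})

#' Configuration for a full pipeline run
#'
#' @slot cohortFile optional subject-level cohort TSV (enables logistic,
#'   amino-acid and LD stages).
#' @slot countsFile optional allele-count TSV (enables scan and RPE stages);
#'   defaults to the packaged count fixture when both paths are empty.
#' @slot subsets disease subsets to analyse.
#' @slot models \code{"allele"} and/or \code{"dominant"}.
#' @slot alphaTests,alphaSubsets Bonferroni accounting inputs (number of
#'   allele tests and of subsets).
#' @slot freqThreshold control allele-frequency filter.
#' @slot maxRounds RPE round cap (\code{Inf} = run to the stopping rule).
#' @slot conditioningPairs list of length-2 character vectors of alleles for
#'   the conditional logistic stage.
#' @slot outDir output directory for the TSV report bundle.
#' @slot quiet suppress progress logging to stderr.
#' @export
setClass("AnalysisConfig",
         representation(cohortFile = "character", countsFile = "character",
                        subsets = "character", models = "character",
                        alphaTests = "numeric", alphaSubsets = "numeric",
                        freqThreshold = "numeric", maxRounds = "numeric",
                        conditioningPairs = "list", outDir = "character",
                        quiet = "logical"))

setMethod("show", "HLACohort", function(object) {
  s <- object@subjects
  cat("HLACohort:", nrow(s), "subjects,", length(object@loci), "loci (",
      paste(object@loci, collapse = ", "), ")\n")
  cat("  classes:", paste(sprintf("%s=%d", names(table(s$emea_class)),
                                  table(s$emea_class)), collapse = " "), "\n")
  for (loc in object@loci)
    cat("  ", loc, ": typed ", sum(!is.na(s[[paste0(loc, "_1")]])), "\n", sep = "")
})

setMethod("show", "AlleleCountTable", function(object) {
  cat(sprintf("AlleleCountTable: %s / %s (%s kind), %d alleles, total %d\n",
              object@locus, object@group, object@kind,
              length(object@counts), as.integer(object@total)))
})

setMethod("show", "RPETrace", function(object) {
  cat("RPETrace at", object@locus, "-", length(object@rounds), "round(s),",
      "stop:", object@stopReason, "\n")
  for (i in seq_along(object@rounds)) {
    r <- object@rounds[[i]]
    cat(sprintf("  round %d: excluded %s, totals %d/%d\n", i - 1L,
                ifelse(is.na(r$excluded_allele), "-", r$excluded_allele),
                r$case_total, r$ctrl_total))
  }
})

setMethod("show", "LogisticFit", function(object) {
  cat("LogisticFit on", object@nUsed, "subjects,",
      if (object@converged) "converged" else "NOT converged", "\n")
  print(object@terms, row.names = FALSE, digits = 3)
})

setMethod("show", "AlleleProteinTable", function(object) {
  cat(sprintf("AlleleProteinTable: %s, %d alleles x %d positions (%d polymorphic)\n",
              object@locus, nrow(object@residues), ncol(object@residues),
              length(polymorphicPositions(object))))
})

setMethod("show", "LDResult", function(object) {
  cat(sprintf("LDResult: %s vs %s  r2 = %.4f  D = %.5f  (n = %d, %d EM iterations)\n",
              object@alleleA, object@alleleB, object@r2, object@d,
              object@nSubjects, object@iterations))
})

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf("SimulationSpec: %d cases / %d controls, prevalence %g, loci %s\n",
              object@nCases, object@nControls, object@prevalence,
              paste(object@loci, collapse = ", ")))
  eff <- object@alleleLogOR[object@alleleLogOR$log_or != 0, ]
  if (nrow(eff))
    cat("  effects:", paste(sprintf("%s OR=%.2f", eff$allele, exp(eff$log_or)),
                            collapse = ", "), "\n")
})

# ---- accessors ----

#' @rdname HLACohort-class
#' @param object,x an object.
#' @export
setGeneric("subjects", function(object) standardGeneric("subjects"))
#' @rdname HLACohort-class
#' @export
setMethod("subjects", "HLACohort", function(object) object@subjects)

#' @rdname HLACohort-class
#' @export
setGeneric("cohortLoci", function(object) standardGeneric("cohortLoci"))
#' @rdname HLACohort-class
#' @export
setMethod("cohortLoci", "HLACohort", function(object) object@loci)

#' @rdname AlleleCountTable-class
#' @param object an object.
#' @export
setGeneric("alleleCounts", function(object) standardGeneric("alleleCounts"))
#' @rdname AlleleCountTable-class
#' @export
setMethod("alleleCounts", "AlleleCountTable", function(object) object@counts)

#' @rdname AlleleCountTable-class
#' @export
setGeneric("countTotal", function(object) standardGeneric("countTotal"))
#' @rdname AlleleCountTable-class
#' @export
setMethod("countTotal", "AlleleCountTable", function(object) object@total)

#' @rdname AlleleCountTable-class
#' @export
setGeneric("countKind", function(object) standardGeneric("countKind"))
#' @rdname AlleleCountTable-class
#' @export
setMethod("countKind", "AlleleCountTable", function(object) object@kind)

#' @rdname RPETrace-class
#' @param object an object.
#' @export
setGeneric("rpeRounds", function(object) standardGeneric("rpeRounds"))
#' @rdname RPETrace-class
#' @export
setMethod("rpeRounds", "RPETrace", function(object) object@rounds)

#' @rdname RPETrace-class
#' @export
setGeneric("stopReason", function(object) standardGeneric("stopReason"))
#' @rdname RPETrace-class
#' @export
setMethod("stopReason", "RPETrace", function(object) object@stopReason)

#' @rdname LogisticFit-class
#' @param object an object.
#' @export
setGeneric("fitTerms", function(object) standardGeneric("fitTerms"))
#' @rdname LogisticFit-class
#' @export
setMethod("fitTerms", "LogisticFit", function(object) object@terms)

#' @rdname LogisticFit-class
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname LogisticFit-class
#' @export
setMethod("isConverged", "LogisticFit", function(object) object@converged)
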