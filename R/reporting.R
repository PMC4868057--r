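#' Build a pipeline configuration
#'
#' @param cohortFile subject-level cohort TSV; empty string to skip the
#'   subject-level stages.
#' @param countsFile allele-count TSV; empty string uses the packaged count
#'   fixture.
#' @param subsets disease subsets to scan.
#' @param models \code{"allele"} and/or \code{"dominant"} (dominant needs a
#'   cohort file to derive carrier counts).
#' @param alphaTests,alphaSubsets Bonferroni accounting: number of allele
#'   tests and of subsets (defaults 30 and 5, giving 3.3e-4).
#' @param freqThreshold control allele-frequency filter.
#' @param maxRounds RPE round cap (default 1, the published single round).
#' @param conditioningPairs list of 2-vectors of allele names for the
#'   conditional logistic stage (needs a cohort file).
#' @param outDir output directory.
#' @param quiet suppress stderr progress logging.
#' @return an \linkS4class{AnalysisConfig}.
#' @export
analysisConfig <- function(cohortFile = "", countsFile = "",
                           subsets = c("MPA", "GPA", "EGPA", "MPO-AAV", "PR3-AAV"),
                           models = "allele", alphaTests = 30, alphaSubsets = 5,
                           freqThreshold = 0.01, maxRounds = 1,
                           conditioningPairs = list(), outDir = tempfile("hla_run_"),
                           quiet = FALSE) {
  new("AnalysisConfig", cohortFile = cohortFile, countsFile = countsFile,
      subsets = subsets, models = models, alphaTests = alphaTests,
      alphaSubsets = alphaSubsets, freqThreshold = freqThreshold,
      maxRounds = maxRounds, conditioningPairs = conditioningPairs,
      outDir = outDir, quiet = quiet)
}

.log <- function(quiet, ...) {
  if (!quiet) message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

#' Render an association scan as a report table
#'
#' Columns mirror the published table layout: allele, \code{n (\%)},
#' \code{OR (95\%CI)}, P (significant results marked with an asterisk) and
#' a zero-cell marker where Haldane's modification was applied. ORs and CI
#' bounds print to two decimals, P to two significant figures (scientific
#' below 1e-3).
#'
#' @param results data.frame from \code{\link{scanLocus}} (or a round of
#'   \code{\link{rpeRound}}).
#' @param sep column separator (default tab).
#' @return character vector of report lines (header first).
#' @export
renderAssociationTable <- function(results, sep = "\t") {
  if (!NROW(results)) stop("no association results to render")
  header <- paste(c("allele", "n (%)", "OR (95%CI)", "P", "significant",
                    "haldane"), collapse = sep)
  lines <- vapply(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    paste(c(r$allele,
            sprintf("%d (%.1f)", as.integer(r$a), 100 * r$freq_case),
            sprintf("%s (%s-%s)", formatOR(r$or), formatOR(r$ci_low),
                    formatOR(r$ci_high)),
            paste0(formatP(r$p), ifelse(r$significant, "*", "")),
            ifelse(r$significant, "TRUE", "FALSE"),
            ifelse(r$haldane, "TRUE", "FALSE")), collapse = sep)
  }, character(1))
  c(header, lines)
}

#' Run the full association pipeline
#'
#' Orchestrates every stage the configuration enables and writes a
#' deterministic bundle of TSV reports to the output directory: per-subset
#' allele scans (and dominant-model scans when a cohort is supplied), RPE
#' traces, conditional logistic pairs, amino-acid position scans, LD
#' estimates, plus a run log recording the significance thresholds, the
#' frequency filter and every excluded allele. Any stage error aborts the
#' run with a stage-named message and removes partial outputs.
#'
#' @param config an \linkS4class{AnalysisConfig}.
#' @param proteinTables optional named list of
#'   \linkS4class{AlleleProteinTable}s keyed by locus for the amino-acid
#'   stage (defaults to the packaged synthetic tables for DRB1/DPB1).
#' @return named list of written file paths, invisibly; the \code{bundle}
#'   attribute carries the in-memory results.
#' @export
runFullAnalysis <- function(config, proteinTables = NULL) {
  outDir <- config@outDir
  written <- character()
  alpha <- bonferroniAlpha(config@alphaTests, config@alphaSubsets)
  logLines <- c(sprintf("alpha_tests=%g", config@alphaTests),
                sprintf("alpha_subsets=%g", config@alphaSubsets),
                sprintf("alpha=%.6g", alpha),
                sprintf("freq_threshold=%g", config@freqThreshold))
  bundle <- list()
  fail <- function(stage, e) {
    unlink(written)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  emit <- function(name, lines) {
    path <- file.path(outDir, name)
    writeLines(lines, path)
    written <<- c(written, path)
    path
  }

  # ---- inputs ----
  cohort <- NULL
  counts <- tryCatch({
    if (nzchar(config@cohortFile)) cohort <- readCohort(config@cohortFile)
    if (nzchar(config@countsFile)) {
      readAlleleCounts(config@countsFile)
    } else if (is.null(cohort)) {
      readAlleleCounts(system.file("extdata", "aav_allele_counts.tsv",
                                   package = "HLAassoc"))
    } else NULL
  }, error = function(e) fail("input", e))
  if (!is.null(cohort)) {
    have <- vapply(config@subsets, function(ss)
      any(subsetPredicate(ss)(subjects(cohort))), logical(1))
    if (any(!have))
      fail("input", simpleError(paste("subset(s) absent from input:",
                                      paste(config@subsets[!have], collapse = ", "))))
  } else {
    have <- vapply(config@subsets, function(ss)
      any(endsWith(names(counts), paste0("/", ss))), logical(1))
    if (any(!have))
      fail("input", simpleError(paste("subset(s) absent from count tables:",
                                      paste(config@subsets[!have], collapse = ", "))))
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  loci <- if (!is.null(cohort)) cohortLoci(cohort) else
    unique(vapply(counts, function(x) x@locus, character(1)))

  # ---- allele scans + RPE ----
  tryCatch({
    for (loc in loci) {
      for (model in config@models) {
        kind <- if (model == "allele") "allele" else "carrier"
        getTab <- function(group) {
          if (!is.null(cohort))
            return(countsFromCohort(cohort, loc, group, kind))
          key <- paste(loc, group, sep = "/")
          if (kind != "allele") key <- paste(key, kind, sep = "/")
          tab <- counts[[key]]
          if (is.null(tab)) stop("no count table for ", key)
          tab
        }
        ctrl <- getTab("HC")
        common <- if (kind == "allele") NULL else {
          ctrlAll <- if (!is.null(cohort))
            countsFromCohort(cohort, loc, "HC", "allele") else
              counts[[paste(loc, "HC", sep = "/")]]
          filterCommonAlleles(ctrlAll, config@freqThreshold)
        }
        for (ss in config@subsets) {
          .log(config@quiet, "scan ", loc, " ", ss, " (", model, " model)")
          res <- scanLocus(getTab(ss), ctrl, alpha = alpha,
                           freqThreshold = config@freqThreshold,
                           commonAlleles = common)
          bundle[[paste("scan", loc, ss, model, sep = "/")]] <- res
          emit(sprintf("scan_%s_%s_%s.tsv", loc, gsub("[^A-Za-z0-9]", "", ss),
                       model), renderAssociationTable(res))
          if (model == "allele") {
            trace <- rpeScan(getTab(ss), ctrl, maxRounds = config@maxRounds,
                             freqThreshold = config@freqThreshold)
            bundle[[paste("rpe", loc, ss, sep = "/")]] <- trace
            lines <- character()
            for (i in seq_along(rpeRounds(trace))) {
              r <- rpeRounds(trace)[[i]]
              lines <- c(lines, sprintf("# round %d excluded=%s totals=%d/%d",
                                        i - 1L,
                                        ifelse(is.na(r$excluded_allele), "-",
                                               r$excluded_allele),
                                        r$case_total, r$ctrl_total),
                         renderAssociationTable(r$results))
              if (!is.na(r$excluded_allele))
                logLines <- c(logLines, sprintf("rpe_excluded %s %s %s",
                                                loc, ss, r$excluded_allele))
            }
            emit(sprintf("rpe_%s_%s.tsv", loc, gsub("[^A-Za-z0-9]", "", ss)),
                 lines)
          }
        }
      }
    }
  }, error = function(e) fail("scan", e))

  # ---- subject-level stages ----
  if (!is.null(cohort)) {
    tryCatch({
      for (pair in config@conditioningPairs) {
        for (ss in config@subsets) {
          .log(config@quiet, "conditional pair ", paste(pair, collapse = " vs "),
               " in ", ss)
          cp <- conditionalPair(cohort, ss, pair[1], pair[2])
          bundle[[paste("condition", ss, paste(pair, collapse = "_"),
                        sep = "/")]] <- cp
          emit(sprintf("condition_%s_%s.tsv", gsub("[^A-Za-z0-9]", "", ss),
                       gsub("[^A-Za-z0-9]", "", paste(pair, collapse = "_"))),
               c(paste(names(cp), collapse = "\t"),
                 apply(cp, 1, paste, collapse = "\t")))
        }
      }
      if (is.null(proteinTables))
        proteinTables <- tryCatch(
          setNames(lapply(intersect(loci, c("DRB1", "DPB1")),
                          syntheticProteinTable),
                   intersect(loci, c("DRB1", "DPB1"))),
          error = function(e) NULL)
      aaAlpha <- bonferroniAlpha(57, 2)
      for (loc in names(proteinTables)) {
        for (ss in config@subsets) {
          .log(config@quiet, "amino-acid scan ", loc, " ", ss)
          aa <- scanPositions(cohort, ss, loc, proteinTables[[loc]],
                              freqThreshold = config@freqThreshold,
                              alpha = aaAlpha)
          bundle[[paste("aa", loc, ss, sep = "/")]] <- aa
          emit(sprintf("aa_%s_%s.tsv", loc, gsub("[^A-Za-z0-9]", "", ss)),
               c(paste(names(aa), collapse = "\t"),
                 apply(aa, 1, paste, collapse = "\t")))
        }
      }
      for (pair in config@conditioningPairs) {
        pa <- .parseAllele(pair[1]); pb <- .parseAllele(pair[2])
        if (pa$locus != pb$locus) {
          ld <- emR2(cohort, "control", pair[1], pair[2])
          bundle[[paste("ld", paste(pair, collapse = "_"), sep = "/")]] <- ld
          emit(sprintf("ld_%s.tsv",
                       gsub("[^A-Za-z0-9]", "", paste(pair, collapse = "_"))),
               c("allele_a\tallele_b\tr2\td\tn_subjects",
                 sprintf("%s\t%s\t%.6f\t%.6f\t%d", ld@alleleA, ld@alleleB,
                         ld@r2, ld@d, ld@nSubjects)))
        }
      }
    }, error = function(e) fail("subject-level", e))
  }

  emit("run_log.txt", logLines)
  .log(config@quiet, "bundle written to ", outDir, " (", length(written), " files)")
  out <- written
  names(out) <- basename(written)
  attr(out, "bundle") <- bundle
  invisible(out)
}
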