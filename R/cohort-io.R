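#' Build an HLACohort from a subject data.frame
#'
#' @param subjects data.frame with the columns described in
#'   \linkS4class{HLACohort}.
#' @param loci locus names; by default inferred from paired \code{<locus>_1}
#'   / \code{<locus>_2} columns.
#' @return an \linkS4class{HLACohort}.
#' @export
makeCohort <- function(subjects, loci = NULL) {
  if (is.null(loci)) {
    cand <- sub("_1$", "", grep("_1$", names(subjects), value = TRUE))
    loci <- cand[paste0(cand, "_2") %in% names(subjects)]
  }
  subjects$subject_id <- as.character(subjects$subject_id)
  for (loc in loci) for (k in 1:2) {
    col <- paste0(loc, "_", k)
    v <- as.character(subjects[[col]])
    v[!is.na(v) & v == ""] <- NA
    subjects[[col]] <- v
  }
  new("HLACohort", subjects = subjects, loci = loci)
}

#' Read a subject-level cohort TSV
#'
#' UTF-8 tab-separated, one row per subject, columns \code{subject_id},
#' \code{emea_class}, \code{mpo_anca}, \code{pr3_anca} and two allele columns
#' per locus (\code{DRB1_1}, \code{DRB1_2}, ...). Empty allele cells mark an
#' untyped locus; a locus must be both or neither. Malformed allele names and
#' half-typed loci are hard errors naming the offending rows.
#'
#' @param path file path.
#' @return an \linkS4class{HLACohort}.
#' @export
readCohort <- function(path) {
  stopifnot(file.exists(path))
  s <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                         na.strings = "")
  cand <- sub("_1$", "", grep("_1$", names(s), value = TRUE))
  loci <- cand[paste0(cand, "_2") %in% names(s)]
  if (!length(loci)) stop("header declares no <locus>_1/<locus>_2 column pairs")
  if (anyDuplicated(s$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(s$subject_id[duplicated(s$subject_id)]), collapse = ", "))
  for (loc in loci) {
    a1 <- s[[paste0(loc, "_1")]]; a2 <- s[[paste0(loc, "_2")]]
    half <- which(is.na(a1) != is.na(a2))
    if (length(half))
      stop("half-typed genotype at locus ", loc, " in row(s) ",
           paste(half, collapse = ", "))
    typed <- which(!is.na(a1))
    bad <- typed[!(grepl(ALLELE_PATTERN, a1[typed]) &
                     grepl(ALLELE_PATTERN, a2[typed]) &
                     startsWith(a1[typed], paste0(loc, "*")) &
                     startsWith(a2[typed], paste0(loc, "*")))]
    if (length(bad))
      stop("unparseable allele name at locus ", loc, " in row(s) ",
           paste(bad, collapse = ", "))
  }
  makeCohort(s, loci)
}

#' Write a cohort back to TSV
#'
#' Inverse of \code{\link{readCohort}}: a written cohort reads back
#' field-for-field identical.
#'
#' @param cohort an \linkS4class{HLACohort}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  utils::write.table(subjects(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Phenotype predicate for a named disease subset
#'
#' Maps the subset names used throughout the analysis onto row predicates:
#' clinical subsets by EMEA class, ANCA subsets by antibody specificity
#' regardless of clinical class (\code{"MPO-AAV"} = MPO-ANCA positive,
#' \code{"PR3-AAV"} = PR3-ANCA positive), \code{"AAV"} = any non-control,
#' \code{"HC"}/\code{"control"} = controls.
#'
#' @param subset subset name.
#' @return function mapping a subjects data.frame to a logical vector.
#' @export
subsetPredicate <- function(subset) {
  switch(subset,
    "MPA" = function(s) s$emea_class == "MPA",
    "GPA" = function(s) s$emea_class == "GPA",
    "EGPA" = function(s) s$emea_class == "EGPA",
    "unclassifiable" = function(s) s$emea_class == "unclassifiable",
    "MPO-AAV" = function(s) s$mpo_anca == "positive",
    "PR3-AAV" = function(s) s$pr3_anca == "positive",
    "AAV" = function(s) s$emea_class != "control",
    "HC" = , "control" = function(s) s$emea_class == "control",
    stop("unknown subset: ", subset))
}

#' Derive an allele-count or carrier-count table from a cohort
#'
#' Under the allele (chromosome) kind each typed subject contributes two
#' counts, homozygotes twice to the same allele, and the total is 2n typed
#' chromosomes. Under the carrier kind each typed subject contributes at
#' most one count per allele (homozygotes and heterozygotes alike) and the
#' total is the number of typed subjects. Subjects untyped at the locus are
#' excluded from numerator and total alike.
#'
#' @param cohort an \linkS4class{HLACohort}.
#' @param locus locus name.
#' @param group subset name (see \code{\link{subsetPredicate}}) or a
#'   predicate function over the subjects data.frame.
#' @param kind \code{"allele"} or \code{"carrier"}.
#' @return an \linkS4class{AlleleCountTable}.
#' @export
countsFromCohort <- function(cohort, locus, group, kind = c("allele", "carrier")) {
  kind <- match.arg(kind)
  stopifnot(locus %in% cohortLoci(cohort))
  s <- subjects(cohort)
  pred <- if (is.function(group)) group else subsetPredicate(group)
  label <- if (is.function(group)) "custom" else group
  s <- s[pred(s), , drop = FALSE]
  if (!nrow(s)) stop("empty group for locus ", locus)
  a1 <- s[[paste0(locus, "_1")]]; a2 <- s[[paste0(locus, "_2")]]
  typed <- !is.na(a1)
  a1 <- a1[typed]; a2 <- a2[typed]
  if (!length(a1)) stop("no subjects typed at ", locus, " in group ", label)
  if (kind == "allele") {
    k <- table(c(a1, a2))
    total <- 2 * length(a1)
  } else {
    carried <- mapply(function(x, y) unique(c(x, y)), a1, a2, SIMPLIFY = FALSE)
    k <- table(unlist(carried, use.names = FALSE))
    total <- length(a1)
  }
  counts <- as.numeric(k); names(counts) <- names(k)
  new("AlleleCountTable", locus = locus, group = label,
      counts = counts[order(names(counts))], total = total, kind = kind)
}

#' Alleles passing the control-frequency filter
#'
#' Returns, in the table's own order, the alleles whose control frequency
#' \code{count / total_2n} reaches \code{threshold}. The filter is defined on
#' allele (chromosome) counts.
#'
#' @param counts control \linkS4class{AlleleCountTable} of kind
#'   \code{"allele"}.
#' @param threshold minimum control allele frequency (default 0.01).
#' @return character vector of allele names.
#' @export
filterCommonAlleles <- function(counts, threshold = 0.01) {
  stopifnot(is(counts, "AlleleCountTable"))
  if (countKind(counts) != "allele")
    stop("the frequency filter is defined on allele-kind counts")
  k <- alleleCounts(counts)
  names(k)[k / countTotal(counts) >= threshold]
}

#' Read allele-count tables from TSV
#'
#' Expects columns \code{locus}, \code{group}, \code{allele}, \code{count},
#' \code{total_2n}, \code{kind}; returns one \linkS4class{AlleleCountTable}
#' per (locus, group, kind) combination.
#'
#' @param path TSV path.
#' @return named list of \linkS4class{AlleleCountTable}s; names are
#'   \code{"locus/group"} (allele kind) or \code{"locus/group/carrier"}.
#' @export
readAlleleCounts <- function(path) {
  stopifnot(file.exists(path))
  d <- utils::read.delim(path, check.names = FALSE,
                         colClasses = c(count = "numeric", total_2n = "numeric"))
  out <- list()
  for (key in split(d, interaction(d$locus, d$group, d$kind, drop = TRUE))) {
    counts <- key$count; names(counts) <- key$allele
    tab <- new("AlleleCountTable", locus = key$locus[1], group = key$group[1],
               counts = counts, total = key$total_2n[1], kind = key$kind[1])
    nm <- paste(key$locus[1], key$group[1], sep = "/")
    if (key$kind[1] != "allele") nm <- paste(nm, key$kind[1], sep = "/")
    out[[nm]] <- tab
  }
  out
}

#' Packaged allele-count tables of the AAV case-control study
#'
#' Loads the shipped machine transcription of the full DRB1 and DPB1
#' allele-count tables of a Japanese ANCA-associated vasculitis case-control
#' cohort (five disease subsets plus healthy controls; allele kind).
#'
#' @param locus optional locus filter (\code{"DRB1"} or \code{"DPB1"}).
#' @param group optional group filter (\code{"MPA"}, \code{"EGPA"},
#'   \code{"GPA"}, \code{"MPO-AAV"}, \code{"PR3-AAV"}, \code{"HC"}).
#' @return a single \linkS4class{AlleleCountTable} when both filters are
#'   given, else a named list.
#' @export
aavAlleleCounts <- function(locus = NULL, group = NULL) {
  path <- system.file("extdata", "aav_allele_counts.tsv", package = "HLAassoc")
  tabs <- readAlleleCounts(path)
  if (!is.null(locus) && !is.null(group)) return(tabs[[paste(locus, group, sep = "/")]])
  if (!is.null(locus)) tabs <- tabs[startsWith(names(tabs), paste0(locus, "/"))]
  if (!is.null(group)) tabs <- tabs[endsWith(names(tabs), paste0("/", group))]
  tabs
}

#' Packaged reference association statistics
#'
#' The odds ratios, 95\% confidence bounds and P values printed alongside the
#' packaged count tables (including the single-round RPE P values of the
#' ANCA-specificity tables), as displayed: ORs/CIs to two decimals, P to two
#' significant figures. Used for regression testing the scan engine.
#'
#' @return data.frame with columns locus, group, allele, or, ci_low,
#'   ci_high, p (character, as printed), p_rpe, haldane.
#' @export
aavReferenceStats <- function() {
  path <- system.file("extdata", "aav_reference_stats.tsv", package = "HLAassoc")
  utils::read.delim(path, check.names = FALSE,
                    colClasses = c(p = "character", p_rpe = "character"))
}
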