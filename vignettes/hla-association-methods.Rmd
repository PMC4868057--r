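---
title: "Methods: HLA case-control association at multiallelic loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HLA case-control association at multiallelic loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HLAassoc)
```

This vignette is the package's account of its statistical methods: the
models, the choices that were genuinely open and how they were settled, the
tunable parameters, what the synthetic-data generator does and does not
emulate, and the numerical details a careful user should know. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The study design the package models

A case-control immunogenetics design at classical HLA class II loci:
patients with ANCA-associated vasculitis (AAV), grouped either by clinical
EMEA class (MPA, GPA, EGPA, unclassifiable) or by ANCA antigen specificity
(MPO-AAV, PR3-AAV — orthogonal to clinical class), against one panel of
healthy controls. Genotypes are unordered pairs of four-digit alleles per
locus (`DRB1*13:02`), with per-locus missingness: a subject may be typed at
DRB1 but not DPB1, and is then excluded from DPB1 analyses only — numerator
and denominator alike. This is why the packaged control tables carry 2n =
1192 chromosomes at DRB1 but 1186 at DPB1. How partially typed subjects
were handled is not derivable from count tables; per-locus exclusion is the
only convention consistent with those totals and is adopted throughout.

## Per-allele 2x2 scans

Each allele `A` with control frequency at or above the `freqThreshold`
(default 0.01, applied to allele-model control counts in all cases) is
tested against *all other chromosomes pooled*: `a` = case chromosomes
carrying `A`, `b` = case total − a, and likewise `c`, `d` for controls.
Under the dominant (carrier) model the unit is the subject and `a` counts
carriers. Alleles present in cases but rare or absent in controls simply
fail the control-frequency filter; rare chromosomes are never pooled into
an "other" bin — totals are all typed chromosomes, which is what makes the
percentage columns of the packaged tables come out right.

Two conventions needed fixing where the source material is silent:

* **Two-sided Fisher P.** `fisherTwoSided()` uses the point-probability
  rule — sum the hypergeometric probabilities of every table (same margins)
  whose point probability is at most that of the observed table, with a
  relative tie tolerance of 1e-7. This is the convention of mainstream
  statistical software, and it reproduces every printed P value in the
  packaged tables at printed precision (the full-table regression test and
  the acceptance script check all ~600 cells). A zero margin returns P = 1.
* **OR confidence interval.** The Woolf logit interval with z = 1.959964.
  Haldane's modification (0.5 added to every cell) applies when any cell is
  zero, to the OR and CI only — never to the Fisher P, which handles zero
  cells natively. This reproduces the published zero-cell rows (e.g. an
  allele absent from 124 PR3-AAV chromosomes at control count 27 gives
  OR 0.17, CI 0.01–2.81).

Multiplicity is plain Bonferroni, stated as an accounting identity:
`bonferroniAlpha(30, 5)` = 0.05/150 = 3.3e-4 for 30 common alleles (21 DRB1
+ 9 DPB1) in five subsets; `bonferroniAlpha(57, 2)` = 0.05/114 = 4.4e-4 for
57 polymorphic amino-acid positions in two subsets.

## Relative predispositional effects (RPE)

At a multiallelic locus every allele's "all other chromosomes" pool
contains the other alleles, so a strong protective association (13:02)
inflates the apparent predisposition of everything else. The RPE procedure
removes the most strongly associated allele's chromosomes from cases and
controls and re-tests each remaining allele against the reduced totals,
iterating until no allele reaches `stopThreshold` (0.05). The per-round
statistic is a fresh Fisher test on the reduced 2×2 — this choice (rather
than an expected-proportion chi-square) reproduces the published
single-round P values (0.0012 for 09:01 after removing 13:02; 0.011 for
DPB1 05:01 after removing 04:01) exactly from the printed counts.

Round-k results depend only on the excluded *set*, not the exclusion order
(tested property). Ties in the exclusion choice break toward the larger
|ln OR|, then lexicographically; the packaged data never tie, but the rule
must exist for the procedure to be deterministic. `maxRounds = 1`
reproduces published single-round tables; the default runs to the stopping
rule.

## Additive-dosage logistic models and conditioning

`fitAdditive()` is maximum-likelihood logistic regression (IRLS via
`stats::glm`) of case status on per-subject allele dosages (0/1/2), Wald
tests per term. "Conditional" analysis means adding the other allele's
dosage as a covariate in the same fit — no matched sets, no stratification;
nothing in the design implies matching. Wald rather than likelihood-ratio P
values are reported; with these sample sizes and effect sizes the two agree
closely, and Wald is what the OR-with-CI table layout implies.

Complete separation is *flagged* (`converged = FALSE`, triggered by IRLS
non-convergence, |β| > 15 or SE > 100), never silently returned and never
"fixed" by penalisation — at these frequencies separation means the data
cannot support the fit, and the caller should know.

The genotype-category analysis classifies subjects at one locus by copies
of a risk and a protective allele (risk/risk, risk/N, risk/protective,
protective/N, protective/protective vs the N/N referent, N = any neutral
allele) and reports Fisher P and Haldane-guarded ORs per category against
N/N. Under a multiplicative (additive-in-log-odds) model the expected
risk/N vs N/N OR equals the per-allele OR — the recovery test uses exactly
this identity.

## Amino-acid fine-mapping

`residueDosage()` maps each chromosome through an allele→residue table, so
residue dosages are exact linear images of allele dosages (a tested
invariant: the dosage of residue r at position p is the sum of the dosage
vectors of the alleles carrying r at p). Per polymorphic position, every
residue with control frequency ≥ 1% is tested residue-vs-all-others; at
positions with three or more residues only the minimum-P residue is
reported (ties break toward larger |ln OR|, then alphabetically), and the
`collapsed` flag records that a choice was made. Conditioning adds residue
or allele dosages as covariates; a candidate residue whose dosage is
perfectly collinear with a conditioning covariate (in particular, the
conditioned residue itself) is skipped rather than fitted, because the
aliased fit would silently drop the covariate and masquerade as
unconditioned.

Positions whose residue partition of the alleles coincides are in absolute
LD and must scan identically; the packaged DPB1 table encodes such a pair
(positions 36/55) and the identity is asserted, mirroring how such pairs
are reported as one signal.

**The packaged residue table is synthetic.** The real IMGT/HLA protein
alignment cannot be redistributed here; the shipped table
(`synthetic_hla_protein_residues.tsv`, loadable via
`syntheticProteinTable()`) covers the common alleles of the packaged count
tables plus a pooled-rare pseudo-allele per locus, and is constrained to
reproduce the encodings the analyses rely on: position 67 F carried by
exactly 08:02/09:01/11:01/12:02; position 71 E carried only by 13:02; the
36/55 absolute-LD pair; and exactly 38 + 19 = 57 polymorphic positions.
One additional structural constraint is imposed by design: at every DRB1
position other than 71, the residue class containing 13:02 carries at
least 12% control frequency from *other* alleles. Without it, a synthetic
position can near-duplicate the 13:02 dosage vector and the "uniquely
tagging residue ranks first" property becomes a coin flip between
statistically identical signals — a fixture artefact, not a method
property. Real alignments impose analogous dilution naturally.
`readProteinTable()` ingests any table in the same four-column TSV layout,
so a real alignment export drops in directly.

## Two-locus r² by EM

For an allele pair at two loci, genotypes are collapsed to presence/absence
dosages per subject; only the double-heterozygote cell is phase-ambiguous.
EM starts at linkage equilibrium, splits that cell by the phase posterior
each iteration, and stops when the log-likelihood improves by less than
`tol` (1e-10, `maxIter` 1000). The estimated haplotype frequencies
reproduce the single-locus allele frequencies exactly at every iteration
(margin preservation — a tested invariant), and
r² = D²/(pA(1−pA)pB(1−pB)). Estimation defaults to the healthy-control
group, the convention for reporting background LD. The independent check
is a profile-likelihood optimisation over the one free haplotype frequency
— a different algorithm that must agree to 1e-4 (absolute, since r² lives
in [0,1]).

A calibration note: at the study's control-panel size (2n = 1192
chromosomes) the *sampling* standard deviation of r̂² around a true 0.44 is
about 0.053 even when phase is known — the phase-known multinomial oracle
in the test suite computes this directly — so roughly 86% of estimates fall
within ±0.08 of the truth and no estimator does materially better at this
n. The tests therefore hold the EM estimator to unbiasedness and to the
oracle's spread, not to a tighter band.

## The synthetic cohort generator

`simulateCohort()` draws two cross-locus haplotypes per individual from a
haplotype frequency table (HWE across the two draws; *all* LD lives inside
the table — `pairLDHaplotypeFreqs()` injects a target D or r² between one
allele pair while preserving both margins), assigns disease by
`logit P(case) = β₀ + Σ dosage × ln OR`, and keeps individuals by rejection
until the target case and control counts are met. β₀ is solved by
`tuneIntercept()` from the exact prevalence sum over diplotype score
classes (monotone root-finding, prevalence matched to 1e-6). One private
seeded RNG stream per cohort; the global RNG state is untouched and the
same seed yields a byte-identical cohort.

Retrospective sampling from a single population model keeps one generative
truth for both the contingency-table and the logistic analyses, and odds
ratios are invariant to outcome-dependent sampling under the logistic
model — which is also why simulations are free to use a convenient
prevalence. Defaults are the study conditions: baseline prevalence 1e-4
(AAV is rare), 377 cases / 596 controls, control allele frequencies from
the packaged tables (unlisted rare chromosomes pooled into a `*99:99`
catch-all), headline effects 09:01 OR 1.57 and 13:02 OR 0.42, DPB1 04:01
null with its association induced through r² = 0.44 LD with 13:02, and
0.5% DPB1 missingness (the 1192 vs 1186 pattern). Engine-calibration
simulations (logistic recovery at 2000+2000, the property-rate loops) use
prevalence 0.01–0.05 so that rejection sampling stays cheap; prevalence
affects none of the tested quantities. Property simulations use 800/800
(conditional dissection) and 750/1000 (amino-acid ranking) — sizes chosen
so the *method property* is tested with stable power rather than
re-enacting the study's marginal power; the acceptance script states the
sizes it used alongside each rate.

What the generator does **not** emulate: population stratification,
relatedness, genotyping error, allele-calling ambiguity, haplotype-level
(cis) interaction effects, and case-mix heterogeneity across EMEA classes
(simulated cases carry one class label and one ANCA specificity). Passing
tests therefore validate the statistical machinery under a clean HWE
population with known truth; they do not certify robustness to the
artefacts real cohorts add.

## Power

`powerTwoProportions()` is the normal-approximation power for an
allele-frequency comparison at unequal chromosome counts, with the case
frequency derived from the control frequency via the odds ratio and a
continuity correction (Fleiss) by default, approximating exact-test power
calculators. The test suite checks it against 2000-replicate Fisher-test
simulation at a study-sized configuration (agreement within 0.03). It is
an approximation for planning, not a reproduction of any published power
table.

## Degenerate inputs and numerical conventions

* Zero margins in 2×2 tables → P = 1; `bc = 0` without Haldane → error.
* Empty groups, half-typed loci, duplicate subject ids, malformed allele
  names → hard errors naming the offending rows; a cohort is never
  silently repaired.
* Constant dosage predictors and one-class outcomes → errors before
  fitting; separation → honest `converged = FALSE`.
* Monomorphic alleles in the LD group → error (r² undefined).
* Display rounding (ORs/CIs to 2 decimals, P to 2 significant figures,
  scientific below 1e-3) is confined to `formatP()`/`formatOR()` and the
  report renderer; all computation is full precision.

## Problem sizes used by the shipped checks

Fixture-driven checks are instantaneous. The seeded simulations use:
100 cohorts of 800+800 (conditional dissection pattern), 100 cohorts of
750+1000 with two 38-position scans each (amino-acid ranking and
conditioning), 200 control panels of 596 (r² recovery), 200 cohorts of
2000+2000 (logistic bias), and 2000 null scans of 21 alleles at the study's
chromosome counts (type-I calibration). Together they run in a few minutes
on one CPU.
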