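---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescape)
```

`splicescape` implements the analysis layer of a splicing-dysregulation
cohort study: PSI quantification and differential-splicing calls, the
intron-retention feature analysis with maximum-entropy splice-site scoring,
RBP motif binding scores, Z-score composite signatures with survival
stratification, and genomic-alteration statistics for splicing-regulatory
genes (SRGs). This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic-data generator does
and does not emulate.

## Differential splicing

PSI for an event in one sample is the length-normalized inclusion
fraction, `psi = (I/l_I) / (I/l_I + S/l_S)`. Effective lengths default to
`l_I = l_S = 1`; length normalization only matters when inclusion and
skipping junctions have unequal mappable support, and callers that need it
can pass annotation-derived lengths. `I + S = 0` marks the event
not-quantifiable in that sample (NA), and an event with no quantifiable
replicate in a group is skipped and logged rather than guessed at.

The group test is a binomial likelihood-ratio test on pooled
inclusion/skipping counts: one shared inclusion rate vs one rate per group,
`G = 2(ll_1 - ll_0)` referred to chi-squared with 1 df. This is a
deliberately transparent stand-in for the testing machinery of dedicated
AS pipelines (rMATS, SUPPA) — not a reimplementation of either — chosen
because every part of it can be checked against closed-form oracles (for a
single replicate per group it reduces to the G-test on the 2×2 table, and
the tests verify agreement with Pearson's chi-squared there). ΔPSI is the
difference of replicate-mean PSI, group B minus group A, with group order
taken from factor level order. Pooling assumes replicates within a group
share one inclusion rate; overdispersion across replicates would make the
test anti-conservative, which is why the null-calibration property (p
approximately uniform on simulated null events) is part of the test suite.

A DSE passes `|dPSI| > 0.1` **and** `q < 0.1` (BH), both strict
inequalities. The same strictness is used everywhere a gate is stated
(`deg_call`, `rank_rbps`' `f > 0.70`).

## The intron-retention splicing code

Constitutive introns are selected as the `n = 300` events with ΔPSI = 0
nearest the center of the ΔPSI-sorted event list, ties to the lower index;
fewer than `n` zeros returns all of them with a warning. Features are
intron length, GC content (N bases excluded from numerator and
denominator), and splice-site strength.

Site windows follow the standard donor/acceptor geometry: the donor 9-mer
is the last 3 exonic + first 6 intronic bases; the acceptor 21-mer is the
last 20 intronic + first 1 exonic base. (The classical acceptor model uses
23 bases; 21 is this package's default geometry, and `fit_maxent` accepts
windows of any single width, so a 23-mer model is a matter of passing
23-base windows.) Minus-strand windows are reverse-complemented so all
windows read 5'→3' on the sense strand.

### Maximum-entropy model

Site strength is `log2(P_signal(w)/P_background(w))` in bits, where each
distribution is the maximum-entropy distribution over the window space
subject to empirical constraints: positional base frequencies (order 0) or
positional + adjacent-pair frequencies (order 1). Two representation facts
drive the implementation:

* For these constraint sets the maximum-entropy solution factorizes along
  the position chain, so the distribution is stored as chain factors and
  never enumerated — necessary because the acceptor space (4^21 ≈ 4×10^12
  windows) cannot be tabulated.
* Fitting is genuine iterative proportional fitting: factors are scaled by
  the ratio of target to model marginals, with model marginals recomputed
  exactly by forward–backward message passing each step, until the largest
  marginal deviation is below `tol = 1e-6` (cap 10,000 iterations;
  non-convergence is an error carrying the diagnostics). On a chain this
  converges in a couple of sweeps; the diagnostics are retained on the
  model object.

Constraints are smoothed with a pseudocount (default 0.5 per positional
cell, distributed as 1/4 that per pair cell so positional and pair
constraints stay mutually consistent); this keeps log-odds finite for
bases unseen in training. Order-0 scores are therefore exactly the sum of
positional log-odds of the smoothed frequencies, which the tests assert.
`maxent_distribution()` enumerates the fitted distribution for small
widths to verify it sums to one and reproduces every constrained marginal;
windows containing N are flagged and not scored. Order-1 constraints are
restricted to adjacent pairs to keep the parameterization chain-structured
and desk-scale.

Feature comparisons between intron groups use two-sided Wilcoxon rank-sum
tests (unpaired — retained and constitutive sets differ in size), exact
for small tie-free samples, and refuse groups below 3.

## RBP binding scores

Motifs are IUPAC consensus strings (U ≡ T); scanning counts all
overlapping match starts on the provided sense-strand sequence only — RNA
binding happens on the transcript, so no reverse-complement scan is done.
Binding frequency `f` is the fraction of sequences with ≥ 1 match. The
mean appearance count `c̄` is taken over **matching** sequences (absence
is already captured by `f`, so averaging zeros in would penalize it
twice); `count_mode = "all"` provides the other convention. The binding
score is `B = f·c̄`. Ranking filters `f > 0.70` first and then takes the
top 20 by `B` (filter-then-rank: the frequency gate defines eligibility,
the score defines priority), with ties broken by `f` descending then name
ascending so output is deterministic.

## Signatures

Z-scores standardize each gene against the mean and SD of a designated
reference sample set (e.g. normal tissue); zero-variance genes are
excluded and listed. When a cohort has no reference samples the whole
cohort is the reference (cohort-wide standardization) — the fallback used
for survival-only cohorts. A composite signature score is the **sum** of
member-gene Z-scores over the detected members (the ±7 AR-activity cutoff
is only meaningful on the sum scale of a 20-gene signature; one convention
is used everywhere). Missing members reduce the detected count, which is
reported. Fractionation at ±7 is inclusive (≥ 7 / ≤ −7), with a strict
variant available; median splits send ties to the low group; extreme
selection (top/bottom 20) breaks boundary ties by sample id.

The shipped signatures are the 20 androgen-induced AR target genes and the
13-gene unfavorable / 13-gene favorable prognostic SRG signatures.

## Survival

Kaplan–Meier estimation and the two-group log-rank test wrap the
`survival` package (subjects censored at an event time remain at risk for
that time). The best-cutoff stratification scans the unique score values
inside the 10–90% quantile range — the bounds prevent near-empty groups,
as no guidance exists for them in common practice — tests `{score > c}` vs
`{score ≤ c}` at each candidate, and returns the minimizer (ties → the
smallest cutoff). Minimal-p selection is known to inflate type-I error
(the tests assert this qualitatively under the null); `n_perm` attaches a
permutation-adjusted p for the selected cutoff, off by default so that the
default output matches the conventional procedure. Direction labels come
from comparing the two KM curves at the last common follow-up time: lower
survival in the high-score group ⇒ "unfavorable".

## SRG alteration statistics

One call per patient–gene cell from {amp, del, mut, none}; multi-track
input is collapsed with precedence amp > del > mut at matrix construction.
Cumulative frequency counts a patient once regardless of how many set
genes are altered; on independent per-gene alterations it matches the
closed form `1 − (1 − p)^G`, which the tests verify. Co-occurrence uses a
one-sided Fisher exact test (enrichment of co-alteration); the test suite
checks it against exhaustive hypergeometric enumeration for **all** 2×2
tables with n ≤ 20. CNV–expression association and grade association are
two-sided Wilcoxon tests with minimum group size 3 (smaller groups are
flagged NA rather than tested).

Gene-set overlap enrichment (e.g. IR-bearing genes vs NMD targets) is a
Pearson chi-squared on the 2×2 over an explicit universe — the universe
must be supplied, since enrichment is meaningless without it — without
Yates correction by default (flag available). Expression-shift tests for
IR-bearing gene sets are two-tailed paired t-tests on per-gene Z
differences, after removing genes with IR events in both directions
(`filter_bidirectional_ir_genes`).

`deg_call` is a plain log2-FC + Welch-t + BH caller used only on synthetic
expression matrices (it stands behind the DEG-threshold logic of the
analysis, with gates like FC ≥ 1.5 & FDR < 0.1 or FC ≥ 2 & FDR < 0.05 &
baseMean > 10); it makes no claim to model counts and is calibrated in the
test suite on data matching its Gaussian assumptions.

## The synthetic-data generator

The generator defines the package's standard study conditions and is the
basis of every property test:

* **Junction counts**: per event and sample, total ~ Poisson(depth),
  inclusion ~ Binomial(total, psi). Defaults: depth 200, 3 replicates per
  group. This is the simplest family matching the PSI estimator; real
  cohorts' count distributions are unknown, so the choice is a modeling
  stand-in, not an inference about any dataset.
* **Annotation/sequence**: each gene on its own scaffold, alternating
  exons and introns with canonical GT…AG boundaries, iid bases at the
  target GC (boundary bases perturb GC negligibly at realistic intron
  lengths). Not realistic genome content — no repeats, no codon structure,
  no branch points.
* **Motif planting**: concrete IUPAC realizations inserted at
  non-overlapping positions into motif-scrubbed backgrounds; insertions
  are rescanned and retried so recorded truth exactly equals a rescan.
* **Cohorts**: alteration calls iid per patient–gene (defaults amp 10%,
  del 10%, mut 2%); amp/del shift that gene's log2 expression ±δ (default
  δ = 2); survival is exponential proportional hazards with log hazard
  `hazard_coef` per SD of the standardized composite signature score
  (default log 3), and uniform administrative censoring whose horizon is
  solved numerically for the target censored fraction (default 30%).
  Replicate noise in expression simulations is SD 0.3 log2 units, typical
  replicate variability for expression data.

What passing tests show is therefore parameter recovery *under these
models* — binomial counting noise, Gaussian expression noise, proportional
hazards, independent alterations. They do not show robustness to
overdispersion, batch effects, dependent alterations, isoform-level
ambiguity, or alignment artifacts, all of which real cohorts have.

Determinism: every generator takes a seed and restores the RNG state
(`withr::with_seed`), so identical seeds give byte-identical outputs after
serialization; the orchestrator threads one seed through all stages.

## Problem sizes

The bundled smoke scenario uses 200 events and 40 patients. The
property-test conditions are 500–2000 events, cohorts of 100–500 patients,
100 simulation replicates for power/calibration claims, 10,000
permutations for the log-rank permutation comparison, and exhaustive
enumeration for the Fisher (all 2×2 tables with n ≤ 20) and BH (1000
random vectors) oracles — sizes at which the whole suite runs in a few
minutes on a single CPU.

## Known limitations

* The differential caller works on junction counts for pre-defined events;
  it does not discover events or model read-level ambiguity.
* The maximum-entropy model ships no pretrained human parameters; scores
  are only comparable across models trained on the same window sets.
* The binding score treats motif occurrence as binary evidence per
  position; no affinity or PWM weighting.
* Best-cutoff p-values are anti-conservative by construction; use the
  permutation adjustment for inference.
* `deg_call` is not a count-model DEG method and should not be applied to
  raw RNA-seq counts.
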