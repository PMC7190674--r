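# splicescape

Dysregulated pre-mRNA splicing is a hallmark of aggressive prostate cancer:
as tumors progress toward castration resistance, the splicing landscape
shifts, intron retention rises, and the expression and copy-number state of
splicing-regulatory genes (SRGs) becomes prognostic. `splicescape` packages
the computational backbone of this kind of cohort study — from junction
counts to survival stratification — as tested, reusable R functions, with a
synthetic-cohort simulator so that every stage can be validated against
planted ground truth without any external downloads.

It is aimed at computational biologists who want the analysis layer of a
splicing-dysregulation study (not read alignment or event discovery, which
upstream tools such as rMATS/SUPPA provide) as a transparent, auditable
implementation.

## What it computes

**PSI and differential splicing.** For an event with inclusion count *I*,
skipping count *S* and effective lengths *l_I*, *l_S*:

    psi = (I/l_I) / (I/l_I + S/l_S)

Group differences are tested with a binomial likelihood-ratio test on pooled
counts (1 df), with Benjamini–Hochberg FDR control; a differentially spliced
event (DSE) passes |ΔPSI| > 0.1 and q < 0.1. Events cover the five canonical
types: SE, A5, A3, MX, IR.

**The intron-retention "splicing code".** Retained vs constitutive introns
(the n = 300 events nearest the center of the ΔPSI-sorted list at ΔPSI = 0)
are compared on length, GC content, and donor/acceptor splice-site strength.
Strength is scored in bits, `log2(P_signal(w) / P_background(w))`, under a
retrainable maximum-entropy model over 9-mer donor windows (3 exonic + 6
intronic bases) and 21-mer acceptor windows (20 intronic + 1 exonic base),
fitted by iterative proportional fitting to positional (order 0) or
positional + adjacent-pair (order 1) marginal constraints. Wilcoxon
rank-sum tests compare groups.

**RBP binding scores.** Each RNA-binding-protein IUPAC consensus motif gets
a binding frequency *f* (fraction of sequences with ≥ 1 match), a mean
appearance count *c̄* over matching sequences, and a binding score
*B = f · c̄*; factors with *f* > 0.70 are ranked by *B* and the top 20
shortlisted.

**Signatures and survival.** Expression is standardized as Z-scores against
a reference sample set; a signature score is the sum of member-gene
Z-scores. Shipped signatures: the 20-gene AR activity score (fractionated
at Z ≥ 7 / ≤ −7) and the 13-gene unfavorable and favorable SRG signatures.
Cohorts are split at the median or at the cutoff minimizing the log-rank
p-value (with an optional permutation adjustment, since minimal-p selection
inflates type-I error), and Kaplan–Meier curves determine whether a
signature is unfavorable.

**SRG genomic alterations.** Per-gene and cumulative alteration
frequencies, top-altered rankings, one-sided Fisher co-occurrence tests,
CNV–expression association, and Gleason-grade association.

**Synthetic cohorts.** `sim_config()` + the `simulate_*`/`generate_*`/
`plant_motifs()` family produce annotations (GTF/FASTA), junction counts
(Binomial inclusion given Poisson totals), motif-bearing sequences and
patient cohorts (CNV→expression shifts, exponential proportional-hazards
survival) with a recorded truth set.

## Worked example

The bundled smoke scenario simulates 200 events (20 with a planted
ΔPSI = 0.3) and a 40-patient cohort whose hazard follows the unfavorable
SRG signature, then runs the full pipeline:

```r
library(splicescape)
cfg <- validate_config(system.file("extdata", "smoke.yaml", package = "splicescape"))
run_pipeline(cfg)
#> splicescape run 'smoke' (seed 1)
#>   simulate  n_events=200  n_samples=6  n_patients=40
#>   quantify  n_tested=200  n_called=20  by_type=20
#>   signature n_samples=40  n_genes=13  score_range=-5.652, 5.530
#>   survival  split=median  p=0.0009601  direction=unfavorable
```

All 20 planted DSEs are recovered with no false calls at the ΔPSI > 0.1,
q < 0.1 gates; the signature's median split separates survival
(log-rank p ≈ 1e-3) and the direction is correctly labeled unfavorable
(high score → worse survival). `recovery_suite(cfg)` tabulates every
planted-vs-recovered parameter with its tolerance and verdict.

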