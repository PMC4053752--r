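---
title: "Methods: classifying non-frameshifting micro-indels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying non-frameshifting micro-indels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfsindel)
```

## The model

`nfsindel` frames micro-indel pathogenicity as supervised binary
classification. Each non-frameshifting (NFS) coding indel — net length a
multiple of 3, all affected bases inside the translated CDS, stop codon
untouched — is represented by 58 features summarising the local sequence
and predicted-structure context of the indel site, and a soft-margin SVM
with a radial-basis-function kernel separates disease from neutral
records. The disease class is positive throughout.

The central modelling assumption is locality: the phenotypic impact of
an NFS-indel is carried by the properties of the residues and bases at
and around the indel site (conservation, structural order, burial,
alignment depth), plus a single global term — the change the indel
induces in the whole-protein profile match score. The window
conventions make locality explicit:

* deletion of residues `first..last`: window
  `max(1, first − n_window) .. min(L, last + n_window)`, i.e.
  `n_del + 2 n_window` positions before clipping;
* insertion between residues `i` and `i+1`: window
  `max(1, i − n_window) .. min(L, i + 1 + n_window)`, i.e.
  `2 + 2 n_window` positions.

Windows are truncated at sequence boundaries, never padded: padding
would inject fabricated values into min/ave/max summaries. The same
half-window `n_window` is applied to every windowed feature, nucleotide
or residue level, so the model has a single locality parameter. For
insertions, the nucleotide-level window is anchored on the two bases
flanking the insertion point in transcript orientation, matching the
orientation used for splice distances.

## Coordinate conventions

VCF alleles are 1-based and anchored; internally the indel is normalised
to its affected bases without the anchor (deleted bases, or the two
flanking bases of an insertion point). GTF intervals are 1-based
inclusive. The CDS convention includes the stop codon, so a valid
transcript satisfies `cds_length = 3 (protein_len + 1)`; the protein
sequence excludes the stop. Indels are used exactly as given — no
left-alignment is performed, because normalisation changes the window
content; a validator warns when REF/ALT do not share their anchor base.

Out-of-phase deletions (net length divisible by 3 but not aligned to
codon boundaries) delete `n_del = net_len / 3` residues while touching
`n_del + 1` codons. The residue span recorded is the span of touched
codons, and the junction residue created by the splice of the two
partial codons is ignored for feature windows. This is the conservative
reading of "deleted residues" when phase handling is otherwise
unspecified; the chosen span convention is recorded in the mapped
output so downstream consumers can detect it.

## The ΔS feature

The indel-induced change to the evolutionary match score is computed by
global Viterbi alignment of a protein sequence to the wild-type profile:
match emissions score `log2(e_j(a) / q_a)` against the background `q`,
insert states emit at background (log-odds 0), and every transition on
the path contributes `log2` of its probability. The begin state behaves
as a virtual match column 0 with fixed begin transitions (1/3 each over
MM/MI/MD; 1/2 over IM/II and DM/DD); the final transition into the end
is unscored. ΔS is the mutant score minus the wild-type score, so
`ΔS = 0` exactly for the identity, and deleting the residue of a
high-information column is strongly negative. Tie-breaking inside the
dynamic programme does not affect the score, which is the only quantity
used. The implementation (Rcpp) is verified against exhaustive
enumeration of all alignment paths on profiles of up to 5 columns.

Production profile-profile aligners score two HMMs against each other
with co-emission sums; this package scores sequence against profile,
which preserves the feature's semantics — the perturbation of the match
score by the indel — with a mechanism that is fully specified and
testable against a brute-force oracle.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `n_window` | 2 | residues / bases | half-window; grid searches 0–7 |
| `C` | 1 | — | SVM soft-margin cost; grid log2 −5..15, step 2 |
| `gamma` | 1/p | — | RBF width; grid log2 −15..3, step 2 |
| `k` | 10 | folds | cross-validation |
| identity threshold | 35 | % | redundancy clustering cutoff |
| MAF threshold | 0.02 | fraction | optional neutral-record filter (strict `<`) |

The grid is deliberately coarse (steps of 2 in log2) — 11 × 10 × 8 = 880
points — because cross-validated MCC varies slowly over C and gamma in
this problem; the search returns the argmax with ties broken toward the
lexicographically smallest `(n_window, log2C, log2gamma)`.

Fold partitions are simple random draws (not stratified), seeded, with
bounded redraws if a training fold loses a class. Cross-validated
metrics are pooled over folds (every record contributes exactly one
out-of-fold prediction) rather than averaged per fold; pooling uses all
the information in one confusion table and avoids per-fold small-sample
noise. Greedy feature selection holds a single fold partition fixed
across all steps, so MCC differences between candidate subsets reflect
the features rather than partition noise; selection ties break toward
canonical feature order. The trace's MCC sequence is strictly
increasing by construction, and selection halts as soon as no remaining
feature improves it.

Probability calibration is a Platt-style sigmoid
`p = 1 / (1 + exp(−(A·d + B)))` fitted by binomial GLM on
cross-validated decision values (internally cross-validated at training
time; pooled out-of-fold values inside `kfold_cv()`). Models serialize
to versioned plain-text JSON with 17 significant digits, which
round-trips IEEE doubles exactly, so `load_model(save_model(m))`
reproduces predictions bit for bit.

## Numerical and edge-case decisions

* **MCC with a zero denominator factor is 0** (degenerate prediction or
  label sets; the common convention).
* **Precision/recall with a zero denominator raise errors** rather than
  returning NaN — a degenerate prediction set is a pipeline bug, not a
  statistic.
* **ROC ties** are collapsed to single thresholds; trapezoid AUC then
  equals the Mann–Whitney normalisation with half-credit for ties
  (verified to 1e-12).
* **MAF bins**: 20 fixed bins of width 0.05; the final bin is closed at
  1.0 so `maf = 1` is binned; empty bins are excluded from the Pearson
  correlation and the least-squares fit.
* **Relative entropy** uses the natural logarithm (the reference
  formulation), BLOSUM62 background frequencies as `q`, and profile
  emissions as `p`; terms with `p_i = 0` contribute 0. Strata
  (`high`/`median`/`low`) split at RE ≥ 150 and RE < 70; for deletions
  RE is averaged over the deleted residues, for insertions over the two
  flanking residues.
* **Pairwise identity** for redundancy reduction is global alignment
  with BLOSUM62, gap open 11 / extend 1, identical columns divided by
  full alignment length; clustering is single-linkage on the
  `identity > threshold` graph, with the longest member (ties:
  lexicographic id) as representative. Exact reproduction of
  coverage-weighted clustering tools is not attempted; the parameters
  are declared and fixed instead.
* **Constant features** are dropped with a warning at standardization
  time; test data are always transformed with training-set parameters.

## What the synthetic generator emulates

`generate_cohort()` writes a complete on-disk cohort — VCF, GTF, protein
FASTA, per-base bedGraph conservation, per-residue structure TSVs,
per-protein profile TSVs, and a truth table — whose class-conditional
structure mirrors the qualitative findings for real NFS-indels. A latent
risk score `z` (disease `N(1.2, 0.6²)`, neutral `N(−1.2, 0.6²)`) drives
the site-level draws:

* disorder ~ Beta with mean `plogis(−z)` and concentration 8 (disease
  sites structured, neutral sites disordered; Beta respects \[0, 1\]);
* ASA ~ `N(50 − 15 z, 15²)` Å², truncated at 0 (disease sites buried);
* per-base conservation ~ `N(0.5 + 1.2 z, 0.8²)` on a phyloP-like scale;
* `n_eff` of match states ~ `N(7 + 2 z, 1.5²)` clamped at 0.5; gap
  transition rates decrease with `z`; profile emissions sharpen around
  the wild-type residue as `z` grows (Dirichlet with a
  `2·exp(0.8 z)` spike).

Neutral minor allele frequencies mix an independent `U(0, 0.5)` draw
with the monotone-decreasing transform `0.5·plogis(−2z)` at weight
`maf_coupling = 0.6` — the simplest mechanism producing the negative
MAF–risk trend. Indel residue lengths are short-biased (weights
0.6/0.3/0.1 for 1/2/3 residues), reflecting that most micro-indels span
one or two residues; deletions and insertions are codon-aligned, placed
away from termini, splice junctions and each other so that every site's
window carries its own class-conditional draws. Transcripts have two
exons on both strands, with deterministic codons per residue, so the
VCF/GTF/FASTA round trip is exactly checkable.

What the generator does **not** emulate: real gene structures and
mutation spectra, out-of-phase indels, linkage between neighbouring
sites, sequencing artefacts, or realistic class overlap — synthetic
cohorts are more separable than real data (cross-validated MCC near 1 at
the defaults). Passing tests therefore demonstrate that the pipeline's
mechanics are correct and that known signals are recovered at their
analytic strength; they do not certify real-data accuracy.

`simulate_feature_cohort()` is the feature-level companion used for
statistical validation at large n: one Gaussian informative feature with
known analytic AUC `Φ(|μ₁ − μ₀| / √(σ₀² + σ₁²))`, optional pure-noise
features, and the same MAF coupling. The validation suite checks, at
the sizes stated, that 10-fold cross-validated AUC recovers the analytic
value within ±0.05 at n = 2,000; that greedy selection picks the planted
feature first among 20 noise features in ≥ 9/10 seeds at n = 1,000; that
a null cohort yields |MCC| < 0.08 at n = 1,000; and that the MAF bin
correlation is negative in ≥ 95% of seeds at n_neutral = 2,000. The
end-to-end pipeline checks use file-backed cohorts of 80–300 indels on
tens of proteins of 80–200 residues — large enough for stable
statistics, small enough to keep the default validation run fast.

## Limitations

* One transcript per indel is required input; consequence arbitration
  across overlapping transcripts is out of scope.
* The ΔS mechanism is sequence-to-profile, not profile-profile (above).
* External predictors (disorder, secondary structure, ASA, conservation,
  profiles) are consumed as annotation tracks; the package does not run
  them.
* bigWig conservation tracks are not parsed (bedGraph / fixed-step
  wiggle only).
* Insertions adjacent to or inside the stop codon region are classified
  as stop-overlapping and excluded from mapping, a conservative edge
  convention.
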