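---
title: "Methods: paralog-based complementation analysis of variant pathogenicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paralog-based complementation analysis of variant pathogenicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paracomp)
```

## The problem

Most human disease genes have no yeast ortholog, so orthology-based
functional complementation assays — in which a human gene rescues a yeast
mutant and variant pathogenicity is read out as failure to rescue — cover
only a small slice of the clinically interesting genome. Paralogs (here,
operationally, any human–yeast homolog pair *not* annotated as orthologous)
can expand that coverage. `paracomp` implements the computational side of
building and evaluating such assays: choosing candidate human–yeast pairs,
relating complementation to sequence identity, scoring spot-dilution
assays into a semi-quantitative failure-to-complement (FC) score, and
benchmarking that score against computational predictors on a panel of
annotated variants.

## Pair selection

A pair enters the search space when five conditions hold simultaneously:
the pair is not annotated as orthologous; the human gene is a disease gene
(an HGMD-"DM"-style flag consumed as input); a human expression clone is
available; the yeast gene is essential and has a temperature-sensitive
(TS) allele; and every protein domain of the yeast protein is "covered" by
the human protein. Domain presence is called from Pfam-style hits at the
conventional E ≤ 0.001 cutoff, and coverage is **accession-set
containment**: copy number and domain position are ignored, because the
available evidence about coverage is accession lists, and because a repeat
domain present once in the human protein still provides the fold. The
orthology flag is an input column; re-deriving seed-ortholog logic from
proteome BLAST is out of scope.

## Alignment and percent identity

Aligned-region analyses use an optimal global (Needleman–Wunsch)
alignment under an affine gap model. Defaults are the ubiquitous protein
settings — BLOSUM62, gap open 11, gap extend 1 — with a gap of length
$k$ costing $11 + (k-1)\cdot 1$. Traceback ties are broken
deterministically (residue pairing, then gap in the yeast sequence, then
gap in the human sequence) so results are reproducible to the byte.
The Rcpp implementation is validated in the test suite against exhaustive
enumeration of all alignments for short sequences.

Percent identity (PID) is reported under four denominators, because the
choice matters when aligned lengths differ:

* `aligned_columns` — identical residues over gap-free columns. This is
  the primary definition ("percentage of aligned positions with identical
  residues").
* `alignment_length` — identities over all columns; substantially lower
  when one protein is much shorter, which is exactly the definition known
  to behave differently in class-comparison analyses.
* `shorter_sequence`, `mean_length` — identities over the shorter input
  or the rounded mean input length.

A variant position is *in the aligned region* when its alignment column
pairs it with a yeast residue. A residue opposite a gap has no homologous
counterpart, so the default is gap-free-column membership; a
first-to-last-aligned-column "span" definition is exposed as an option for
users who prefer the looser region. Note that the aligned-region flags in
the packaged benchmark table are consumed as published data, never
recomputed.

## The spot assay model and FC scoring

The assay grows 10-fold dilution series (default 5 spots) of strains
carrying the test plasmid, the wild-type human gene (positive control) and
GFP (negative control) across a temperature panel (24–38 °C). The readout
per temperature is the number of spots with visible growth — a
deliberately discrete quantity, since plate photographs are interpreted
qualitatively and any monotone readout is faithful; integers make tests
exact.

At each temperature let $g = \text{test} - \text{GFP}$ and
$G = \text{wt} - \text{GFP}$ be spots rescued over background. The call
is: wild-type-like (score 0) if $g \ge G$; reduced (0.6) if
$G/2 \le g < G$; severely reduced (0.8) if $0 < g < G/2$; no
complementation (1) if $g \le 0$. The four score levels are the published
convention; the cutoffs between them ($G/2$ and $G$) are this package's
operationalisation — the published account defines the levels, not the
boundaries — and are documented here for that reason. Temperatures where
GFP grows at least as well as the wild-type control are permissive (the
TS allele is functional, there is no selective signal) and are excluded.

The FC score is the mean of per-temperature scores over evaluable
temperatures, rounded to one decimal (half-up, so means land on the 0.1
grid deterministically). Mean aggregation is the only simple rule
consistent with observed panel scores of 0.2 and 0.4 despite the level
set being $\{0, 0.6, 0.8, 1\}$. By construction the wild-type control
scores 0 and GFP scores 1 at every panel. A variant is called deleterious
when FC is strictly greater than 0.5.

Screening follows the two-replicates-then-confirm design: two initial
replicates, complementation in at least one makes a candidate, and only
candidates passing an independent third assay are confirmed; a candidate
failing confirmation is demoted to a negative outcome.

## Benchmarking decisions

* **Decision rules.** FC and PolyPhen-2 are damaging when score > 0.5
  (strict); PROVEAN when score ≤ −2.5. The PolyPhen-2 and PROVEAN rules
  are not stated anywhere in the published material; they were inferred
  as the unique thresholds exactly concordant with all 35 published
  Damaging/Neutral calls in the panel (e.g. PROVEAN −2.51 → Damaging,
  −2.35 → Neutral; PolyPhen-2 0.517 → Damaging, 0.343 → Neutral), and
  that concordance is asserted in the test suite.
* **Intervals.** Precision confidence intervals are exact
  Clopper–Pearson, computed through `stats::binom.test()`. This choice
  reproduces the published interval 58%–96% for 15/18 and approximately
  51%–90% for 15/20; the interval method was otherwise unnamed.
* **PR curves.** Points are per distinct score value with tie blocks
  processed atomically, making every curve statistic order-invariant.
  Areas use the Davis–Goadrich nonlinear interpolation (precision is not
  linear in recall between achievable confusion states); a step-function
  integration is available for cross-checks, and the analytic segment
  integration is validated against fine-grid numerics in the tests.
  REC90 is the maximum recall along the interpolated curve with
  precision ≥ 0.9.
* **AUROC** is the tie-aware rank statistic (probability a random
  positive outscores a random negative, ties counting one half).
* **AUPRC_norm** is AUPRC divided by prevalence, used when comparing
  strata whose priors differ (aligned vs non-aligned variants).
* **Calibration.** "Precision within held-out training groups" is a
  two-sentence published recipe with several readings. The implemented
  one: variants are split into `n_groups` seeded random folds; a
  variant's calibrated score is the precision among the other folds'
  variants scoring at least as damaging; the fold's mapping is then
  isotonically smoothed (`stats::isoreg`) so calibrated scores never
  decrease with damaging rank. Folds whose training complement is
  single-class are merged with a neighbour, with a warning.
* **Combination.** min, max, mean and the weighted means
  $\alpha\,\mathrm{FC} + (1-\alpha)\,\mathrm{PPH2}$ with
  $\alpha = 0.9, 0.8, 0.7, 0.6$ (named w1–w4).
* **Hypothesis tests** go through `stats::wilcox.test` (exact for small
  tie-free samples, tie-corrected normal approximation with continuity
  correction otherwise) and `stats::fisher.test`; both are cross-checked
  against enumeration oracles in the test suite.

## Published values this panel does and does not reproduce

Applying the rules above to the packaged 35-variant table reproduces: all
105 Damaging/Neutral calls; the PolyPhen-2 MCC 0.48 and PROVEAN MCC 0.37;
FC detecting 15/19 (79%) disease and 4/16 (25%) non-disease variants;
100% precision at 42% recall for FC at the 0.7 threshold; 75% precision
at 79% recall for PolyPhen-2 at 0.5; and the PolyPhen-2 AUPRC (0.76).

Several published summary values are **not** recoverable from the panel
under the stated rules, and this package deliberately does not assert
them: the FC-row summary statistics (MCC 0.59, REC90 0.78) and the
83%-precision figure — FC > 0.5 on all 35 rows gives precision 15/19 ≈
79% and MCC ≈ 0.54, whereas 83% equals 15/18, consistent with one
predicted-positive variant having been excluded by an unstated rule — and
the published AUROC column (0.55/0.52/0.55), which no standard rank-based
AUROC on these scores yields. Values combining this panel with an earlier
ortholog-based panel require data not shipped here and are likewise out
of scope. The machinery that would compute all of these is exercised by
structural invariants instead (label-flip antisymmetry of MCC,
combination bounds, stratified summaries).

## The synthetic generator

`simulate_gene_universe()`, `simulate_assay()` and
`simulate_variant_table()` generate every input the pipeline consumes,
with planted ground truth emitted alongside (and never read by pipeline
stages). Defaults are the study conditions:

* variant panels are ~54% disease-associated (19 of 35), with 79% of
  disease and 25% of benign variants carrying high latent damage — the
  observed deleterious-call rates;
* high damage is uniform on [0.7, 1] and low damage on [0, 0.1], so that
  noise-free assays land cleanly in the wild-type-like region (FC ≤ 0.5)
  or the damaging region (FC > 0.5);
* the assay grows 5-spot series over the 24–38 °C panel with a GFP
  baseline of 1 spot and wild-type rescue of 4 spots at restrictive
  temperatures; each spot's visibility flips with probability 0.02, a
  realistic plate-to-plate inconsistency level;
* pair PIDs are normal (sd 10) around 25% for non-complementing pairs,
  shifted up 7 points for complementing pairs — chosen once so that a 30%
  PID cutoff captures ~60% of complementing pairs while ~30% of
  non-complementing pairs also exceed it, the published operating point
  of PID as an informative-but-imperfect predictor;
* computational scores are noisy monotone transforms of latent damage:
  logit-scale Gaussian noise (sd 1) for the PolyPhen-2-like score, linear
  Gaussian noise (sd 1.5) around $0.5 - 8 \cdot \mathrm{damage}$ for the
  PROVEAN-like score. These noise models are invented — only empirical
  score columns exist to anchor them — and are configuration-exposed.

Batch scoring of simulated panels uses a vectorised implementation of the
identical growth-and-category arithmetic; its exact agreement with the
per-variant assay path is asserted at zero noise in the test suite.

What the generator does **not** emulate: real protein sequences (the
alignment module is exercised on random and hand-built sequences),
image-based colony readouts, correlated errors between computational
predictors, gene-level clustering of variants, or allele-frequency
structure. Passing simulation tests therefore demonstrate correctness of
the pipeline's arithmetic and its statistical behaviour under the planted
model, not predictive performance on new laboratory data.

Problem sizes used by the test suite were chosen as the smallest that
make the stochastic checks stable: damaging-fraction recovery uses
1000-variant panels over 100 seeds (tolerance ±0.04), PID-shift power
uses 200-pair universes over 200 seeds, and enumeration oracles run on
sequences of length ≤ 7 and samples of size ≤ 12, where exhaustive
computation is exact.

## Numerical conventions and degenerate inputs

Protein coordinates are 1-based and inclusive throughout. FC rounding is
half-up to one decimal. Classification thresholds are strict or inclusive
exactly as stated per system. Curves require both classes; MCC requires
all four margins positive; PID requires a positive denominator; an assay
with no evaluable temperature is an error rather than a silent zero.
Missing scores exclude a variant from the affected analysis with a
warning and a count, so partial score columns are supported. All
randomness is seed-controlled (`withr::with_seed`), and generator output
is identical across runs given the seed.

## Known limitations

The category cutoffs of the assay model and the calibration reading are
documented conventions, not published facts; both are configurable. The
benchmark panel is small (35 variants, 7 genes), so interval estimates
are wide and gene-level dependence between variants is ignored, as in the
original analysis. Orthology annotation, domain calls and computational
scores are consumed as inputs; the package neither re-runs HMM scans nor
the predictors themselves.
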