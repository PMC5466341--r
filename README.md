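# paracomp

Paralog-based yeast complementation analysis of human variant
pathogenicity.

Functional complementation — expressing a human gene in a yeast strain
whose cognate gene is disabled and asking whether growth is rescued — is
one of the most direct ways to test whether a human missense variant
damages protein function. Classically these assays require a human–yeast
*ortholog* pair, which exists for only a few percent of disease genes.
`paracomp` implements the computational pipeline for extending such
assays to *paralogs* (homologs not annotated as orthologous): selecting
candidate human–yeast pairs, relating complementation to sequence
identity, turning spot-dilution growth assays into a semi-quantitative
**failure-to-complement (FC) score**, and benchmarking FC against
computational predictors (PolyPhen-2, PROVEAN) on an annotated variant
panel. It is aimed at groups building complementation assays and at
anyone evaluating variant-effect predictors on small labelled panels.

## What it computes

* **Pair selection.** A human–yeast pair is retained when it is not an
  annotated ortholog, the human gene is a disease gene with an available
  clone, the yeast gene is essential with a temperature-sensitive allele,
  and every significant Pfam domain (E ≤ 0.001) of the yeast protein is
  covered by the human protein.
* **Alignment / PID.** Optimal global alignment (BLOSUM62, affine gaps
  11/1) with four percent-identity definitions and classification of
  variant positions as inside or outside the aligned region.
* **FC scoring.** Per-temperature calls from rescued-spot arithmetic
  (levels 0, 0.6, 0.8, 1), averaged over evaluable temperatures;
  a variant is deleterious when FC > 0.5.
* **Benchmarking.** Confusion matrices and the Matthews correlation
  coefficient

  $$\mathrm{MCC} = \frac{tp\cdot tn - fp\cdot fn}
  {\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}},$$

  precision–recall curves with Davis–Goadrich interpolation (AUPRC,
  REC90, prevalence-normalised AUPRC), rank-based AUROC, exact
  Clopper–Pearson intervals, cross-validated precision calibration and
  weighted score combination, Wilcoxon and Fisher tests.
* **Synthetic data.** A fully seeded generator for gene universes, spot
  assays and scored variant panels with planted ground truth, so the
  whole pipeline is testable offline.

The package ships the 35-variant benchmark panel (19 disease-associated,
16 not, across 7 genes) as a checksummed fixture, `table2_variants()`.

## Worked example

```r
library(paracomp)

v <- table2_variants()
dplyr::count(v, disease_associated)
#>   disease_associated     n
#> 1 FALSE                 16
#> 2 TRUE                  19

perf_summary(v, "pph2")
#> Performance of pph2 on 35 variants (prevalence 0.54)
#>   system     n prevalence    tp    fp    fn    tn   mcc auprc auroc rec90
#> 1 pph2      35      0.543    15     5     4    11 0.480 0.763 0.755     0
```

PolyPhen-2 at its 0.5 threshold calls 20 variants damaging, 15 of them
truly disease-associated (precision 75%, recall 15/19 ≈ 79%, MCC 0.48).
The FC score at the stricter 0.7 threshold trades recall for precision:

```r
precision_recall_at(v, "fc", 0.7)
#>   threshold precision recall    tp    fp    fn    tn
#> 1       0.7         1  0.421     8     0    11    16
```

all 8 predicted-deleterious variants are disease-associated (100%
precision at 42% recall). Exact binomial uncertainty for a precision of
15/18:

```r
clopper_pearson(15, 18)
#>   estimate lower upper
#> 1    0.833 0.586 0.964
```

End-to-end runs (simulate → select pairs → benchmark) go through
`run_pipeline(run_config(...))`, which writes TSV/JSON artifacts and a
manifest with a configuration hash; identical configurations reproduce
identical outputs.

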