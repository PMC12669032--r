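# XenoScreen

High-throughput screens of chemicals against bacterial monocultures produce
thousands of OD600 growth curves per strain; deciding which chemical–strain
pairs are genuine inhibitory interactions, how potent they are, and which
genes modulate them requires a consistent statistical pipeline. XenoScreen
implements that pipeline end to end for chemical-pollutant × gut-bacteria
screening studies and their follow-up experiments:

- **Growth metrics** — baseline correction (per-curve minimum set to 0),
  trapezoidal area under the growth curve (AUC), logistic fits
  *N(t) = K / (1 + ((K − N0)/N0)·e^(−rt))*, and population doublings
  *G = log2(OD_final/OD_initial)*.
- **Monoculture hit calling** — plate normalization by the vehicle-control
  (DMSO) median or by row/column medians (edge correction); per-well
  *z = (raw AUC − control median) / control s.d.* converted to a one-sided
  inhibition p-value; Benjamini–Hochberg correction across the compound
  library; a replicate is significant when *P*adj < 0.05 with a >20 %
  reduction in normalized AUC, and a compound × strain pair is a hit when at
  least two of three replicates are significant. MICs are the lowest tested
  concentration with normalized AUC (or blanked 24-h OD) below 0.1.
- **Arrayed mutant screens** — plate-median-relative AUCs (rAUC), the
  treatment/control ratio nrAUC, Welch tests with BH correction, and the
  *P* < 0.05 with >20 % effect hit rule.
- **Pooled transposon (TnBarSeq) fitness** — trimmed-total-read-count (TTR)
  normalization, masking of insertion sites outside the central 80 % of each
  coding region, a 20,000-permutation resampling test per gene (exhaustive
  enumeration for small designs), log2 fold changes with pseudocount 1,
  doublings-bias correction, BH correction, the |log2FC| > 0.25 and
  *P*adj < 0.05 hit rule, and Fisher-exact term enrichment.
- **Chemical space** — Tanimoto/Jaccard similarity on fingerprint bit sets,
  closest-match library coverage, threshold counts, two-sample KS coverage
  comparisons, and Jaccard distance matrices of inhibition profiles.
- **Activity prediction** — species-specific random-forest classifiers
  (500 trees, √p feature sampling, unlimited depth) over molecular features,
  repeated stratified 8:2 splits (20× cross-validation), probability
  thresholding at the training-set hit frequency, balanced accuracy and
  average precision, and shuffled-label null distributions.
- **Community and bioaccumulation arithmetic** — relative and OD-scaled
  absolute abundances, treated/control abundance ratios, calibration-line
  quantification, and supernatant-depletion statistics.
- **Synthetic data** — seeded generators for every input above with known
  ground truth (planted hits, MICs, gene fitness effects, structure–activity
  rules, community sensitivity shifts), so every stage is verifiable without
  any laboratory data.

Data containers follow Bioconductor conventions: `GrowthCurveSet`,
`PlateMap`, `HitMatrix`, `FingerprintSet` and `ToxDataset` are S4 classes
with validity checks and accessors, and insertion count tables are a
`SummarizedExperiment` subclass (`InsertionExperiment`).

## Worked example

Simulate a one-plate screen of 88 compounds against four strains with 10 %
planted inhibitory interactions, then run the full hit-calling pipeline:

```r
library(XenoScreen)

sim <- simScreen(n_compounds = 88, n_strains = 4, hit_fraction = 0.1, seed = 42)
res <- screenCallHits(sim$curves, sim$maps, m = 1076)
res$hits
#> HitMatrix: 88 compounds x 4 strains; 22 hits

summarizeHits(res$hits, n_species = 4)
#> $n_interactions      22     # significant compound-strain pairs
#> $n_active_compounds  19     # compounds inhibiting >= 1 strain
#> $n_broad_compounds    3     # compounds hitting > 1/3 of strains
#> $n_strong_compounds   1     # >= 1 hit with > 90% growth reduction

head(res$replicateStats[res$replicateStats$sig,
     c("compound_id", "strain_id", "replicate", "norm_auc", "z", "p_adj")])
#>      compound_id strain_id replicate  norm_auc         z        p_adj
#> D04     cmpd0025  strain01         1 0.3502856 -11.79100 7.789170e-30
#> G05     cmpd0035  strain01         1 0.3753148 -11.33677 1.160293e-27
#> A08     cmpd0053  strain01         1 0.2071836 -14.38801 1.655347e-44
```

Each row is one replicate of one compound on one strain: `norm_auc` is
growth as a fraction of the plate's DMSO-control median (0.35 = 65 %
inhibition), `z` scores the raw AUC against the control distribution, and
`p_adj` is the library-wide FDR-adjusted inhibition p-value. The
`HitMatrix` aggregates these by the two-of-three replicate-concordance rule.

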