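---
title: "Statistical methods behind XenoScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind XenoScreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(XenoScreen)
```

XenoScreen analyses high-throughput chemical–bacteria growth screens and
their genetic follow-ups. This vignette documents the statistical models,
the tunable parameters, the numerical conventions, and the design choices
made where the methodology left genuine freedom. It also explains precisely
what the synthetic-data generators emulate, and therefore what a passing
test suite does and does not demonstrate about real data.

## Growth curves to fitness proxies

A well's fitness proxy is the area under its OD600-vs-time curve after the
curve's minimum has been shifted to zero. `baselineCorrect()` performs the
min-to-zero shift per curve (idempotent; shape-preserving);
`aucTrapezoid()` integrates by the trapezoid rule **on the observed time
stamps**, with no resampling or smoothing. On hourly data the trapezoid
rule is exact for piecewise-linear signals and linear in the OD values,
which makes the downstream normalizations (all ratios of AUCs) insensitive
to the time grid. Whether AUC should be computed on further blank-corrected
OD beyond the min-to-zero shift is not prescribed anywhere; only the
min-to-zero shift is applied.

`fitLogistic()` fits the three-parameter logistic
$N(t) = K/(1 + ((K - N_0)/N_0)\,e^{-rt})$ by Levenberg–Marquardt least
squares (via minpack.lm), the standard model for microplate growth curves.
Starting values are deterministic: $N_0$ = first OD reading, $K$ = maximum
OD, $r$ = 4 divided by the time of half-maximum. A curve whose dynamic
range is below `dynamic_floor` (default 0.02 OD, roughly twice reader
noise) or whose fit fails is returned with `converged = FALSE` rather than
an error, because non-growing wells are data, not failures.

`doublings()` computes $G = \log_2(\max(OD_f, \text{floor}) /
\max(OD_i, \text{floor}))$, clamped at zero, on absolute (uncorrected) OD.
The floor (default 0.01 OD) guards against taking logarithms of blank-level
readings; the exact floor used by any particular instrument pipeline is a
free parameter, and results are insensitive to it whenever inocula are
above it.

## Monoculture hit calling

Two normalizations are supported, matching the two plate designs such
screens use:

- **Vehicle-control normalization** (`normalizeDmso`): each well's AUC is
  divided by the median AUC of the plate's DMSO wells, so 1 means
  control-level growth. Requires at least 3 control wells; a control median
  of zero rejects the plate.
- **Edge correction** (`normalizeEdge`): a multiplicative two-way
  correction, $\mathrm{norm}(r,c) = \mathrm{raw}(r,c) \cdot
  \tilde{m}_{\mathrm{plate}} / (\tilde{m}_{\mathrm{row}(r)} \cdot
  \tilde{m}_{\mathrm{col}(c)})$ with $\tilde m$ denoting medians over assay
  wells (dye and empty wells excluded). A uniform plate maps to 1
  everywhere, i.e. the output is on the same fraction-of-typical-growth
  scale as the DMSO normalization, which is what the downstream 20 %
  effect-size rule expects. Rows or columns with a zero median yield NA
  wells rather than infinities.

Significance is computed per replicate: $z = (\text{raw AUC} -
\text{control median})/\text{control s.d.}$ — note *raw* AUC against raw
control statistics, while the effect-size filter uses *normalized* AUC;
this separation is deliberate and follows the screen's stated formula. The
z-score is converted to a **one-sided lower-tail** normal p-value: the
screen calls inhibition only, so growth promotion is never significant
(`alternative = "two.sided"` is available). The control spread is the
sample standard deviation of the vehicle wells by default, with a MAD
option (`robust = TRUE`) for contaminated control sets.

BH correction runs across the full compound library within each
strain–replicate: `bhAdjust(p, m)` takes the library size as an explicit
denominator (e.g. `m = 1076`) because a single plate tests only a subset of
the library but the family of tests is the whole library. A replicate is
significant at `p_adj < 0.05` and normalized AUC `< 0.8` (normalized AUCs
are clamped at zero before the comparison, since edge correction can
produce small negatives); a compound inhibits a strain when **at least two
of three replicates** are significant. This concordance rule, combined with
the effect-size filter, is what suppresses the compound-level false-positive
rate far below the per-replicate 5 % FDR — the property the acceptance
suite verifies on null plates.

The MIC is the lowest tested concentration whose growth metric falls
strictly below 0.1 (i.e. >90 % inhibition), with **no monotonicity
repair**: a non-monotone dose series reports the lowest qualifying dose,
and a series that never qualifies is censored as "greater than the top
dose". Validation concordance counts a main-screen hit as confirmed when
the validation series shows a significant >20 % inhibition at any tested
dose at or below the main-screen dose; the exact confirmation rule behind
published concordance figures is not fully specified anywhere, so this
documented rule is the package's own choice.

## Arrayed mutant screens

Each plate's mutant AUCs are divided by the plate's median mutant AUC
(`computeRauc`), under the assumption that most mutants are phenotypically
neutral — the median is then an internal wild-type proxy and the output
median is exactly 1. Technical replicates are averaged first
(`arrayedScreenAnalysis`), and the biological replicates form the arms of a
two-sided Welch test per mutant; whether published analyses pooled
technical duplicates into the test arms or averaged them first is
ambiguous, and averaging-first is the choice here (with only technical
duplicates available the duplicates would form the arms — a documented
limitation). Hits use **raw** p < 0.05 together with a >20 % change in the
treatment/control ratio nrAUC, while the BH-adjusted p-value is reported
alongside for transparency. Mutants whose mean control rAUC is below 0.1
are excluded as failing growth in vehicle. Degenerate identical arms with
zero variance return p = 1.

## Pooled transposon fitness

Counts are normalized by the trimmed total read count: per sample, the mean
of nonzero site counts after discarding the top and bottom 5 % of nonzero
values, rescaled to the across-sample grand trimmed mean. Trimming makes
the size factors robust to single jackpot insertion sites. Sites outside
the central 80 % of a coding region (fractional offset
$f = (\mathrm{pos}-\mathrm{start})/(\mathrm{end}-\mathrm{start}+1)$ with
$0.1 \le f < 0.9$) are masked, because insertions in terminal gene segments
often fail to disrupt function.

The per-gene test is a permutation resampling test. The statistic is the
difference of per-arm means; the two-sided p-value is the fraction of label
permutations whose absolute statistic reaches the observed one, with the
observed arrangement included in both numerator and denominator (so p is
floored at 1/n\_perm and never zero). When the number of distinct
assignments is at most `n_perm` (default 20,000) the enumeration is
exhaustive and the p-value exactly deterministic; otherwise permutations
are sampled under the caller's seed, and for efficiency all genes sharing a
design reuse one permutation set — reuse affects no marginal p-value and
makes runs bit-reproducible.

A critical design point is the **observation unit**. In the full pipeline
(`tnseqFit`) the permuted observations are the normalized counts of each
retained site in each sample — the convention of established transposon
resampling tools — rather than per-sample gene totals. With typical designs
of two-to-three samples per arm, permuting whole samples cannot produce a
two-sided p below 2/C(n, n1) (0.1 for a 3-vs-3 design), which after FDR
correction across thousands of genes can never reach significance;
site-level observations restore resolution. The generic `resamplingTest()`
operates on whatever observation collections the caller passes, so both
conventions are available. Site-level permutation assumes observations
within a gene are exchangeable under the null; the synthetic generator
satisfies this (sites within a gene share their negative-binomial mean),
and the null calibration the acceptance suite checks (near-uniform
p-values) holds exactly in that regime. Real insertion data carry strong
per-site effects, which make site-level permutation p-values conservative —
a known property of this test family, and a limitation to keep in mind.

Fold changes are $\log_2((\bar{x}_{\mathrm{cond}} + 1)/(\bar{x}_{\mathrm{ctrl}}
+ 1))$ with pseudocount 1 to avoid infinities, computed from per-sample
gene totals. The doublings-bias correction rescales the fold change to the
control arm's doubling count, $\mathrm{lfc} \times G_{\mathrm{ctrl}} /
G_{\mathrm{cond}}$ — a per-doubling rescaling adopted as a documented
stand-in, since the exact form of the published correction script is not
reproduced in any methods text; nonpositive doublings skip the correction
with a flag. Hits require `p_adj < 0.05` and `|log2FC| > 0.25`. Term
enrichment is a one-sided (greater) Fisher exact test per term with BH
correction across terms.

## Chemical space

All similarity math operates on bit sets (`FingerprintSet`), making it
independent of the chemistry software used to produce fingerprints;
fingerprint generation from SMILES is deliberately outside the tested core,
and the conventional parameters (circular fingerprints of radius 2, 2048
bits) are a matter for the upstream tool. The Tanimoto index is
$|a \cap b| / |a \cup b|$, defined as 0 for two empty sets. Coverage of a
library over a query space is the per-query maximum Tanimoto over the
library, with ties broken toward the alphabetically first library id;
enlarging a library can never decrease any query's coverage. The two-sample
Kolmogorov–Smirnov comparison of coverage distributions uses the asymptotic
two-sided p-value, appropriate for the hundreds-to-thousands of compounds
involved; exact small-sample p-values are out of scope.

## Activity classification

Species-specific classifiers are probability random forests: 500 trees,
$\sqrt{p}$ features per split, and **nodes grown to purity** (minimum node
size 1, i.e. unlimited depth). Node purity matters: with shallow or
size-limited leaves, the predicted probability of an inactive compound
converges to the class base rate, which is exactly where the decision
threshold sits (below), inflating false positives. "20× cross-validation"
is implemented as 20 independent stratified 8:2 shuffle-splits — matching
repeated splitting with stratification, not a 20-fold partition — and each
split's threshold is that split's own training-set hit frequency (the
alternative, a single global frequency, is nearly identical in balanced
datasets but leaks information across splits). Thresholding uses $\ge$, so
a probability exactly at the prevalence is called active; tie handling is
not prescribed anywhere and this choice is documented here.

Metrics are imbalance-aware: balanced accuracy (mean of sensitivity and
specificity; chance level 0.5 at any prevalence) and average precision
(step-wise area under the precision–recall curve, ties processed as
blocks; chance level equals the prevalence). The shuffled-label null
re-runs the *entire* pipeline — splitting, fitting, thresholding — on
label-permuted data, which is the only null that honestly accounts for the
pipeline's degrees of freedom.

## Community composition and bioaccumulation

Relative abundances are count proportions; the absolute-abundance proxy
multiplies them by the culture's optical density, so a species' proxy is
comparable across samples with different total growth. Treatment effects
are per-species ratios of arm means of these proxies; species with a zero
control mean are flagged NA rather than infinite, and ratios are invariant
to common sequencing-depth rescaling. Calibration-curve quantification is
ordinary least squares with inversion, flagging out-of-range samples as
extrapolated. Percent depletion is $100\,(1 -
\bar{c}_{\mathrm{supernatant}}/\bar{c}_{\mathrm{whole}})$ using means of
replicates, with a Welch two-sided t-test across replicates; whether
published depletion figures used means-of-arms or means of per-replicate
ratios is not stated, and means-of-arms is the choice here.

## What the synthetic data emulate — and what they do not

The generators reproduce the *structure* of the study conditions: 96-well
plates with eight interspersed DMSO controls, starting OD600 0.05, hourly
reads for 24 h, three biological replicates, a single 20 µM dose;
logistic growth with multiplicative lognormal noise (a per-well biological
factor and per-read measurement noise, default CV 5 %, a typical plate
reader regime); twofold dose series up to 20 µM with Hill-type responses
(coefficient 4) constructed so the noiseless normalized AUC crosses 0.1
exactly at the planted MIC; negative-binomial insertion counts (dispersion
0.2, a typical overdispersion for amplicon-like counts) with 2–3 samples
per arm and planted log2 effects; sparse random fingerprints (64 bits,
10 % density, plus a 16-column noisy linear projection standing in for a
learned embedding) with a planted two-bit AND rule whose bit probabilities
hit a target prevalence of 0.15; and Dirichlet-multinomial community counts
with planted per-species fold changes. The compact fingerprint is a
deliberate abstraction: real circular fingerprints are longer but highly
redundant, whereas independent random bits carry no redundancy, so a short
synthetic fingerprint is the fair analogue for testing whether the planted
rule is learnable at all.

They do **not** emulate: correlated compound structure (fingerprint bits
are independent), per-site insertion-efficiency effects (sites within a
gene are exchangeable), plate-position artefacts beyond multiplicative
row/column effects, carry-over or edge evaporation dynamics, taxonomic
misclassification in community counts, or any chemistry. Passing tests
therefore demonstrate that the *statistics* behave as specified under
their stated assumptions — calibrated nulls, recovery of planted effects at
realistic noise — not that any biological conclusion transfers to a given
real dataset.

Every generator is a pure function of its arguments including the seed, and
each draws from its own seed substream (fixed per-generator offsets), so
adding one generator to a script never perturbs another's output.

## Problem sizes and numerical conventions

The verification runs use: 12 null plates × 3 replicates and a
1,000-compound × 8-strain planted screen for hit calling; 100 dose–response
pairs for MIC recovery; 2,000 genes at 20,000 permutations for permutation
calibration and recovery (with 50 two-vs-three designs compared against
exhaustive enumeration); a 500-mutant null arrayed library and 30
single-planted-mutant libraries for detection probability; and an
800-compound library with 20 splits and 20 label shuffles for
classification. These sizes keep each stage's run in the seconds-to-minutes
range while leaving the binomial uncertainty of each estimated rate well
inside the margins being tested.

Numerical conventions: permutation-statistic comparisons use a relative
tolerance of 1e-12 to absorb floating-point ties; permutation p-values are
floored at one over the permutation count; BH adjustment is the standard
step-up with an explicit family size; trapezoid integration uses observed
time stamps; logistic fitting is bounded (K, N0 > 0, r ≥ 0) with
deterministic initial values; and all random-forest fits run single-threaded
under explicit seeds for bit-reproducibility.

## Known limitations

- Site-level permutation p-values are conservative under strong per-site
  heterogeneity (see above); gene-level resampling with many samples per
  arm is the remedy when designs allow it.
- The doublings correction is a per-doubling rescaling, not a mechanistic
  model of selection during regrowth.
- The arrayed-screen Welch test with two biological replicates per arm has
  limited power; the detection probabilities verified here assume the
  averaged-technical-replicate design.
- `GrowthCurveSet` requires a shared time grid per set, which matches
  plate-reader exports; ragged per-well time grids must be split into
  separate sets.
- The KS coverage p-value is asymptotic and should not be used for samples
  of fewer than a few dozen compounds.
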