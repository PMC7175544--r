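---
title: "Copy-number abnormality scoring and histology classification from shallow-WGS cfDNA: models and design"
author: "plasmaCNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plasmaCNA methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmaCNA)
```

# The problem

Advanced lung cancer sheds tumor DNA into plasma. At shallow whole-genome
sequencing depth (~0.1–1x), individual mutations are invisible, but somatic
copy-number alterations (CNAs) leave a dosage footprint on read coverage:
counting reads in fixed 100 kb bins and normalizing against healthy
references yields a per-bin log2 ratio in which a gained region floats above
zero and a lost region sinks below it, with an amplitude set by the tumor
fraction *f* of the cfDNA. plasmaCNA implements the downstream analysis of
such profiles: segmentation, reference-standardized segmental Z-scores,
aberration calls, a genome-wide tumor-burden score with a
false-discovery-rate-calibrated abnormality cutoff, histological subtype
classification (LUAD / LUSC / SCLC) from discretized CNA states, paired
solid/liquid concordance statistics, and in-silico tumor enrichment by
cfDNA fragment-size selection. Everything upstream of normalized bin ratios
(alignment, duplicate marking, GC/mappability normalization) is out of
scope; the pipeline starts from bin-ratio tables plus a control panel.

# Data model

- `BinGrid` — the genome partition: 0-based half-open bins of fixed width
  (100 kb default), a per-bin usability mask (centromere-like loci carry no
  information), and per-bin weights.
- `CopyNumberProfile` — one sample's per-bin log2 ratios on a grid.
- `ReferencePanel` — the p × n matrix of control ratios. It supplies both
  the per-bin weights (reciprocal of the per-bin population standard
  deviation across controls, `panelBinWeights()`; zero-spread bins are
  masked) and the denominator of the segmental Z-score. The population
  (divide-by-p) spread estimator is used in both places for consistency.
- `SegmentSet` — an ordered tiling of the usable bins into segments with
  mean ratio, Z-score and call.

# Segmentation

`segmentProfile()` partitions each chromosome independently by a circular
binary segmentation–style recursion: over all arcs (i, j] of the compacted
usable-bin values the two-sided t-like statistic

$$T(i,j) = \frac{|\bar{x}_{in} - \bar{x}_{out}|}{\hat\sigma\sqrt{1/k + 1/(n-k)}}$$

is maximized (leftmost maximizer on ties; an arc and its complement induce
the same cut set), and the best split is accepted when a within-chromosome
permutation test yields p < `alpha` (default 0.01, 1000 permutations,
early-stopped as soon as significance is impossible). Accepted pieces are
searched recursively; stretches shorter than `minBins` (default 3) are
never tested. Masked and sample-missing bins are skipped with compacted
indices, never interpolated. Values are centered before each scan so the
procedure is exactly translation invariant. The scan kernel is compiled
(Rcpp); permutations draw from R's RNG so a seed fixes the result. The
published segmenter's pruning/undo heuristics are not reproduced; on small
instances the accepted split provably maximizes the statistic (exhaustive
search in the test suite). Whether the original analysis segmented weighted
or unweighted values is unstated; unweighted values are used here, weights
enter only the Z-score means.

# Segmental Z-scores, calls, CPA

For a segment spanning bins n..m, `scoreSegments()` computes

$$Z = \frac{\mu_w(R_{n..m}) - \mu\big(\mu_w(r_{1,n..m}), \ldots, \mu_w(r_{p,n..m})\big)}
          {\mathrm{sd}\big(\mu_w(r_{1,n..m}), \ldots, \mu_w(r_{p,n..m})\big)}$$

where $\mu_w$ is the weighted bin mean (same panel-derived weights for the
case and every control) and sd is the population spread over the p
controls. Gains are called at Z ≥ 3, losses at Z ≤ −3. Segments whose
control spread is zero are undeterminable and excluded downstream.

The copy number profile abnormality score summarises tumor burden:

$$\mathrm{CPA} = \frac{1}{n}\sum_{i=1}^{n} |Z_i| \, l_i$$

with segment lengths $l_i$ in units of 100 Mb (the score is "per 100 Mb")
and n the number of determinable segments. A flat diploid profile scores
near 0. Two documented conventions: lengths count usable bins only, and
because the score divides by n it is not invariant to how finely a profile
is segmented — splitting one segment into equal halves halves its
contribution. This sensitivity is inherent to the definition and is
documented rather than "fixed".

# Abnormality calling

`calibrateCutoff()` fits a normal distribution (moment estimates; sample
standard deviation — whether the original analysis used the sample or
population estimator is unstated, and at n ≥ 100 controls the difference is
negligible) to control CPA scores and places the cutoff at the 1 − FDR
quantile, `mu + qnorm(1 - fdr) * sigma` (FDR 0.01 by default). A sample is
abnormal when its CPA is strictly greater than the cutoff ("crosses" it).
Calibration is done separately per modality (plasma vs FFPE tissue) because
FFPE noise depresses Z-scores. The adequacy of the normality assumption is
checked by a Monte-Carlo Lilliefors test (`lillieforsNormality()`): the KS
distance to the fitted normal, with mean and sd re-estimated in every null
replicate; 10,000 replicates by default (2,000 inside `calibrateCutoff()`,
where it is a diagnostic rather than an inference).

**Known limitation.** Under the synthetic generator below, the null CPA is
the mean of ~22 per-chromosome |Z|·length terms and therefore inherits a
mild right skew (≈ 0.2–0.3) that a body-level normality test rarely
detects, while the extreme right tail is still heavier than normal: the
normal-quantile cutoff at the 99th percentile empirically flags ~1.5–2% of
held-out synthetic controls rather than 1%. This is a property of the
normal-fit calibration applied to a skewed mean-of-absolute-values
statistic, not of its implementation; real cfDNA panels with additional
per-sample variance components may be closer to normal. The Lilliefors
p-value is reported with every calibration precisely so users can judge
the assumption.

# Synthetic cohort generator

The generator exists so every stage can be validated end-to-end without
patient data, and its defaults define the package's study conditions:

- **Genome** — 22 autosomes with sizes proportional to the human autosomes,
  scaled to a configurable total (3000 bins of 100 kb by default; most
  tests and the acceptance analyses run at 300–660 bins, which changes no
  statistical property of the methods, only runtime). A centromere-like run
  (3% of each chromosome) at the 40% point is masked and separates the p
  and q arms. Sex chromosomes are excluded to avoid constitutional-copy
  modelling.
- **Noise** — per-bin Gaussian noise with bin-specific standard deviations
  drawn once from `binNoiseSdRange` (default 0.05–0.2 log2 units, typical
  of shallow-WGS 100 kb bins) and shared by the panel and all samples,
  emulating locus-specific technical variability.
- **Aberrations** — arm-level subtype fingerprints realized per event with
  a penetrance. The defaults encode the qualitative lung-cancer patterns:
  5p gains shared by all subtypes; 1p and 9p gained in SCLC but lost in
  NSCLC; 3p lost in LUSC and most often in SCLC; 3q gains typical of LUSC;
  1q/14q/19p events on the LUAD side. No quantitative per-subtype
  penetrance table exists in the source material, so the penetrance values
  are this package's qualitative reading and are configurable
  (`defaultFingerprints(penetrance = 0.9)` gives the high-signal cohort
  used in the classifier checks). Gains are 3 copies and losses 1 copy by
  default (`gainCopies = 5` emulates amplification), and amplitudes follow
  `expectedLog2Ratio(f, copies) = log2((2(1-f) + f·copies)/2)`.
- **Tumor fractions** — uniform on 0.05–0.5 for plasma-like cases, 0.3–0.9
  for the array-style (tissue) training table, where purity is high.
- **Fragments** — a two-component Gaussian insert-size mixture, normal
  (167 ± 12 bp) vs tumor (145 ± 25 bp), the simplest shape preserving the
  "shorter = more likely tumor-derived" ordering; reads fall into bins in
  proportion to local expected coverage 2(1−f) + f·copies and carry their
  true origin so enrichment can be verified against truth. Sequence-level
  artifacts (GC bias, 10 bp periodicity) are not modelled.

All generators are deterministic given the config seed; each consumer
derives an independent stream from it. Because noise is Gaussian and
independent across bins, passing tests demonstrate correctness of the
statistics under the stated model — they do not demonstrate robustness to
wavy backgrounds, correlated noise or mappability artifacts in real data.

# Classification

Per-bin states are discretized to −1/0/+1 (`discretizeFeatures()`): from
called segments via the |Z| ≥ 3 rule, or from array-style continuous
segment states via a symmetric ±0.1 log2 threshold (the exact threshold
used for the public array data is not in the main source text; ±0.1 is this
package's choice). Discretization deliberately sidelines tumor fraction as
a variance source: any monotone amplitude rescaling that preserves call
boundaries leaves the features unchanged.

The first-class model is multinomial logistic regression with ridge
penalty (glmnet), penalty strength chosen by inner 5-fold cross-validation
over a 7-point log-spaced grid 10^-3–10^3; `"lasso"`, `"enet"`, `"rf"` and `"svm"`
complete the comparison harness behind the same interface. Every glmnet
fit uses class-balanced observation weights, so fitted probabilities are
never driven by class priors — this matches the class-balanced design
(68 samples per class, `balancedSubsample()`), and it removes a
leave-one-out artifact in which the held-out sample's class is depleted in
the training fold and a prior-driven model ranks it systematically lower
(pushing null-model AUCs far below 0.5 instead of to 0.5).

`loovEvaluate()` runs leave-one-out cross-validation — balancing, penalty
selection and fitting see only the n − 1 retained samples — pools held-out
class probabilities, and reports one-vs-all ROC AUCs (midrank/Mann–Whitney,
`rocAuc()`), their mean (mAUC) and argmax accuracy.
`binaryGrouping()` collapses to the clinically decisive SCLC-vs-NSCLC
task using p(SCLC) directly. Samples without detectable aberrations
(all-zero rows) are still predicted but flagged `flat`; they gravitate to
the class whose training profiles are quietest (LUAD in the default
fingerprints — LUAD tumors carry the weakest footprint). `coefficientReport()`
ranks loci by |β| per class and aggregates to arms.

# Concordance

`smoothProfile()` interpolates the centered 100-bin window mean to each
position (window shrinks at chromosome edges; never crosses chromosomes);
paired profiles are compared by Pearson r on smoothed values and by the
total-least-squares slope (first principal axis of the centered scatter —
slope > 1 means the second profile has larger amplitudes, i.e. higher
tumor fraction). Group-level aberration-frequency waves (%gain, %loss,
signed %gain − %loss per bin) are clustered by complete linkage on the
Pearson distance d = (1 − r)/2. Group summaries that weight samples
unequally use `weightedGroupSummary()` with an effective-sample-size CI;
for paired-biopsy analyses the dot weight is `1/(1 + days)^2`
(`intervalWeights()`) — the direction of the original quadratic
interval-time weighting is ambiguous in the source figures, and
down-weighting long intervals (interval time as a confounder) is the
interpretation adopted here.

# Fragment-size enrichment

Tumor cfDNA fragments skew short, so keeping paired-end reads with insert
size 90–135 bp (inclusive at both ends — inclusivity is unstated in the
source and chosen here) enriches tumor-derived reads. `fragmentPipeline()`
derives three profiles per sample: raw, insert-size filtered, and a
random downsample matched to the filtered read count (the negative control
showing that apparent new CNAs are not a read-depth artifact). Profiles
come from `log2(observed/expected)` after total-count scaling, with
synthetic truth expectations standing in for a reference normalization.
The closed-form enrichment is
`f' = f·passTumor / (f·passTumor + (1−f)·passNormal)`; with the default
components the 90–135 bp window passes ~33% of tumor but only ~0.4% of
normal fragments, so f = 0.1 becomes f′ ≈ 0.9. `amplitudeShift()`
measures per-segment |mean ratio| across the three arms and summarises the
deltas; only segments with raw amplitude ≥ 0.1 enter the summary, because
the absolute value of a noisy zero is biased upward and would spuriously
inflate the lower-count arms.

# Numerical and degenerate-input conventions

- Segmentation tie-breaks: leftmost maximizer; chromosomes (or recursion
  pieces) with fewer than `minBins` usable bins are single segments.
- Empty usable ranges raise a typed `"undeterminableSegment"` condition;
  zero control spread makes a segment's Z `NA` and drops it from CPA.
- `sigma = 0` in calibration degenerates to `cutoff = mu` with a warning;
  CPA equal to the cutoff is *not* abnormal.
- All-constant feature matrices train an intercept-only prior model.
- Insert sizes are integers ≥ 1; filter bounds are inclusive.
- Every stochastic routine takes an explicit seed and restores the
  caller's RNG state.

# Problem sizes used in the validation suite

Chosen so the full suite runs comfortably on one CPU: Z-score oracle
checks at ≤ 10 bins × ≤ 8 controls × 1000 instances; segmentation recovery
at 100-bin chromosomes × 200 replicates; calibration at a 660-bin genome,
50-control panel, 500 calibration + 10,000 held-out controls; classifier
checks at 68 samples/class on a 660-bin genome; enrichment at 10^5 reads.
The generator itself defaults to the 3000-bin genome.

# Known limitations

- The normal-fit abnormality cutoff over-flags mildly skewed null CPA
  distributions (see above): expect ~1.5–2% empirical type-I error at a
  nominal 1% under the Gaussian generator.
- CPA depends on segmentation granularity (divides by n).
- The generator does not model correlated noise, GC waves or mappability
  structure; classifier performance on it is an upper bound.
- Real-BAM ingestion (proper-pair flags, Picard-style insert-size metrics)
  is out of scope; fragment records enter as plain tables.
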