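---
title: "Methods: microbiota-based provenance classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbiota-based provenance classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Adult *Anopheles gambiae* mosquitoes accumulate bacteria from their
environment throughout life — maternally (e.g. *Wolbachia*), in larval
breeding water (*Massilia*, *Shewanella*), and from adult nectar feeding
(*Acinetobacter*). If villages differ in these sources, the whole-body
microbiota acts as a record of where a mosquito has lived, and a classifier
trained on 16S OTU counts can assign individuals to their village of
capture. That assignment, and the exceptions to it, carry information about
mosquito movement between villages — directly relevant to how quickly a
local vector-control intervention could be undone by immigration.

`microprov` implements the full analysis chain for this question, starting
from an OTU count table (everything upstream — read merging, 97% OTU
clustering, taxonomic annotation — is left to standard amplicon tools):

1. depth filtering and rarefaction (`filter_low_depth`, `rarefy_table`,
   `rarefaction_curve`);
2. unsupervised community structure: Morisita–Horn dissimilarity, average
   linkage clustering, NMDS, one-factor PERMANOVA, Pearson co-occurrence
   (`distance_matrix`, `hierarchical_cluster`, `nmds`, `permanova`,
   `cooccurrence`);
3. supervised provenance classification by a random forest inside a
   repeated double cross-validation (rdCV) scheme with inner-loop backward
   OTU elimination (`run_rdcv`);
4. model-validity testing against a permuted-label null population
   (`build_h0`, `predicted_h0_mean`, `h0_pvalue`);
5. a synthetic-data generator that emulates the study design so the whole
   chain is testable without external data (`generate_dataset`).

The package is organised as an analysis workflow: the numbered scripts in
`analysis/` run the stages in order on a synthetic study dataset and write
their tables under `results/`; every computation they perform lives in the
package functions, which is what the test suite exercises.

# The rdCV classifier

## Scheme

Double cross-validation separates *tuning* from *assessment*. For one
repetition:

- The samples are split into `n_outer` stratified outer folds.
- For each outer fold, the remaining training samples are split again into
  `n_inner` folds. On this inner loop the model complexity — here, the
  *number of OTUs* — is tuned: forests are fitted on the inner-training
  segments, OTUs are ranked by their average importance rank across the
  inner-segment models, the worst 10% (`drop_fraction`, count rounded up)
  are eliminated, and the loop repeats down to `min_otus`. Each step
  records the total inner-validation misclassifications; the OTU set
  minimizing that count is selected, ties broken toward fewer OTUs.
- One forest is then fitted on the full outer-training set restricted to
  the selected OTUs, and class probabilities are recorded for the held-out
  outer fold. The held-out samples never influenced OTU selection or
  fitting — the audit trail (`keep_folds = TRUE`) lets tests verify this.

The whole double loop is repeated (`n_rep`, 200 for a full run) with fresh
fold splits, giving a *population* of class probabilities per observation
rather than a point estimate. The consensus class is the argmax of the
repetition-mean probability (ties broken by lexicographic class order), so
an observation is called "misclassified" only when its whole probability
population leans away from its true label — which is exactly the behaviour
that flags recent migrants: an individual captured in one village but
carrying another village's flora is *consistently* assigned to the source
village.

## Null model and validity p-value

With ~29 samples and hundreds of OTUs, overfitting is the default outcome
unless the validation design prevents it. The package therefore builds an
explicit null: `n_models` (400 for a full run) rdCV models fitted after
permuting the labels without replacement, recording each model's consensus
misclassification count. Under label permutation a prediction is correct
with probability $\sum_k (n_k/n)^2$, so the expected misclassification
count is

$$E[m] = n - \frac{\sum_k n_k^2}{n},$$

which `predicted_h0_mean()` computes ($(1-1/K)\,n$ for $K$ balanced
classes; 19.3 for 29 samples in three balanced classes). Agreement of the
*estimated* null mean with this closed form is the built-in check that the
procedure does not leak information. The model p-value is the lower-tail
cumulative probability of the observed count in a location-scale Student-t
fitted to the null population by its sample moments with
`n_models − 1` degrees of freedom; the population's skewness and excess
kurtosis are reported as diagnostics for that distributional reading.

## Design choices the literature leaves open

The rdCV description this implements does not fix every detail; the
following are this package's choices, configurable where sensible:

- `n_outer = 6`, `n_inner = 5`: six outer segments hold out 4–5 samples at
  n ≈ 29, in line with common rdCV practice. Folds are stratified by class
  — with three classes of ~10, unstratified folds frequently lose a class
  from a training segment.
- OTU importance is the forest's permutation importance (out-of-bag
  accuracy decrease); impurity importance is available via
  `importance = "impurity"`.
- The drop count per elimination step is `ceiling(drop_fraction * n)`,
  guaranteeing progress for small OTU sets; rank ties at the cut break by
  stable OTU order.
- The inner loop selects a concrete OTU *set* per outer fold (not merely a
  count that is re-derived elsewhere).
- Per-OTU importance is aggregated over all outer models; OTUs a model did
  not select share the tied average of that model's trailing rank
  positions, so every OTU has a defined average rank.
  `importance_summary()` reduces OTU ranks to genus level by the best OTU
  rank within each genus.
- Seeding: the master seed spawns one seed per repetition by a seeded
  draw; every stage is bit-reproducible given its seed.
- Null models default to a single repetition each
  (`null_n_rep = 1`): the null *mean* is a chance-level quantity that does
  not depend on the repetition count, and several hundred null models at
  full repetitions would dominate runtime for no inferential gain. A
  paper-scale null is one flag away.
- Default `forest_size` is 128 trees; with ~25 training samples the
  out-of-bag error is flat well below this. The bundled studies use 50
  trees (and 32 for null models) — the reported quantities are insensitive
  to forest size at these problem sizes.

# Community-structure methods

"Horn" dissimilarity here is the Morisita–Horn overlap index

$$d(x, y) = 1 - \frac{2\sum_i x_i y_i}
{\left(\frac{\sum_i x_i^2}{X^2} + \frac{\sum_i y_i^2}{Y^2}\right) X Y},$$

the formula behind the `"horn"` method of the classical vegetation-analysis
distance functions — not Horn's information-theoretic overlap. It is zero
for identical relative-abundance profiles, one for disjoint support, and
invariant to per-sample depth rescaling. NMDS minimizes Kruskal stress-1
with isotonic regression (primary tie treatment), taking the best of a
metric-scaling start plus `n_starts` random restarts; no abundance
autotransform is applied since the input is already a dissimilarity.
PERMANOVA is the one-factor pseudo-F from between/within sums of squared
distances with significance by label permutation and the unbiased
$(1 + \#\{F_\pi \ge F\})/(1 + n_\text{perm})$ convention; the default
9,999 permutations are desk-scale, and `n_perm` accepts $10^6$ for
publication-grade p-values. These standard steps are delegated to vegan
(`vegdist`, `metaMDS`, `adonis2`) and `stats::hclust` behind the package's
interfaces; the package's own tests still verify them against hand
formulas, exhaustive permutation enumeration and brute-force agglomeration.

Rarefaction subsamples each sample without replacement (multivariate
hypergeometric) to a common depth, and the analytic rarefaction curve is
the hypergeometric expectation
$E[S(d)] = \sum_i \left[1 - \binom{N - N_i}{d}\middle/\binom{N}{d}\right]$,
evaluated in log space so realistic depths do not overflow.

# The synthetic-data generator

`generate_dataset()` emulates the statistical structure of village-labelled
whole-body mosquito microbiota:

- **Depths.** Per-sample read depths are log-normal with natural-scale
  mean 17,300 and SD 13,161.83 (method-of-moments fit, see
  `lnorm_from_moments`), matching the depth spread of whole-body mosquito
  16S libraries — including samples that fall below the 7,500-read filter,
  so the filtering step is genuinely exercised.
- **Composition.** A shared background of `n_background_otus` (default
  200) OTUs has log-normal baseline abundances
  (`background_log_abundance_sd = 1.5`), giving the long tail of rare OTUs
  plus a few dominant ones typical of rank–abundance curves in these data.
  Each village additionally enriches its own
  `n_signature_otus_per_class = 4` signature OTUs by
  `signature_fold_change = 5` in expected relative abundance. Signature
  OTUs are annotated to marker genera (Massilia-like, Wolbachia-like,
  Shewanella-like, Acinetobacter-like); the fold change of 5 is a
  moderate, biologically plausible enrichment that yields the ≥90%
  consensus accuracy regime the classifier is meant to operate in.
- **Counts.** Given its depth, a sample's counts are multinomial draws
  from its village's expected profile; an optional `overdispersion`
  parameter adds Dirichlet noise for realism studies. Row sums equal the
  drawn depths exactly.
- **Migrants.** A migrant is defined at the expected-profile level: its
  profile is `weight * source-village + (1 - weight) * home-village`. This
  matches the interpretation of a recently arrived individual (high
  weight) or one with a long mixed exposure history (intermediate weight),
  without attempting read-level simulation.
- **Design.** Default class sizes are 10/10/9 — three villages totalling
  29 samples, the size regime the pipeline targets. The generated 29
  samples play the role of a *post-filter* analysis set; the bundled
  workflow scripts additionally simulate the pre-filter situation by
  letting the log-normal depths produce sub-threshold samples.

What the generator does **not** emulate: sequence content (no reads, no
chimeras), phylogenetic correlation between OTUs, compositional
interactions beyond the shared background, batch effects, or
taxon-specific overdispersion. Passing tests on synthetic data therefore
demonstrate that the *procedures* behave correctly under the assumed
sampling model — multinomial counts over village-specific expected
profiles — not that real mosquito data satisfy that model.

# Numerical and scale choices

- Elimination from 212 OTUs at 10% per step takes ~33 steps to reach
  `min_otus = 2`; each step fits `n_inner` forests, so one repetition fits
  about a thousand forests. The bundled studies use 25 repetitions
  (classification) and 200 single-repetition null models (calibration),
  which reproduce the headline quantities at desk scale; full-scale runs
  (200 repetitions, 400 null models) are configuration changes only.
- The null-calibration study runs on a narrower table (12 signature + 40
  background OTUs): the null misclassification mean depends only on the
  class sizes, and the narrower substrate keeps 200 null models fast.
- Degenerate inputs are rejected loudly: zero-depth samples (Horn and
  relative abundance are undefined), rarefaction depths exceeding a
  sample's total, stratified fold counts exceeding the smallest class, a
  zero-variance null population (`sd = 0`) in `h0_pvalue`.
- Ties: isotonic regression averages tied blocks (Kruskal's primary
  approach); consensus-class ties break lexicographically; elimination
  ties break by stable OTU order — all deterministic.

# Known limitations

- The t-distribution reading of the H0 population is a modelling choice;
  with 400 models the normal and t readings are numerically close, and the
  shape diagnostics let a user judge the assumption, but a rank-based
  p-value is not provided.
- PERMANOVA is one-factor only; the analyses this supports test single
  grouping factors (village, sex/diet class) separately.
- NMDS on strongly separated synthetic data can reach near-zero stress,
  where the embedding is underdetermined; the `converged` flag and stress
  value should be read together.
- The classifier treats OTUs as exchangeable features; it does not use
  taxonomy, phylogeny or abundance structure beyond what the forest
  learns.
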