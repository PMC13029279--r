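---
title: "Mechanistic integration of pregnancy pharmacovigilance reports: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic integration of pregnancy pharmacovigilance reports: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pregvig)
```

## The problem

Spontaneous pregnancy pharmacovigilance reports (individual case safety
reports, ICSRs) describe adverse reactions observed under real-world
antiviral use: heavy polypharmacy, boosted regimens, and reaction patterns
that cluster into recurring phenotypes. `pregvig` implements an integration
pipeline over such reports: it harmonises pre-existing reaction-cluster
labels into stable phenotypes, profiles those phenotypes against
structure-derived ADMET liabilities, quantifies drug–phenotype
disproportionality, models seriousness as a function of regimen size,
characterises the co-medication network and its robustness to hub removal,
condenses everything into a drug-level mechanistic vulnerability index (MVI)
and a regimen-level interaction prioritisation score (DPS), and checks the
biological plausibility of transporter/enzyme liabilities against pregnancy
pharmacokinetic exposure bounds.

Because real line listings cannot be redistributed, the package ships a
synthetic cohort generator whose defaults encode the study conditions the
analyses assume, together with a ground-truth record so every estimator can
be validated by parameter recovery.

## The data model

Two linked representations are used throughout:

* **Case level** — one row per deduplicated ICSR: suspect actives (the
  reporter-designated causal candidates), concomitant actives, reaction
  terms, the regulatory seriousness flag, sex/follow-up/literature flags and
  a raw reaction-cluster label. Deduplication unions multi-row exports per
  case id and ORs the seriousness flag. All inference-sensitive analyses
  (seriousness proportions, regressions, disproportionality counting) run at
  this level to avoid pseudo-replication.
* **Expanded level** — one row per (case, suspect drug, reaction) triple,
  used only for mechanistic linkage (ADMET signatures, significance panels,
  drug-level aggregation). Concomitants never enter the expansion; they feed
  polypharmacy counts and the co-medication network instead, reflecting the
  pharmacovigilance convention that concomitants are context, not causal
  candidates.

Primary active drugs are assigned per case by the antiviral class hierarchy
INSTI > PI > NNRTI > NRTI > RdRp; any other class ranks below RdRp, and ties
within the winning class break to the lexicographically smallest name so the
assignment is deterministic and order-invariant.

## The synthetic cohort generator

`synth_config()` fixes the study conditions; the important defaults and the
reasoning behind them:

* **Polypharmacy.** Actives per report follow a shifted negative binomial,
  `1 + NB(size = 0.60, mu = 19.25)`. No (size, mu) pair reproduces the
  target quartiles 6/11/27 simultaneously — the family is not flexible
  enough at that skew — so the parameters were chosen to match the median
  (11) exactly, giving quartiles 4/11/27. The median is the quantity the
  downstream invariants constrain.
* **Seriousness.** `serious ~ Bernoulli(plogis(0.50 + log(1.05) * n_actives))`:
  a 5% odds increase per additional active, with the intercept set so the
  marginal prevalence lands near 0.82, the high-seriousness regime typical
  of pregnancy reporting (congenital anomalies and Important Medical Events
  are inherently serious).
* **Phenotype labels.** Raw cluster labels are drawn directly from
  `phenotype_probs` (default: one dominant cluster at 0.55, two mid-sized,
  one small, and two below the 2% harmonisation threshold) so the configured
  distribution is the case-label distribution. At least one sub-2% cluster
  is required by construction so harmonisation is always exercised.
* **Drug–phenotype linkage.** Each drug has a "home cluster"; suspect drugs
  whose home cluster matches the case's label get their sampling weight
  multiplied by the odds `coupling/(1 - coupling)` (default coupling 0.9,
  i.e. 9:1). This induces the association that ADMET signatures detect
  while leaving phenotype marginals untouched. The default strength was
  fixed once so that a planted 2-SD ADMET shift is recovered in sign
  essentially always at cohorts of a few hundred cases.
* **Hub structure.** A fixed backbone of 6 drugs carries an 8-fold
  concomitant-sampling weight, producing the concentrated hub topology under
  which targeted node removal dominates random removal.
* **Boosters.** Reports include ritonavir or cobicistat with probability
  0.236.
* **ADMET table.** Continuous predictors are `global mean + home-cluster
  shift x feature SD + noise`, with a configurable missing-cell fraction
  (default 12%) to exercise the median imputation used before
  random-forest fitting; binary transporter/enzyme liability flags are
  Bernoulli per drug.
* **PK tables.** Per drug x pregnancy stage x metric (Cmax in ug/mL,
  AUC0–24 in ug*h/mL): lognormal central values with uniform min/max bounds;
  a fifth of rows carry only a central estimate, exercising the degenerate
  sampling path. Potency values (IC50/Ki) are lognormal in uM.

All randomness flows from a single seed through derived sub-seeds; a fixed
seed reproduces every table byte-identically.

What the generator does *not* emulate: MedDRA hierarchies and coding noise,
reporting-volume time trends, correlated missingness, indication channeling,
and real drug identities. Passing tests therefore demonstrate estimator
correctness under the assumed structure, not robustness to the full
messiness of regulatory exports.

## Phenotype analyses

* **Harmonisation** collapses raw labels under 2% of cases into `"Other"`.
* **ADMET signatures** are phenotype-level medians of drug-borne features
  over expanded records, z-scored across phenotypes within feature using
  sample (n-1) scaling. Under that convention a single extreme phenotype
  among five can reach at most `(n-1)/sqrt(n) = 1.79`, which is exactly the
  ceiling observed in practice for a small outlying phenotype; population
  scaling would put that ceiling at 2 and was rejected for consistency with
  the worked example (medians 1 and 3 giving z = ±0.707). Constant features
  are reported as z = 0 with a flag rather than dropped.
* **Kruskal–Wallis panel** tests each feature across phenotypes at the
  expanded-record level (the level at which extreme significance is
  attainable), with tie correction and Benjamini–Hochberg adjustment across
  the panel.
* **ICC(1)** uses the one-way random-effects form
  `(MSB - MSW)/(MSB + (k0 - 1) MSW)` with the unbalanced group-size constant
  `k0`, truncated at zero. The unit of analysis is the expanded record
  carrying its drug's composite ADMET risk, grouped by phenotype — the only
  level at which phenotype membership and ADMET risk coexist; this is an
  interpretive choice and is flagged as such.
* **Reaction-class concordance** is a case-level 2x2 odds ratio of
  term-set membership (default hepatobiliary term list, configurable) in one
  phenotype versus the rest, Woolf CI, Haldane–Anscombe 0.5 on zero cells.

## Disproportionality

Contingency tables are built at case level. Under primary attribution every
case counts for exactly one drug, so the per-pair `a` counts partition the
cohort; the all-suspect variant, in which a case counts once per suspect
drug, is the sensitivity analysis, compared by top-10 Jaccard overlap per
phenotype (ranking by observed/expected ratio, ties by q then name). The
reporting odds ratio is the cross-product with 0.5 added to all four cells
only when a cell is zero; the p-value is the two-sided Fisher exact test;
q-values are step-up Benjamini–Hochberg; a pair is *enriched* when `q <
0.05` and `ROR > 1`. No Bayesian shrinkage (IC/EBGM) is provided — the
method family here is ROR-only by design.

## Network robustness

The co-medication graph joins two actives when they co-occur in one report
(weight = number of co-reporting cases); centralities are computed on the
unweighted simple graph, betweenness normalised by `2/((n-1)(n-2))`. The
robustness simulation removes nodes either targeted (current highest degree,
recomputed each step, ties broken uniformly at random per replicate — a
deterministic tie-break would collapse replicate variance) or uniformly at
random, tracking the fraction of original edges removed and the modularity
of a greedy agglomerative partition of the remainder, with percentile 95%
intervals over replicates (default 1200 per strategy; the replicate count is
read as per-strategy since the figure-level description does not say).
Modularity is undefined on an edgeless remainder and reported as missing.

## Seriousness regression

A case-level ML logistic fit of the seriousness flag on
`poly_actives_total`, reporting `exp(slope)` with Wald 95% CIs (the
published CIs are tight and symmetric, which profile intervals would not
change materially). An HC0 sandwich covariance is available; it never moves
the point estimate. Quasi-perfect separation aborts with a diagnostic. The
single-predictor specification is the headline model; covariate-adjusted
variants are labelled as such, since per-unit ORs of 1.03 and 1.05 can both
arise from the same data under different specifications. The restriction
sensitivity (female, non-follow-up, non-literature) refits on the subset and
reports the retained fraction.

## Scoring

The MVI chain per drug: `adr_composite = total_reports x n_clusters`
(case-level suspect volume times distinct phenotypes; the expanded-record
volume is also reported since the published table's denominators are
ambiguous); a high-burden label at the inclusive type-7 upper quartile; a
probability random forest for `P(high burden)` using out-of-bag
probabilities (median imputation column-wise; the label constituents
`total_reports` and `n_clusters` are excluded by default to avoid leakage,
with the inclusive variant behind `exclude = character(0)`); the composite
`0.60 P + 0.15 z(polypharmacy) + 0.15 z(network) + 0.10 z(severity)` where
`z(network)` is the mean of z-scored degree and betweenness and `z(severity)`
is the z-scored serious-report fraction; and finally
`MVI = 100 x (rank - 1)/(n - 1)` with average ranks for ties. That
percent-rank convention is the only one consistent with the printed
sequence 100.0, 95.8, 91.7, 87.5, … at n = 25 (steps of 100/24).

Diagnostics: stratified 70/30 hold-out AUC, leave-one-drug-out AUC,
out-of-bag error, bootstrap percentile intervals of the predicted
probabilities (B = 500), importance coefficient-of-variation over bootstrap
refits, Spearman/Kendall rank correlations between default- and
alternative-weight rankings, and variance inflation factors across the four
composite components.

The DPS is a convex combination for each observed regimen (unique
suspect-drug sets of size >= 2): MOS = fraction of liability axes flagged in
at least two members, NAS = percent rank of summed member degree, SVS = mean
member MVI/100, `DPS = (MOS + NAS + SVS)/3`. The component formulas are
package conventions — the source framework names the components without
defining them — and are configurable. Tiers use absolute thresholds (0.75 /
0.50) by default; a percentile mode exists because the two published
descriptions (percentile thresholds, yet zero of 212 regimens above the
lowest tier) cannot both hold under a fixed-percentile rule. The
contradiction is documented rather than resolved.

## Exposure–liability simulation

For each drug x stage x metric row with micromolar potency values
available: exposures are sampled uniformly within the reported min–max
bounds (degenerate at the central estimate when bounds are absent),
AUC0–24 is reduced to `Cavg24 = AUC/24`, mass units convert to molar by
`x1000/MW`, and the ratio distribution against IC50/Ki is summarised by
median, 2.5/97.5 percentiles, `P(ratio > 1)` and `P(ratio > 10)` (strictly
greater, matching the notation). Stages are never pooled. The default
10,000 samples per combination makes the Monte Carlo error on an exceedance
probability about 0.005. A closed-form uniform exceedance
(`analytic_exceedance()`) serves as the independent oracle in the test
suite. This is plausibility screening in the IVIVE-margin sense, not PBPK,
not a DDI prediction.

## Embedding

Drug-level features (two sets: the mixed
polypharmacy/network/reporting/ADMET set, and a continuous-ADMET-only set —
both are provided because the source description states both and neither can
be privileged) are z-standardised (constant features dropped with a log
entry), decomposed by PCA with variance fractions over all components, and
sign-fixed so the largest-magnitude loading per component is positive,
making runs bit-comparable. Leave-one-drug-out refits re-standardise the
subset, sign-align to the full fit by inner product, and report per-component
Pearson correlations of the loadings.

## Numerical conventions and problem sizes

* Quantiles: type 7 (linear interpolation) throughout.
* Zero-cell corrections: Haldane–Anscombe 0.5 on all four cells, only when
  a zero is present, flagged in output.
* Percent ranks: `(rank - 1)/(n - 1)`, average ranks on ties, degenerate
  single-element inputs defined as the top with a warning.
* All stochastic stages take explicit seeds; sub-seeds are derived from the
  master seed, and the caller's RNG state is always restored.

The shipped test-suite problem sizes — cohorts of 250–5000 cases, 200
replicate cohorts for slope recovery, 1200 robustness replicates on a
~60-node graph, 10,000 Monte Carlo samples per exposure ratio — were chosen
as the smallest sizes at which the estimators' sampling error is safely
inside the asserted tolerances.

## Known limitations

* The generator's phenotype–drug coupling is a single global odds
  multiplier; real attribution heterogeneity is richer.
* The random-forest component is a ranking heuristic on ~25 drugs; its
  AUCs are noisy by construction and are reported, not optimised.
* Reproduction of published per-drug exposure exceedance values requires
  the curated pregnancy PK/potency tables those values were computed from;
  the package looks for a user-supplied copy and reports its absence rather
  than substituting synthetic values.
* Scores are relative prioritisation tools; nothing here is calibrated to
  absolute clinical risk.
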