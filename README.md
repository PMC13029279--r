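# pregvig

Mechanistic integration of pregnancy pharmacovigilance reports.

Spontaneous pregnancy individual case safety reports (ICSRs) for antivirals
arrive with heavy polypharmacy, boosted regimens, and reaction patterns that
cluster into recurring adverse-drug-reaction (ADR) phenotypes. This package
is for pharmacovigilance analysts and pharmacometricians who want to go
beyond pairwise disproportionality: it links phenotype-labelled case reports
to structure-derived ADMET liabilities, co-medication network context, and
pregnancy pharmacokinetic exposure bounds, and condenses the result into
drug- and regimen-level prioritisation scores.

## What it computes

- **Case model** — deduplication to one row per ICSR (set-union of drugs
  and reactions, OR of the seriousness flag), structural expansion into
  (case, suspect drug, reaction) records, primary-active assignment by the
  antiviral class hierarchy INSTI > PI > NNRTI > NRTI > RdRp, and
  polypharmacy/booster accounting.
- **Phenotypes** — harmonisation of raw cluster labels (labels under 2% of
  cases collapse into "Other"), per-phenotype seriousness, z-scored median
  ADMET signatures, a tie-corrected Kruskal–Wallis panel with
  Benjamini–Hochberg control, the one-way intraclass correlation
  ICC(1) = (MSB − MSW)/(MSB + (k₀ − 1)·MSW), and reaction-class concordance
  odds ratios.
- **Disproportionality** — per drug–phenotype 2×2 table: reporting odds
  ratio ROR = ad/bc (Haldane–Anscombe 0.5 on zero cells), Woolf 95% CI,
  two-sided Fisher exact p, BH q, observed/expected enrichment, and an
  all-suspect attribution sensitivity summarised by top-10 Jaccard overlap.
- **Network** — within-report co-medication graph, degree and normalised
  betweenness, and a targeted-versus-random hub-removal robustness
  simulation tracking edge loss and greedy-partition modularity.
- **Seriousness model** — case-level logistic regression of the regulatory
  seriousness flag on the total active count, OR per additional active with
  Wald (optionally sandwich) intervals, odds compounding (e.g.
  1.03⁵ ≈ 1.16), and the female/non-follow-up/non-literature restriction.
- **Scoring** — the mechanistic vulnerability index
  `composite = 0.60·P̂ + 0.15·z(poly) + 0.15·z(net) + 0.10·z(sev)`, where
  P̂ is an out-of-bag random-forest probability of upper-quartile reporting
  burden, mapped to `MVI = 100·(rank−1)/(n−1)`; plus the regimen-level
  DDI prioritisation score DPS = (MOS + NAS + SVS)/3 with tiering.
- **Exposure–liability** — uniform Monte Carlo sampling of pregnancy
  exposure bounds, µg/mL → µM conversion by molecular weight,
  Cavg24 = AUC₀₋₂₄/24, and exceedance probabilities P(ratio > 1) and
  P(ratio > 10) against IC50/Ki thresholds.
- **Embedding** — PCA of z-standardised drug-level features with
  variance decomposition and leave-one-drug-out loading stability.
- **Synthetic cohorts** — a generator with ground truth (per-active odds
  ratio, planted ADMET shifts, hub identities) for end-to-end validation.

## Worked example

```r
library(pregvig)

cfg <- synth_config(n_cases = 1000, seed = 42)   # study-shaped cohort
coh <- generate_cohort(cfg)
map <- harmonise_phenotypes(coh$cases)

fit_seriousness(coh$cases)
#> Seriousness ~ polypharmacy (single-predictor, n = 1000)
#>   OR per additional active: 1.050 (95% CI 1.036-1.063), p = 1.53e-13

graph <- build_comed_graph(coh$cases)
admet <- generate_admet_table(coh$catalog, seed = 42)
mvi   <- mvi_table(coh$cases, map, graph, admet, seed = 42)
head(mvi[order(-mvi$mvi_pct),
         c("drug", "total_reports", "n_clusters", "rf_prob", "mvi_pct")], 3)
#>   drug  total_reports n_clusters rf_prob mvi_pct
#> 1 av22            103          5   0.561   100
#> 2 av15             87          5   0.509    95.8
#> 3 av12             88          4   0.690    91.7
```

The fitted odds ratio recovers the generator's true per-active effect
(1.05): each additional co-reported active raises the odds of a serious
outcome by about 5%. The MVI column shows the 0–100 percentile scale: with
25 tie-free drugs, consecutive ranks sit exactly 100/24 ≈ 4.17 apart, so the
top three drugs score 100.0, 95.8 and 91.7.

`run_pipeline(run_config(...))` executes all stages in dependency order and
writes every table plus a manifest (configuration hash, seeds, file list)
into a run directory; see the methods vignette
(`vignettes/pregvig-methods.Rmd`) for the models, conventions and their
rationale.

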