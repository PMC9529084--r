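---
title: "Methods: the matriscreen prioritisation pipeline"
author: "matriscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the matriscreen prioritisation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matriscreen)
```

## Scope and model

`matriscreen` implements a multi-stage screen for genes — in its motivating
use, matrisome (extracellular-matrix) genes — whose copy-number alteration,
expression change and survival association line up across cancer cohorts.
The screen is deliberately simple and auditable: each stage is a filter or a
rank with an explicit rule, and each rule is exposed as its own exported
function so it can be tested in isolation and recombined.

The stages, with their defaults:

* **Deep-event counting.** GISTIC-thresholded calls code −2 (deep
  deletion), −1 (shallow deletion), 0, +1, +2 (low/high-level gain). Only
  the extreme codes ±2 are counted as alteration events; shallow calls are
  treated as noise. Some data sources label +1 "amplification" and +2
  "gain", inverting the usual GISTIC nomenclature; whatever the labels, the
  procedure counts the extreme codes, and the simulator plants shallow ±1
  background precisely so that a wrong implementation that counted them
  would fail the tests.
* **Top-fraction selection** (`top_fraction`). The top
  `ceiling(fraction * n_genes)` genes per direction, default 5%. Ceiling is
  used because on a 1027-gene universe it yields 52 genes per direction
  (floor would give 51), the convention adopted throughout. Ties at the
  selection boundary are all included — deterministic and order-independent;
  genes with zero events are never selected even when the nominal cut would
  reach them, since selection is among altered genes. Whether the per-cancer
  5% should be taken over the full universe or only over genes altered in
  that cancer is genuinely ambiguous; the package computes 5% of the input
  universe, and callers wanting the other reading can pre-filter the counts
  table.
* **Differential expression** (`tumour_vs_normal`,
  `anchor_stratified_deg`). Welch's two-sample t on log2(TPM+1)-like
  values, the conservative default when variances differ between groups; a
  Wilcoxon option is provided (`deg_test = "wilcoxon"`). "Fold change > 2"
  is interpreted as |log2FC| ≥ 1 computed as a difference of means on the
  log2 scale. Calls use raw p-values at α = 0.05, because the screen's
  stage-wise thresholds are defined that way; a Benjamini–Hochberg FDR
  column is emitted alongside for transparency but does not drive the
  calls.
* **Percentile stratification** (`assign_groups`). "High" is strictly
  above the 75th empirical percentile and "low" strictly below the 25th,
  with the middle half excluded — the custom-cutoff convention of
  GEPIA2-style survival screens. Both cutoffs are parameters, so the
  alternative reading (top 75% of samples vs bottom 25%) is one argument
  away. Values tied exactly at a percentile boundary fall in "excluded"
  (neither strictly above nor below), a deterministic, order-independent
  rule; with equal cutoffs the split degenerates to a two-way cut with ties
  going low.
* **Survival statistics** (`logrank_test`, `cox_univariate`,
  `cox_subgroup`). The log-rank test uses the standard O−E formulation
  with the hypergeometric variance for tied event times; the Cox fits use
  the Efron tie approximation (more accurate than Breslow when event times
  are discrete). Subgroup hazard ratios are fitted separately within each
  race or gender level — one HR per level, not a simultaneous
  multivariable adjustment — because that is the presentation the screen's
  per-subgroup tables call for. Significance classification of a cancer as
  "affecting survival" uses the log-rank p-value.
* **Breadth and scoring** (`percent_affected`, `rank_scores`,
  `combined_score`). A gene's expression breadth is
  `100 * k / n` (cancers significantly concordant over cancers analysed,
  reported to two decimals), similarly for survival. Each breadth vector is
  competition-ranked (top gene scores 1; tied values share the minimal
  position of their block, since bars of equal height have no defined
  order; the next distinct value resumes at its actual position) and the
  two ranks are summed. Up- and downregulated genes are ranked in separate
  tables, never mixed. Genes with a breadth defined in only one of the two
  graphs are dropped rather than penalised, and the drop is visible in the
  output. Alphabetical tie-breaks make every table deterministic.
* **Validation battery** (`spearman_anchor`, `stage_anova`,
  `cooccurrence_test`, `hub_rank`, `criteria_intersect`). Spearman
  correlation with two-sided p; one-way ANOVA across tumour stages with
  sub-stages collapsed to their parent (IIIa → III; the collapsing rule is
  the package's choice, as sources rarely state theirs); co-occurrence via
  a 2×2 table of joint alteration status with a Haldane–Anscombe +0.5
  correction whenever a cell is zero (keeping the log2 odds ratio finite,
  as a bar-plot statistic must be) and a two-sided Fisher exact p by the
  point-probability method; hub ranking by degree within the
  candidate-induced subgraph, the cytoHubba "Degree" criterion. A sample
  counts as altered when its GISTIC call is ±2 (`alter_on = "deep"`), with
  `"any"` and an explicit mutation flag available since alteration
  definitions differ between portals.

## The pan/individual combination

`run_prioritization` mirrors the two-track design: a pan-cancer track
(pooled call matrix → top 5% per direction → concordance → breadth →
rank-sum score) and an individual-cancer track (per-cancer shortlist →
per-cancer concordance → per-cancer survival screen). The final selection
is their intersection: pan-shortlisted concordant genes hitting at least
two individual cancers. Pooling alone is sensitive to a few
heavily-altered cohorts; recurrence across individual cancers alone admits
genes with no aggregate signal; requiring both is what gives the screen
its specificity, and the null-cohort tests quantify that (see below).

Pan-cancer concordance needs each shortlisted gene classified up, down or
no-change overall. The package classifies by majority vote over the
gene's *significant* per-cancer calls (up if strictly more cancers call it
significantly up than down, and at least one does; symmetric for down).
This keeps the classification on the same per-cancer evidence the breadth
statistic uses, rather than re-testing on a pooled sample mixture whose
composition is an artefact of cohort sizes.

## The cohort simulator

`simulate_cohort` generates the statistical structure the screen assumes,
with known ground truth:

* GISTIC calls: per gene and tumour sample, deep events with the gene's
  amplification/deletion probability (drivers elevated, background 0.02
  split between −2 and +2) plus shallow ±1 noise at 0.10 on otherwise
  neutral samples.
* Expression, directly on the log2(TPM+1)-like scale so that planted
  effects are interpretable in log2 units: normals draw
  `baseline + N(0, 0.8)`; tumours add `cna_coupling × call`
  (default 0.5 log2 per GISTIC step), the driver shift, and a per-stage
  trend; values are floored at zero.
* Survival: exponential times with hazard
  `baseline_hazard × exp(Σ γ_g z_g)` over the drivers' within-cancer
  expression z-scores, censored by an independent uniform time over a
  study window solved numerically to hit the target censoring fraction
  (default 30%); no particular censoring mechanism is canonical, and
  independent-uniform keeps the censoring non-informative.
* A 2×2-exact co-occurrence planter (`simulate_cooccurrence_pair`): the
  joint-positive cell is the admissible root of the quadratic implied by
  the marginals and target odds ratio, so the planted odds ratio is exact
  in distribution.
* An interaction edge list containing the complete clique over the driver
  genes (confidence 0.9) plus random background edges, giving hub-recovery
  tests a known answer.

Default study conditions used by the test suite and the acceptance script:
5 cancers × 100 tumour/40 normal samples × 150 genes for pipeline-level
checks, with one driver at amplification probability 0.3, expression shift
+1.5 log2, and log hazard ratio 0.7 in 3 of the 5 cancers; 500 genes at
60 tumour/30 normal for calibration; n = 500 and 100 replicates for
hazard-ratio recovery; n = 10⁴ and 20 seeds for odds-ratio recovery. These
sizes give each stage comfortable power (a +1.5 log2 shift at n = 100/40
and noise 0.8 is detected essentially always; a log HR of 0.7 over a
~2.2-z-score group gap yields group hazard ratios near 5) while keeping a
full 50-replicate pipeline experiment in the low minutes on one core.

What the simulator does **not** emulate: copy-number segment structure
(calls are independent across genes), tumour purity, batch effects,
library-size artefacts, correlated expression beyond the planted channels,
and non-proportional hazards. Passing tests therefore demonstrate that the
implementation applies its stated rules correctly and recovers effects
under its stated model — not that the model captures everything in real
tumour data.

## Numerical and degenerate-input choices

* Missing GISTIC calls are rejected outright (the error says so): silent
  imputation would corrupt event counts invisibly.
* Welch tests on two zero-variance groups: p = 1 when the means are equal,
  p = 0 otherwise.
* Log-rank with no events in either group: p = 1 by convention, with a
  warning.
* Cox non-convergence or complete separation yields a flagged row
  (`converged = FALSE`, missing CI), never an exception, so cohort-wide
  screens don't die on one degenerate gene.
* Constant expression vectors: group assignment and correlation refuse
  them explicitly (error and not-evaluable record respectively).
* STRING-style 0–1000 integer confidences are auto-detected (any score
  > 1) and rescaled to [0, 1]; reciprocal duplicate edges collapse to the
  highest-confidence record.
* Gene lists are plain text, one symbol per line — diff-able and
  dependency-free; duplicates are dropped (keeping first occurrence) with
  a warning.

## Calibration and recovery, as computed here

The test suite and `scripts/acceptance.R` verify, among others: the
top-5%-of-1027 arithmetic (52 + 52 = 104); `percent_affected(17, 52) =
32.69` and `(23, 52) = 44.23`; null rejection rates of the expression,
log-rank and stage screens inside the 99% binomial band around α = 0.05
over 500 genes (the Fisher co-occurrence screen is held to the band's
upper bound only, exact tests on discrete tables being conservative);
mean recovered log HR within ±0.15 of 0.7; mean recovered log2 odds ratio
within ±0.3 of 2; and the planted driver as the unique final selection in
≥ 90% of 50 seeded pipeline runs with null cohorts producing a non-empty
selection in ≤ 10%. Exact-oracle tests check the log-rank statistic
against hand-enumerated risk-set tables, Fisher p-values against
exhaustive hypergeometric enumeration, Spearman rho against the
rank-difference formula, and hub degrees against adjacency recounts.

## Known limitations

* The screen's thresholds (5%, 75/25, |log2FC| ≥ 1, α = 0.05) are
  conventions, not optimised quantities; the package exposes them all but
  ships the conventional defaults.
* The "multivariate" subgroup analysis is per-level univariate Cox, not a
  simultaneously adjusted model; genuinely multivariable adjustment is out
  of scope.
* Count-based DE models (negative-binomial), normalisation from raw
  counts, paired designs, competing risks and time-varying covariates are
  out of scope.
* Cross-cohort reproduction of published gene lists requires the original
  portal data; the package reproduces the printed worked numbers and the
  full logic on simulated cohorts instead.
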