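---
title: "Co-expression-network-based prognostic modeling for censored outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-expression-network-based prognostic modeling for censored outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcnsurv)
```

## The problem

Prognostic gene panels for relapse-free survival (RFS) are usually built
from a fixed list of candidate genes — genes recurrently significant in
earlier differential-expression studies. That list is a bottleneck: a
gene whose expression drives relapse but that never made a
differential-expression shortlist is invisible to any model whose
candidate pool is the shortlist itself. `gcnsurv` implements an
alternative: treat the candidate genes as *seeds*, expand the pool with
every gene strongly rank-correlated with a seed in the relapse stratum
(a genetic co-expression network, GCN), and let censoring-aware model
selection decide which pool members carry independent prognostic signal.

The package covers the whole path: preprocessing of expression matrices,
network construction, stepwise Cox panel selection, partial-Cox risk
scores, censoring-aware evaluation, a meta-selection step ("stepwise
network modeling", SNM), a constraint-based causal skeleton over the
selected panel, and a calibrated simulator that generates cohorts with
known ground truth so every stage can be validated end to end.

## Preprocessing

Expression data are log2-scale matrices in genes x samples orientation.
Three standard steps are provided:

* `collapse_probes()` — per-sample median over a gene's probes.
* `quantile_normalize()` — every sample is forced onto the mean
  order-statistic distribution. Tied values within a sample receive the
  mean of the quantile values they span; this "ties = average" dialect
  is deterministic, order-independent, and makes the operation
  idempotent.
* `align_to_reference()` — pooled empirical-quantile mapping of one
  dataset's values onto a designated reference dataset's distribution, a
  monotone transform that removes cross-platform location/scale
  differences while preserving every within-sample ranking. When several
  cohorts are merged, the intended order is: per-dataset quantile
  normalization first, then alignment of each remaining dataset to the
  chosen reference. (Alignment after merging is also possible by calling
  the function on the merged matrix; the per-dataset default reflects
  that batch differences are per-dataset phenomena.)

Missing expression values are rejected rather than imputed — no
imputation scheme is part of the method, and silently imputing would
change the rank statistics everything downstream depends on.

## Network construction

`spearman_profile()` correlates each seed with every gene (Spearman,
midrank ties) over a sample stratum — by convention the relapse stratum,
since co-regulation under relapse is the signal of interest.
`build_gcn()` keeps seed-gene pairs with `|rho|` at or above a
threshold, then applies a top-2 pruning rule: each node nominates its
two strongest incident candidate edges (by `|rho|`, ties broken by
partner identifier) and an edge survives if *either* endpoint nominates
it. Two consequences are worth knowing:

* The rule is monotone in the threshold: the edge and node sets at a
  higher threshold are always subsets of those at a lower threshold,
  because newly admitted edges at a lower threshold are weaker than
  every previously admitted edge and so cannot displace one from a
  node's top two. Pools at thresholds 0.82 / 0.80 / 0.79 are therefore
  nested by construction.
* "Strongest" means `|rho|`: strong negative co-expression qualifies.
  A signed-only variant is available (`use_abs = FALSE`) for users who
  want positive co-regulation only.

Useful thresholds are data-dependent (they control how many times larger
than the seed set the network becomes), so the package exposes the
threshold as a parameter rather than hard-coding a ladder; 0.82, 0.80
and 0.79 are sensible defaults for arrays of ~10^4 genes and a relapse
stratum of a few hundred samples.

## Panel selection: stepwise Cox with SLE/SLS and a VIF guard

`stepwise_forward()` is a deterministic forward-selection loop on the
Cox partial likelihood (Efron ties by default, matching the common
`coxph` default): among candidates outside the model, the one with the
smallest Wald p inside the augmented model enters if p <= SLE (default
0.08) *and* its variance inflation factor in the augmented design is
below 10; after each entry, any non-mandatory covariate with Wald
p > SLS (default 0.05) is removed, worst first. Lymph-node status is a
mandatory covariate — present from step 0, exempt from removal — because
node positivity is the one clinical factor consistently available and
strongly prognostic; samples missing it are dropped with a recorded
count. The VIF guard is what lets co-expressed pools work at all: block
partners are nearly collinear with their seeds, and without the guard
the selection would enter redundant copies.

Two details are deliberate choices where the procedure is conventionally
underspecified: the entry statistic is the Wald test of the candidate in
the augmented model (one fit per candidate, no score-test shortcut), and
a candidate blocked by VIF is skipped for the current pass but retried
after the design changes. Removed genes do not re-enter, which
guarantees termination.

## Partial-Cox risk scores

`fit_partial_cox()` condenses a selected panel into mutually
uncorrelated prognostic components, in the spirit of partial least
squares adapted to censored outcomes: genes are centered; at each step
the component is the unit-norm combination of current residual genes
weighted by their univariable Cox coefficients; every gene is then
residualized on the component before the next step. Residualization
makes the in-sample component scores exactly orthogonal — the binding
contract, asserted on every fit at |r| < 1e-6 — regardless of the
weighting details. Components with univariable Cox p < 0.05 are
retained (`select_components()`); their joint Cox fit gives the
coefficients of the risk score

    score_i = sum_k beta_k * chi_ik .

Since every component has training mean zero, zero is the natural
cut-off: `risk_score()` labels samples `high` (score > 0) or `low`. The
default of at most five components is a pragmatic cap — panels here have
at most a few dozen genes and selection at p < 0.05 prunes further; the
count is a parameter, not a tuned constant. New samples are centered
with the *training* means stored in the model, so external validation
data can be scored without refitting. If no component passes selection
the default behaviour keeps the single smallest-p component with a
warning (an errorring variant is available), because a pipeline that
returns no score at all is rarely what an analyst wants from a weak
panel.

A note on the model form: the component-level proportional-hazards model
is sometimes written with an intercept inside the exponential; a Cox
partial likelihood cannot estimate such an intercept (it is absorbed
into the baseline hazard), so the implementation has none.

## Model pipeline and SNM

`build_reference_model()` (pool = seeds only) and `build_gcn_model()`
(pool = network nodes plus seeds at a given threshold) run the same
stepwise + partial-Cox tail, so differences between them isolate the
effect of the candidate pool. Pools are built from the relapse-stratum
network; the no-relapse network can be computed and exported but does
not feed pools. Seeds are always included in every pool. `snm()` pools
the final genes of several fitted models and keeps those passing a
node-adjusted univariable filter — p < 0.001 and hazard ratio above 1.5
or below 0.7, strict inequalities, so boundary values fail — then refits
the same tail on the survivors. The filter is monotone: relaxing either
rule can only grow the passing set.

## Evaluation under censoring

* `horizon_labels()` / `horizon_metrics()` — at horizon t, samples are
  `event_by_t`, `event_free_at_t` (follow-up reaches t; reaching exactly
  t counts as event-free), or `inevaluable` (censored before t,
  excluded — their status is unknown and any imputation would bias the
  comparison). AUC is rank-based concordance with ties at 1/2 and a
  Hanley–McNeil interval; accuracy classifies at probability 0.5 from a
  logistic fit of label on score (a Youden-threshold variant would be
  data-dependent and is intentionally not the default).
* `time_dependent_auc()` — cumulative/dynamic AUC with inverse
  probability of censoring weights from the Kaplan–Meier estimate of
  the censoring distribution (left limits at event times). With no
  censoring it equals the uncensored horizon AUC exactly.
* `prediction_error()` — IPCW Brier curve, with predicted survival
  either supplied or derived from a Cox fit on the score with a Breslow
  baseline.
* `univariable_or()` — exact cross-product odds ratios (equal to
  exponentiated univariable logistic coefficients) with Wald p-values,
  for clinical contingency tables; reference levels are explicit (node
  negative, grade 1, ER negative for the bundled cohort tables). Zero
  cells are flagged, not continuity-corrected.

## Causal skeleton over the selected panel

`pc_skeleton()` implements the PC-stable variant (neighbor sets
snapshotted per conditioning order, so the output is invariant to gene
input order — a requirement for reproducible pipelines) with Fisher-z
partial-correlation tests, `z = atanh(r) sqrt(n - |S| - 3)`, at alpha
0.01 and conditioning sets up to size 3 — panels here are small (~10–40
genes), and order-3 separation suffices at that scale.
`orient_edges()` adds v-structures (a collider is oriented when the
middle node is absent from its pair's separating set; conflicting
demands cancel and the edge stays undirected) and closes under the Meek
rules, yielding a CPDAG — a Markov equivalence class, not a unique DAG.
`gene_importance()` ranks genes by their share of the Wald chi-square
within each model (shares sum to one per model), summed across models;
the top genes are the natural nodes for the pathway graph.

## The simulator and what passing tests mean

`simulate_cohort()` generates what the analysis assumes: Gaussian
log-expression; block partners sharing a latent factor with their seed,
with the factor loading set by the Gaussian-copula identity
`r = 2 sin(pi rho_s / 6)` so the *Spearman* target is hit analytically
rather than by rank shuffling; relapse times from a proportional-hazards
model (exponential baseline by default, Weibull available); independent
exponential censoring whose rate is solved numerically so the expected
censored fraction, given the drawn event times, equals the target —
configs speak in the observable quantity (fraction censored), not a
rate parameter; and optional additive per-dataset mean shifts emulating
cross-cohort batch structure.

Defaults encode the cohort conditions the pipeline targets: 900
samples, 34 seed genes, a 38% event fraction (censoring target 0.62),
12% node-positive prevalence with node log-HR 0.7, and an exponential
baseline rate of 0.08/year (median event time ~8.7 years at the
baseline, matching follow-up spans of 0–15 years).
`make_paper_like_scenario()` fixes the canonical hidden-signal design:
300 genes (a desk-scale stand-in for ~13,000-gene arrays — large enough
for realistic network pruning and spurious-candidate pressure, small
enough for hundred-replicate experiments), three prognostic non-seed
genes (log-HR 0.7) placed in Spearman-0.85 blocks of seeds, one
modestly prognostic seed (log-HR 0.4), and six non-prognostic decoy
blocks at Spearman 0.80. On these cohorts the 0.82-threshold network
model beats the seed-only reference on 3-year-horizon AUC in well over
90% of replicates — the mechanism the method exists to exploit,
reproduced with known ground truth.

What the simulator does *not* emulate: heavy-tailed platform noise,
probe-level artifacts, realistic pathway topology, informative
censoring, or correlated clinical covariates. Passing tests therefore
demonstrate that the estimators are correct and that the pipeline
recovers planted structure under its own assumptions — not that any
particular threshold or panel generalizes to a given real cohort.

## Numerical choices and limitations

* Cox fits iterate to relative log-likelihood change < 1e-9 (at most
  100 iterations); runaway coefficients or non-finite information flag
  the fit as non-converged rather than erroring mid-selection.
* Exact collinearity yields infinite VIF, which always blocks entry.
* All tie-breaks (edge nominations, stepwise entry order, gene unions)
  fall back to lexicographic identifiers, so every pipeline stage is
  deterministic given the data.
* Identifiers are case-sensitive exact strings; no symbol mapping is
  attempted.
* The stepwise procedure inherits the usual caveats of forward
  selection (p-values of the final model are optimistic; the SLE/SLS
  levels are screening devices, not error guarantees), and the partial-
  Cox components are uncorrelated in-sample only.
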