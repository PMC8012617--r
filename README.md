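# gcnsurv

Prognostic modeling of censored relapse outcomes from gene expression,
built around genetic co-expression networks (GCNs). The package is for
analysts building relapse-free-survival (RFS) gene panels from
microarray/RNA expression cohorts who suspect that a fixed candidate
list misses prognostic genes, and for methodologists who want every
stage of such a pipeline testable against synthetic cohorts with known
ground truth.

## The method

Starting from a set of seed genes (e.g. 34 candidates recurrently
significant in earlier signatures), the pipeline:

1. **Expands the candidate pool by co-expression.** Spearman
   correlation of each seed with every gene over the relapse stratum;
   genes with |ρ| ≥ r form candidate edges, and each node keeps its two
   strongest edges (an edge survives if either endpoint nominates it).
   Pools at r = 0.82 / 0.80 / 0.79 are nested by construction.
2. **Selects a panel by stepwise forward Cox regression** on the pool,
   with significance-to-enter SLE = 0.08, significance-to-stay
   SLS = 0.05, a variance-inflation guard VIF < 10, and lymph-node
   status as a mandatory covariate.
3. **Condenses the panel into a risk score by partial Cox regression**:
   mutually uncorrelated components χ_k (univariable-Cox-weighted,
   residualized), components kept at p < 0.05, and

       score_i = Σ_k β_k χ_ik ,

   with patients split into high/low risk at the zero cut-off (each
   component has training mean zero).
4. **Evaluates under censoring**: horizon accuracy/AUC at 3/5/10/15
   years, IPCW time-dependent AUC and Brier curves, and node-adjusted
   hazard ratios of the risk score (continuous and high-vs-low).
5. **SNM (stepwise network modeling)**: pools the final genes of
   several models, filters at univariable p < 0.001 and HR > 1.5 or
   < 0.7 (node-adjusted), and refits — a compact panel from the union
   of model evidence.
6. **Explores structure**: PC-stable causal skeleton + CPDAG
   orientation (Fisher-z tests, α = 0.01) over the top genes ranked by
   their share of model Wald χ².

A calibrated simulator (`simulate_cohort()`,
`make_paper_like_scenario()`) generates cohorts matching the assumed
structure — Spearman-targeted seed blocks via the Gaussian-copula
identity, proportional-hazards relapse times, censoring calibrated to a
target rate — so the whole pipeline is validated end to end with known
truth.

## Worked example

```r
library(gcnsurv)

sc <- make_paper_like_scenario(1)        # 900 samples, 300 genes, truth known
seeds <- sc$truth$seeds

ref <- build_reference_model(seeds, sc$expr, sc$surv)   # seed-only pool
net <- build_gcn_model(0.82, seeds, sc$expr, sc$surv)   # network pool
net
#> prognostic model [gcn@0.82]: pool 49 gene(s) -> 7 selected
#>    G0001, G0004, G0005, G0009, SEED01, SEED04, SEED34

lab <- horizon_labels(sc$surv, 3)
horizon_metrics(ref$scores, lab)$auc
#> [1] 0.804814
horizon_metrics(net$scores, lab)$auc
#> [1] 0.8453037
```

The scenario hides most prognostic signal in non-seed genes (G0001,
G0005, G0009) that are Spearman-0.85 partners of seeds: the seed-only
model can see them only through attenuated proxies, while the
0.82-threshold network model admits them into its pool, selects them,
and gains ~0.04 of 3-year-horizon AUC. `snm()` then compresses the
union of both panels, and `evaluate_model()` produces the full
per-horizon report with time-dependent curves and risk-group hazard
ratios.

Published contingency tables ship with the package for the univariable
clinical odds ratios:

```r
tabs <- clinical_cohort_counts()
univariable_or(tabs$node, reference = "Negative")
#> univariable odds ratios (reference: Negative)
#>                OR            p
#> Positive 1.830319 1.173205e-05
```

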