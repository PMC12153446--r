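# symptomnet

Symptom-network analysis for anxiety–depression comorbidity in ordinal
screening data. The package is written for epidemiologists and
psychometricians working with participant-by-item tables from the GAD-7
(7 anxiety items) and CES-D-10 (10 depression items), both coded 0–3 —
the typical shape of community-survey mental-health data on, for example,
older adults living alone. Instead of total scores, it estimates the
item-level conditional association network and asks which symptoms are
most central and which ones bridge the two disorders.

## What it computes

1. **Cohort screening** — staged exclusion cascade (missing
   demographics or >1/3 of the 17 items; any missing GAD-7 item; any
   missing CES-D item; disjoint first-stage attribution), scale scoring
   with the conventional cutoffs (CES-D ≥ 10, GAD-7 ≥ 5), per-item
   descriptives and flag prevalences.
2. **Network estimation** — a Gaussian graphical model on the
   PSD-smoothed Spearman matrix via the graphical lasso
   (off-diagonal L1 penalty, block coordinate descent in compiled code),
   with λ selected by the extended BIC
   `EBIC = −2L + E log n + 4γE log p` (γ = 0.5 default, γ-sensitivity
   helper included; a 10-fold cross-validated EBIC mode is provided as a
   cross-check). Edge weights are partial correlations
   `w_ij = −θ_ij / √(θ_ii θ_jj)`.
3. **Centrality** — expected influence `EI_i = Σ_j |w_ij|` and bridge
   expected influence `BEI_i = Σ_{j in other community} w_ij`, with
   deterministic ranks.
4. **Stability** — nonparametric bootstrap edge CIs (λ re-selected in
   every resample), bootstrapped difference tests for edges and
   centralities, case-dropping subset bootstrap with the
   correlation-stability (CS) coefficient.
5. **Reporting** — Fruchterman–Reingold layout, figure with
   machine-readable sidecars, combined descriptive/centrality table.
6. **Synthetic data** — a latent-copula ordinal generator around a
   planted sparse partial-correlation network (two communities, four
   cross-community bridges at 0.34/0.28/0.13/0.12, skewed item
   marginals), plus exact-count screening fixtures and recovery metrics,
   so every stage is testable against ground truth.

See `vignettes/symptomnet-methods.Rmd` for the model, the assumptions,
and the measured effects of ordinal attenuation on recovery.

## Worked example

```r
library(symptomnet)

truth <- make_ground_truth()                 # planted 17-node network
X     <- sample_ordinal(truth, n = 2000, seed = 7)

fit <- select_network(X)
fit$model
#> Partial-correlation network model
#>   17 nodes (anxiety: 7, depression: 10), 31 edges
#>   lambda = 0.06426, gamma = 0.5
#>   |weight| range: 0.000 .. 0.278

head(cross_community_edges(fit$model), 4)
#>    node_a node_b     weight
#> 10   GAD1 CESD10 0.20004755
#> 5    GAD3  CESD4 0.15958015
#> 3    GAD6  CESD3 0.08727927
#> 8    GAD4  CESD8 0.04262599

cs <- case_drop_bootstrap(X, selection_config(n_lambda = 40),
                          boot_config(n_boot = 25, seed = 7))
cs
#> Correlation-stability (CS) coefficients from case-dropping bootstrap
#>   EI   CS = 0.75  [robust (> 0.50)]
#>   BEI  CS = 0.75  [robust (> 0.50)]
```

The four recovered cross-community edges are the planted bridges, in the
planted order; their weights are smaller than the latent 0.34/0.28/0.13/
0.12 because 4-category skewed items attenuate rank correlations and the
lasso shrinks — which is exactly what the CIs and the vignette's
calibration discussion are about. A CS of 0.75 (the top of the drop grid)
means centrality orderings survive dropping 75% of cases.

File-based runs: `run_pipeline(default_config(seed = 1), "out/")`
executes screen → correlate → estimate → stability → report and writes
every artifact with a hashed manifest; a thin CLI wrapper lives at
`inst/scripts/symptomnet.R`
(`Rscript inst/scripts/symptomnet.R --out out --seed 1 [--stage screen]`).

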