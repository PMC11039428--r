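# symbmeta

Phylogenetically informed multilevel meta-analysis of symbiont fitness.

Experiments across many host–symbiont systems measure a symbiont fitness
proxy (CFU, counts, density, nodule number, colonized area, growth rate,
survival) under two conditions — in symbiosis vs. free-living, benign vs.
perturbed environment, younger vs. older host. `symbmeta` is for
researchers synthesizing such two-group contrasts across studies while
accounting for the shared ancestry of the organisms involved. It provides:

* **Effect sizes** — the percent change in symbiont fitness,
  `pc = 100 (x̄_control − x̄_alt) / x̄_control`, with a first-order
  delta-method sampling variance
  `v = 100² r² (SE_c²/x̄_c² + SE_a²/x̄_a²)`, `r = x̄_a/x̄_c`, and a
  sign-preserving cube-root transform of both (`y = sign(pc)|pc|^(1/3)`,
  `v → v^(1/3)`) to tame effect sizes spanning orders of magnitude.
* **Phylogenetic correlation** — Brownian-motion correlation matrices from
  newick trees (shared root-to-tip path length, normalized for possibly
  non-ultrametric depths), plus the tree surgery used in practice: stand-in
  tip substitution, population-level tip expansion at distance
  ε ≪ 10⁻⁵, and distance-preserving pruning.
* **The model** — `y_i = x_iᵀβ + u_study + b_i + p_tip + e_i`, with
  between-study, within-record and phylogenetic variance components
  estimated by REML under known heteroscedastic sampling variances
  `e_i ~ N(0, v_i)`; Wald z tests per coefficient and the omnibus
  QM = β_bᵀ Σ_bb⁻¹ β_b ~ χ²(k−1) moderator test.
* **Influence screening** — leave-one-out Cook's distances with the
  strict `D > 3 × mean(D)` removal rule, one pass, with both fits reported
  side by side.
* **A synthetic-data generator** — pure-birth trees and effect-size tables
  with known truth, back-solved to raw two-group summaries so the entire
  pipeline is testable end to end without any download.

The core machinery (REML fit, QM tests, Cook's distances) is implemented in
the package itself; the test suite cross-checks it against
`metafor::rma.mv` and against brute-force dense-algebra and Monte-Carlo
oracles.

## Worked example

Simulate a "time" corpus (younger vs. older hosts) with a known negative
overall effect and a host-life-stage moderator, then run the full analysis:

```r
library(symbmeta)

truth <- simulation_truth(
  beta0 = -0.9, n_studies = 25, effects_per_study = c(1, 3),
  n_tips = 35, analysis = "time", seed = 11,
  moderators = list(host_life_stage = list(
    type = "categorical", levels = c("adult", "juvenile", "mixed"),
    effects = c(adult = 0, juvenile = 0.8, mixed = 0.2))))
sim <- simulate_dataset(truth)

report <- run_analysis(analysis_config(
  "time", dataset = sim$records, tree = sim$tree,
  moderators = "host_life_stage"))

print(report$overall)
#> Multilevel meta-analytic model (REML), n = 50
#> Variance components:
#>  study within  phylo
#> 0.3252 1.7024 0.0000
#>         estimate   se    zval pval
#> intrcpt  -1.2469 0.27 -4.6185    0

print(report$moderators$host_life_stage)
#> Multilevel meta-analytic model (REML), n = 50
#> Variance components:
#>  study within  phylo
#> 0.3607 1.6620 0.0000
#>                         estimate     se    zval   pval
#> intrcpt                  -1.5754 0.4125 -3.8194 0.0001
#> host_life_stagejuvenile   1.0136 0.7186  1.4105 0.1584
#> host_life_stagemixed      0.3295 0.5508  0.5983 0.5496
#> QM = 1.9920, df = 2, p = 0.3694

print(report$influence)
#> Cook's distance screen: mean D = 0.01887 threshold (3x mean) = 0.0566
#> 4 of 50 record(s) flagged (5, 12, 29, 43)
```

Reading it: the overall intercept on the cube-root scale is −1.25
(z = −4.62, p < 0.001) — symbiont fitness is significantly greater in
older hosts in this simulated corpus, consistent with the generating
intercept of −0.9 plus a juvenile-stage shift. The life-stage moderator
does not reach significance here (QM = 1.99, df = 2, p = 0.37), and the
conclusion survives the outlier screen (z = −4.66 after removing the four
flagged records).

## The analysis workflow

The numbered scripts under `analysis/` run the study end to end and write
their tables under `results/`:

1. `01_simulate_corpus.R` — builds the working corpus (synthetic, with
   known truth, in the same schema as the archived deposit).
2. `02_effect_sizes.R` — recomputes effect sizes and variances from raw
   two-group summaries and verifies them against the carried values.
3. `03_fit_models.R` — overall and moderator models for the three
   analyses, plus the intracellular subset under both aggregation
   conventions.
4. `04_outlier_sensitivity.R` — the with/without-outliers table and which
   conclusions are stable.
5. `05_recovery_and_calibration.R` — parameter recovery at the reference
   design and QM null calibration.

The methods vignette
(`vignettes/symbiont-fitness-meta-analysis.Rmd`) documents the model, the
numerical choices and the generator's scope.

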