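---
title: "Phylogenetic multilevel meta-analysis of symbiont fitness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic multilevel meta-analysis of symbiont fitness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbmeta)
```

## The scientific problem

Whether symbionts themselves profit from living with a host is an open
question in symbiosis research. Individual experiments measure a symbiont
fitness proxy — colony-forming units, cell counts, density, nodule number,
colonized area, growth rate, survival — under two conditions: in symbiosis
versus free-living, a benign versus a perturbed environment, or younger
versus older hosts. `symbmeta` implements the full quantitative pipeline for
synthesizing such two-group contrasts across studies: a ratio-of-means
effect size on a common percent scale, a multilevel random-effects model
that respects both the study structure and the phylogenetic relatedness of
the symbionts (or hosts), omnibus moderator tests, and an influence screen.

## Effect sizes

Each record contributes the percent change in symbiont fitness,

$$\mathrm{pc} = 100\,\frac{\bar{x}_{\mathrm{control}} - \bar{x}_{\mathrm{alt}}}{\bar{x}_{\mathrm{control}}},$$

where the control condition is the reference state (in symbiosis, ambient
environment, younger host). Positive values mean fitness is greater in the
reference state. The quantity is bounded above by 100 for non-negative
fitness measures but unbounded below, which is why heavy left tails appear
whenever the alternative condition favors the symbiont by orders of
magnitude.

The sampling variance is the first-order delta-method variance of a ratio
of two independent means: with $r = \bar{x}_a/\bar{x}_c$ and squared
standard errors $SE_c^2, SE_a^2$,

$$v_{\mathrm{pc}} = 100^2\, r^2 \left(\frac{SE_c^2}{\bar{x}_c^2} +
  \frac{SE_a^2}{\bar{x}_a^2}\right).$$

The package's tests hold this expression against a $10^6$-draw Monte-Carlo
oracle. The first-order expansion is accurate to well under 5% when the
coefficient of variation of each mean is below about 0.1; the truncation
error grows like $3\,\mathrm{CV}^2$ of the denominator mean, so records with
very noisy control means carry an approximation error that no closed-form
ratio variance avoids. Records with a zero control mean are rejected rather
than continuity-corrected; records with negative means are flagged with a
warning, since fitness proxies are non-negative by construction.

Because a handful of percent changes are orders of magnitude larger than
the rest, both the effect and its variance are cube-root transformed with
the sign preserved: $y = \mathrm{sign}(\mathrm{pc})\,|\mathrm{pc}|^{1/3}$,
$v = v_{\mathrm{pc}}^{1/3}$. Cube-rooting a *variance* is unusual — the
transformed `v` is not the delta-method variance of `y` — but it is the
convention this pipeline reproduces, and it is applied literally by
default. For sensitivity analysis, `transform_effect(..., variance_mode =
"delta")` propagates the variance to the transformed scale properly,
$v' = v_{\mathrm{pc}} / (9\,|\mathrm{pc}|^{4/3})$, guarded by a floor on
$|\mathrm{pc}|$ as the derivative blows up at zero. Likewise the percent
(×100) scale is the default, with a fraction-scale switch.

## Phylogenetic correlation

Related symbionts may respond similarly, so effect sizes are not
independent across species. Under a Brownian-motion model of trait
evolution the covariance between two tips equals the branch length they
share on their root-to-tip paths — the depth of their most recent common
ancestor. `bm_correlation()` normalizes by $\sqrt{C_{ii}C_{jj}}$, so
non-ultrametric trees (common when trees come from taxonomy databases) are
handled without assuming equal depths, and rescaling all branch lengths
leaves the matrix unchanged. Polytomies need no resolution: the shared-path
definition applies directly.

Tree plumbing mirrors how such trees are prepared in practice:

* `substitute_tips()` relabels a designated close relative to stand in for
  a species missing from the source tree; topology and lengths are
  untouched, so distances among all other tips are preserved.
* `expand_populations()` replaces a species tip with a polytomy of
  population-level tips on pendant branches of $\epsilon/2$ (default
  $\epsilon = 10^{-6}$, and required to be $\ll 10^{-5}$), so that records
  from different studies of the same species remain distinguishable while
  correlating at essentially 1. The pendant construction changes any other
  pairwise distance by at most $\epsilon$.
* `prune_to()` takes the induced subtree with unary nodes suppressed and
  their lengths summed, preserving pairwise distances exactly.

A ridge option on the correlation matrix exists for near-singular
downstream solves; it defaults to off and announces itself when active.

## The multilevel model

On the transformed scale each record $i$ in study $s(i)$, mapped to tip
$t(i)$, is modeled as

$$y_i = \mathbf{x}_i^\top\boldsymbol\beta + u_{s(i)} + b_i + p_{t(i)} +
  e_i,$$

with $u_s \sim N(0, \sigma^2_{\mathrm{study}})$ i.i.d. per study,
$b_i \sim N(0, \sigma^2_{\mathrm{within}})$ i.i.d. per record,
$\mathbf{p} \sim N(\mathbf{0}, \sigma^2_{\mathrm{phylo}} R)$ with $R$ the
Brownian-motion correlation, and $e_i \sim N(0, v_i)$ with the sampling
variances $v_i$ treated as known — the standard meta-analytic assumption.
The marginal covariance is assembled exactly that way in
`marginal_covariance()`, and the restricted likelihood

$$\ell_R(\boldsymbol\sigma^2) = -\tfrac12\left[\log|M| +
  \log|X^\top M^{-1}X| + \mathbf{y}^\top P \mathbf{y} +
  (n-p)\log 2\pi\right]$$

is maximized over the non-negative components. (Some implementations add a
constant $\tfrac12\log|X^\top X|$ to this criterion; the package's tests
account for that when cross-checking against `metafor::rma.mv`, with which
the estimates, standard errors, variance components and QM statistics agree
to optimizer tolerance.)

Numerical choices worth knowing:

* **Optimizer.** Bound-constrained L-BFGS-B from three starting points —
  near-zero, a method-of-moments point that puts the excess residual
  variance on the within-record component, and an equal split across
  components — with an `nlminb` retry wherever the L-BFGS-B line search
  aborts on a flat boundary likelihood. The best converged solution wins;
  non-convergence from every start is an error carrying the best value
  found, never a silent result. Relative tolerance $10^{-8}$.
* **Known variances.** $v_i \le 0$ (degenerate source data) is floored at
  $10^{-10}$ with a warning so $M$ stays invertible.
* **Design.** Categorical moderators are dummy-coded against the
  alphabetically first level, keeping the intercept, so a $k$-level factor
  yields an omnibus Wald test $Q_M = \boldsymbol\beta_b^\top
  \Sigma_{bb}^{-1}\boldsymbol\beta_b \sim \chi^2_{k-1}$. The QM statistic
  is invariant to the reference level; the per-level $z$ values are not. A
  continuous moderator is centered and contributes one degree of freedom.
  Per-coefficient tests use the standard normal, two-sided, with no
  small-sample $t$/$F$ correction — matching the convention this pipeline
  reproduces. The Wald $Q_M$ with REML-estimated components is known to be
  mildly liberal at small $n$; the package's calibration suite quantifies
  this honestly rather than correcting for it.
* **Intercept-only models** report the overall effect through the Wald $z$
  of the intercept; `wald_tests()` refuses an empty moderator block.

With $\sigma^2_{\mathrm{phylo}}$ pinned at zero the fit is numerically
identical whether or not a correlation matrix is supplied; with all
components pinned at zero it collapses to the closed-form inverse-variance
fixed-effect estimate — both are frozen tests.

## Influence screening

`cooks_distances()` deletes one record at a time and measures the
fixed-effect displacement against the full-data coefficient covariance,
$D_i = (\hat\beta_{(-i)} - \hat\beta)^\top \Sigma_\beta^{-1}
(\hat\beta_{(-i)} - \hat\beta)$. Variance components are re-optimized for
every deletion by default — the standard definition for this model class —
with a fixed-components fast mode for large simulations (in the
fixed-effect limit that mode reproduces the brute-force leave-one-out
weighted-least-squares distances exactly). If a deletion empties a
moderator level, that record's distance is computed on the reduced,
estimable design with a note, rather than failing the whole screen.

The removal rule flags records with $D_i$ strictly greater than three
times the mean of all $D$ (the candidate included in the mean), refits once
on the retained set — a single pass, not iterated — and reports both fits
side by side, so every conclusion can be read with and without outliers.

## The pipeline

`run_analysis()` ties the stages together for one analysis subset (host
association, environment, time, or the intracellular-only environment
subset): compute effect sizes where raw summaries are given, subset,
optionally aggregate, substitute and prune the tree, expand it to
population-level tips keyed by record identifier, fit the overall model and
the moderator battery, screen outliers on the overall model, and repeat
every fit on the retained records. Moderators with fewer than two observed
levels in a subset are skipped with a recorded reason. Reports are
serialized as JSON and a markdown table, and embed input hashes, the
package version and the configuration, with no timestamps, so identical
inputs give byte-identical reports.

Two aggregation conventions handle symbionts contributing multiple effect
sizes: collapse per unique host–symbiont pairing or per unique symbiont,
each group replaced by its mean transformed effect. The aggregated
sampling variance is the mean variance divided by the group size (the
variance of a mean of independent effects) by default; a plain-mean
alternative is available, since the convention is not fully determined by
"mean effect size" alone. The phylogeny used as the random-effect
structure — symbiont or host tree — is a single configuration switch, so
both variants of every analysis are one flag apart.

## The synthetic-data generator

`simulate_tree()` draws a pure-birth tree and rescales it to unit depth;
`simulate_dataset()` layers study, record and phylogenetic effects with the
requested variances on a fixed intercept plus moderator effects, adds
sampling noise with known heteroscedastic variances, and then *back-solves*
raw two-group summaries (control mean 100, five replicates per group, equal
relative standard errors split across the two groups) whose percent change
and delta-method variance reproduce the transformed pair $(y_i, v_i)$
exactly — so the effect-size code path is exercised end to end, not
bypassed. Records whose implied percent change reaches 100 cannot be
realized with positive means; they are emitted on the transformed scale
only and flagged, never fabricated.

Default design sizes emulate a moderate synthesis corpus: 50 studies
contributing 1–5 effect sizes each, 60 symbiont species, comparable
between-study and within-study heterogeneity (1.0 each on the transformed
scale), a weaker phylogenetic component (0.5), and sampling variances
uniform on [0.5, 2]. Everything is deterministic per seed, with the
caller's RNG state restored.

What the generator does *not* emulate — and hence what passing tests do not
establish about real corpora: the taxonomic composition of any real study
set, publication bias, digitization error in source summaries, correlation
between moderators and phylogeny, non-normal random effects, and
misreported dispersions (SD versus SE — the schema carries an explicit
`disp_kind` flag precisely because silent misreading scales variances by
the replicate count).

## Validation experiments and problem sizes

The test suite and the acceptance script rerun, at fixed seeds:

* the $10^6$-draw Monte-Carlo check of the delta-method variance;
* brute-force shared-path oracles for the correlation matrix (30-tip
  trees) and dense-algebra oracles for the restricted likelihood, QM and
  Cook's distances;
* a null-calibration suite for the QM test — 1000 synthetic null datasets
  of 50 records in 25 studies with a three-level moderator, mild
  heterogeneity (both components 0.1) under dominant sampling variance
  (uniform on [0.5, 1.5]) — against the binomial 99% band around the
  nominal 0.05. With components fixed at truth the p-values are exactly
  uniform; with estimated components the test sits near the band's upper
  edge, the expected mild liberality of Wald tests at this scale;
* a parameter-recovery experiment at 80 studies × 5 records on 60 tips,
  averaged over 10 replicates: the single-replicate spread of the
  phylogenetic component is wide (few effective degrees of freedom at 60
  tips), so recovery is asserted on replicate means — which is the
  estimator property of interest — rather than on one draw.

These sizes were chosen to give each check clear resolution at desk scale;
`analysis/05_recovery_and_calibration.R` prints the same experiments
narratively.

## Known limitations

* The literal cube-rooted variance is not a delta-method variance on the
  transformed scale; inference on `y` treats it as known all the same.
  The `"delta"` mode exists to quantify how much this convention matters.
* The Wald/QM machinery has no small-sample correction, by design; near
  the boundary (tiny heterogeneity, few studies) expect mild liberality.
* The phylogenetic component is weakly identified against the
  within-record component unless the tree induces substantial off-diagonal
  correlation among sampled records.
* Aggregation assigns a group the metadata of its first record; continuous
  covariates that vary within a group (one symbiont in hosts with
  different generation times) must be resolved to a per-group column by
  the user — the pipeline will not guess.
* Trees are file inputs; no taxonomy service is consulted, and whatever
  branch lengths the input carries are taken at face value.
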