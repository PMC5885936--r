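---
title: "Group-level structural covariance networks from cortical thickness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-level structural covariance networks from cortical thickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thicknet)
```

## The model

A structural covariance network treats brain regions as nodes and
across-subject covariation of a morphometric measure — here, regional
cortical thickness — as evidence of an edge. Unlike functional or diffusion
connectivity, the graph is defined at the *group* level: one network per
diagnostic group, built from that group's subjects.

For a group with $n$ subjects, $p$ regions and $k$ nuisance covariates, the
pipeline is:

1. **Partial correlation.** Each region's thickness column is residualized
   by ordinary least squares on an intercept plus the covariates (age, sex,
   IQ, depression and trauma scores, medication status, or whatever the
   study controls). Entry $(i, j)$ of the group's matrix is the Pearson
   correlation of the residualized columns $i$ and $j$ — the partial
   correlation given the controls. This requires residual degrees of
   freedom $n - k - 2 \ge 1$, hence the package-wide guard $n \ge k + 3$.
2. **Positive-edge binarization at a matched wiring cost.** Only strictly
   positive partial correlations are edge candidates (negative thickness
   correlations are not considered evidence of direct connection). Edges
   are added in descending order of partial correlation; the *minimum
   wiring cost* of a group is the smallest edge count $E_{\min}$ at which
   its graph first spans all $p$ nodes in one component (the percolation
   point, found by a union-find scan). Comparing topology across groups
   requires equal density, so every group is binarized at
   $E^\* = \max_g E_{\min}(g)$ — the largest minimum cost. All group
   networks are then fully connected with as few redundant paths as the
   densest bottleneck allows, and the wiring cost $E^\*/\binom{p}{2}$ is
   identical across groups by construction.
3. **Centrality.** Four node-importance measures per network: degree (edge
   count), betweenness (unnormalized Brandes-style shortest-path mediation
   over unordered pairs, fractional across tied geodesics), closeness in
   the Wasserman–Faust component-rescaled form
   $\frac{r-1}{p-1}\cdot\frac{r-1}{S(v)}$ (with $r$ the node's component
   size and $S(v)$ its summed geodesic distances, so values stay in
   $[0,1]$ on disconnected graphs), and eigenvector centrality (the
   non-negative principal eigenvector of the full adjacency, unit
   Euclidean norm). A degree-0 node scores 0 on all four measures.
4. **Inference.** Per node and measure, the between-group difference of
   centrality is referred to a permutation null: subjects' group labels are
   reshuffled (covariates travel with their subjects), both
   partial-correlation matrices and top-$E^\*$ networks are rebuilt, and
   the centralities recomputed — 10,000 reshuffles at full scale. Two-sided
   p-values use the add-one rule $p = (1 + \#\{|\Delta_{perm}| \ge
   |\Delta_{obs}|\})/(B + 1)$. A node is declared different only when at
   least three of the four measures have $p \le 0.05$ (two of four for
   regions flagged a priori). Reliability is assessed by leave-one-subject-out
   jackknife envelopes ($\widehat{SE} = \sqrt{\frac{n-1}{n}\sum_i
   (\theta_{(i)} - \bar\theta)^2}$, 99% interval $\bar\theta \pm 2.576\,
   \widehat{SE}$); observed values outside their envelope are flagged, not
   removed.

Before any of this, regions whose thickness *variance* differs between any
pair of groups (two-sample F test at the 1% level) are excluded globally,
so group differences in connectivity cannot be driven by unequal dispersion.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `variance_alpha` | 0.01 | level of the equal-variance F screen; 0 disables it |
| `perm_alpha` | 0.05 | per-measure level entering the 3-of-4 rule |
| `n_perm` | 10000 | permutation replicates per group pair |
| `jackknife_z` | 2.576 | normal quantile for the 99% reliability envelope |
| `cost_override` | — | wiring cost in (0, 1] replacing the matched-minimum rule |
| `recompute_cost_in_permutations` | `FALSE` | re-match $E^\*$ inside every replicate |

Permutation replicates reuse the *observed* matched edge count by default:
holding the cost fixed makes the null target centrality reconfiguration
rather than density changes. Recomputing the matched cost per replicate is
available but changes the null hypothesis subtly and roughly doubles the
cost of each replicate. Replicates whose pseudo-groups cannot supply
$E^\*$ positive edges are redrawn (capped at $10\times$ `n_perm` draws) so
the null sample size stays fixed; the redraw count is recorded on the
result.

The decision rule's nominal product bound ($0.05^3 = 1.25\times10^{-4}$,
`chance_bound()`) assumes independent measures. The four centralities are
computed from the same edge set and are strongly correlated, so the bound
is a reporting convention, not an attained error rate: on null synthetic
cohorts we measure a 3-of-4 decision rate of roughly 1–2% — about three
times more conservative than any single measure at 5%, but far above the
product bound.

## The synthetic-cohort generator

No clinical MRI data ship with the package; `generate_cohort()` produces
cohorts with the statistical structure the analysis assumes. For subject
$s$ in group $g$:

$$t_{s,j} = \mu_j + \textstyle\sum_k \beta_{k,j}\, c_{s,k} +
\text{planted}_{s,j} + \varepsilon_{s,j}, \qquad
\varepsilon \sim \mathcal N(0, \sigma^2)$$

The planted structure is a *star*: each member $m$ of the planted set $M$
carries an independent latent factor $f_{s,m}$ contributing $\lambda
f_{s,m}$ to region $m$, and the hub receives $\lambda \sum_m f_{s,m} /
\sqrt{|M|}$. Asymptotically $\operatorname{var}(\text{hub}) = \sigma^2 +
\lambda^2$ and $\operatorname{cov}(\text{hub}, m) = \lambda^2/\sqrt{|M|}$
while members stay mutually uncorrelated — exactly one node becomes a
correlation hub, giving a clean recovery target for degree and
betweenness. A star rather than a clique was chosen for that reason.
`generate_null_cohort()` plants the *same* star in every group, so all
between-group topology differences are null by construction — the
calibration ground truth for the permutation machinery.

Defaults mirror a three-group veteran cohort: 181/35/101 subjects
(trauma-exposed controls, remitted and current patients), 148 regions (74
per hemisphere, as in the Destrieux parcellation), eight covariates with
sex and medication flag binary, baseline thickness 2.5 mm, noise SD
0.15 mm, age $\sim \mathcal N(40, 10)$ (matching the cohort's published
demographics), and small default covariate effects (−0.005 mm per year of
age, +0.02 mm for sex) of the sign and order reported for these nuisance
variables. Simulation studies in the test suite override $\lambda = \sigma
= 1$, at which scale thickness values are no longer positive
millimetres — the generator is then operating in arbitrary units, which the
correlation-based pipeline never notices. File ingestion
(`read_thickness_table()`) still enforces positive values, since there the
units are physical.

What the generator does *not* emulate: scanner/site effects, spatially
autocorrelated parcellation noise, heavy-tailed or skewed thickness
distributions, subject motion artifacts, or covariate–group confounding.
Passing tests therefore demonstrate the machinery's correctness and
calibration under a Gaussian factor model, not robustness to everything
real morphometry can do.

## Numerical conventions

* **Tie-breaking.** Edges with exactly equal partial correlation are
  ordered by lexicographic node-pair index, making thresholding
  deterministic across platforms.
* **Eigenvector centrality.** Dense symmetric eigen-decomposition with a
  non-negative sign fix; when the two leading eigenvalues are within
  $10^{-8}$ (e.g. two isomorphic components tie for spectral radius) the
  package switches to a deterministic power iteration on $A + I$ from the
  uniform vector, which converges to the projection of the uniform vector
  onto the leading eigenspace. Non-convergence raises an error rather than
  returning a silent approximation. Entries below zero by rounding are
  clamped and the vector renormalized.
* **Permutation symmetry.** Group pairs are canonicalized to lexicographic
  order internally, so swapping the pair negates every observed difference
  bit-for-bit and leaves every p-value unchanged under the same seed.
* **Seeds.** One master seed; each pairwise comparison derives a substream
  by a fixed prime offset, kept below $2^{31}$.
* **Degenerate inputs.** Zero-variance residual columns, rank-deficient
  covariate designs, unconnectable positive-edge graphs, and infeasible
  edge counts are hard errors with the offending region/replicate named.
  Missing covariate values are rejected, never imputed.

## Design choices on open questions

* The estimator behind "partial correlation" is residualize-then-correlate
  (OLS on an intercept plus covariates, then Pearson), the standard
  definition given controls and exactly reproducible.
* Cost matching is done in integer edge counts, not real-valued costs,
  avoiding rounding ambiguity in "equal number of edges".
* The variance screen excludes a region if *any* group pair fails at the
  1% level, with no multiple-testing correction — the screen is a global
  pre-filter, not an inference.
* The 99% jackknife interval is the normal-quantile construction
  $\bar\theta \pm 2.576\,\widehat{SE}$.
* Whether published wiring costs refer to the pre- or post-screening
  region count is ambiguous in the literature this design follows; the
  package computes costs after screening and records $p$ in every report.

## Problem sizes used by the test suite

The full-scale analysis (10,000 permutations, 148 regions) is what the
exported functions default to; the automated checks run the same code at
reduced scale, chosen as the smallest sizes at which the statistical
properties are identifiable:

* oracle equivalence: all 995 connected graphs on ≤ 7 nodes (graph atlas)
  plus 500 random graphs on ≤ 30 nodes, against pure-R brute-force oracles;
* percolation bottleneck: 200 random 15-region partial-correlation
  matrices against an exhaustive connectivity scan;
* null calibration: 200 null cohorts (p = 20, n = 50/group, shared star
  λ = 1) × 200 permutations; the mean per node-measure rejection rate at
  α = 0.05 is required to sit inside the exact binomial 99% interval for
  200 trials. The mean across the 80 node-measure cells is used because a
  per-cell assertion over 80 dependent 99% intervals would fail by chance
  in a large fraction of runs even for a perfectly calibrated test;
* planted-hub recovery: 50 seeds of (λ = 1, σ = 1, |M| = 6, n = 80/group,
  p = 30) × 500 permutations;
* jackknife coverage: 10 two-group cohorts at n = 60, p = 30.

## Known limitations

* **Permutation power under planted covariance.** Label permutation pools
  planted subjects into both pseudo-groups, so the null distribution at a
  genuinely different node carries the hub signal at roughly half
  strength. This inflates null |Δ| exactly where the alternative lives and
  caps single-hub detection power well below what independence heuristics
  suggest (measured ≈ 0.1–0.3 at λ = σ = 1, n = 80/group, and only ≈ 0.5
  by n = 400). This is a property of group-level network permutation
  itself, not of the implementation.
* **Variance screen vs. planted effects.** The star model raises planted
  regions' variance ($\lambda^2 + \sigma^2$ vs $\sigma^2$), so a strong
  planted effect in one group is exactly what the equal-variance screen
  removes. End-to-end recovery demonstrations therefore disable the screen
  (`variance_alpha = 0`); on real data, where group covariance differences
  need not come with variance differences, the screen and the inference
  are complementary rather than antagonistic.
* **Jackknife on rank-degenerate networks.** When many candidate edges
  have near-identical partial correlations (pure noise), leave-one-out
  resampling flips the retained edge set and centrality becomes a
  non-smooth functional; the jackknife SE then need not shrink with n.
  With structured covariance the envelopes behave classically.
* The group-level construction yields no subject-level networks, so no
  individual-differences analysis is possible; only positive partial
  correlations are modelled; and no correction across the p regions is
  applied beyond the multi-measure consensus rule.
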