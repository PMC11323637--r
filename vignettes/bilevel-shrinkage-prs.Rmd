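---
title: "Bilevel continuous shrinkage for annotation-aware polygenic risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilevel continuous shrinkage for annotation-aware polygenic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsbils)
```

## The model

A polygenic risk score (PRS) predicts an individual's genetic liability as a
weighted sum of allele counts. Given standardized genotypes $G$ ($N \times M$)
and a standardized phenotype $y$, the underlying regression is

$$ y = G\beta + \epsilon, \qquad \epsilon \sim MVN(0, \sigma^2 I_N), \qquad
p(\sigma^2) \propto \sigma^{-2}. $$

Only a small fraction of variants is typically causal, and that fraction — and
the share of heritability — differs across functional annotation categories
(gene-based classes, pathways). The package therefore places a *bilevel*
global–local continuous shrinkage prior on the effects: one shrinkage scale
per variant and one per annotation group,

$$ \beta \mid \sigma^2, \delta^2, \lambda^2 \sim
   MVN\!\left(0, \tfrac{\sigma^2}{N} V_\delta V_\lambda\right), \qquad
   \delta_k \sim C^+(0,1), \qquad \lambda_j \sim C^+(0,1), $$

with $V_\delta = diag\{\delta^2_{A_1}, \dots\}$ the group scales indexed by
each variant's annotation $A_j$ and $V_\lambda = diag\{\lambda_1^2, \dots\}$
the local scales. The heavy-tailed half-Cauchy prior shrinks noise hard while
letting genuine signals escape; the group level lets an annotation class that
carries most of the heritability be shrunk less as a whole.

Individual-level data are not required: with marginal GWAS effects
$\hat\beta = G^T y / N$ (on the standardized scale, $z/\sqrt{N}$) and a
block-diagonal LD matrix $D = G^T G / N$ estimated from an external reference
panel, the effect-size conditional becomes

$$ \beta \mid \cdot \sim MVN\!\left(\tfrac{N}{\sigma^2}\Sigma\hat\beta,
   \Sigma\right), \qquad
   \Sigma = \tfrac{\sigma^2}{N}\left[D + (V_\delta V_\lambda)^{-1}\right]^{-1}, $$

whose mean $[D + (V_\delta V_\lambda)^{-1}]^{-1}\hat\beta$ does not depend on
$\sigma^2$.

## Gibbs sampling

The half-Cauchy is a scale mixture of inverse-gamma distributions: if
$x^2 \mid a \sim IG(\tfrac12, 1/a)$ and $a \sim IG(\tfrac12, 1)$ then
$x \sim C^+(0,1)$. `rhalfcauchy_mixture()` exposes the composition and the
test suite verifies it against the $C^+(0,1)$ CDF by a Kolmogorov–Smirnov
test. With that representation every update is conjugate:

* $\sigma^2 \mid \cdot \sim IG\big(\tfrac{N+M'}{2},
  \tfrac{N}{2}\{1 - 2\beta^T\hat\beta + \beta^T[D + (V_\delta V_\lambda)^{-1}]\beta\}\big)$;
* $\delta_k^2 \mid \cdot \sim IG\big(\tfrac{M_k+1}{2},
  \sum_{j: A_j = k} \tfrac{N\beta_j^2}{2\sigma^2\lambda_j^2} + \tfrac{1}{t_k}\big)$,
  $\quad t_k \mid \cdot \sim IG(1, \delta_k^{-2} + 1)$;
* $\lambda_j^2 \mid \cdot \sim IG\big(1,
  \tfrac{N\beta_j^2}{2\sigma^2} + \tfrac{1}{c_j}\big)$,
  $\quad c_j \mid \cdot \sim IG(1, \lambda_j^{-2} + 1)$.

The local-scale update conditions on the absolute marginal signal
$N\beta_j^2/(2\sigma^2)$; the group scales act on $\beta$ through the prior
covariance rather than inside the local update's quadratic term. This is the
convention of the continuous-shrinkage PRS lineage this sampler extends, and
it keeps the division of labour clean: $\lambda_j$ tracks how strong variant
$j$'s signal is, $\delta_k$ tracks how much of it group $k$ accumulates.

One sweep updates, in this fixed order with a single seeded RNG stream:
$\beta$ (jointly per LD block, sequentially across blocks — exact because $D$
is block-diagonal), then $\sigma^2$, then $\{\delta_k^2, t_k\}$, then
$\{\lambda_j^2, c_j\}$, then (auto mode only) $\tau^2$. Defaults are 1,000
iterations, 500 burn-in, thinning 5, i.e. 100 retained draws; posterior means
are averaged over retained draws.

### Modes

* **`bils`** — the bilevel model above. Overlapping annotations are handled
  by the $M'$ copy expansion: a variant belonging to several groups
  contributes one *copy* per membership, each with its own effect, local
  scale, and group assignment; $\sigma^2$ uses $M'$ in its shape, and the
  group-wise scores sum each group's own copies. `bils_overlap` names the
  same code path.
* **`prscs_auto`** — the single-group benchmark: annotations are collapsed,
  the one group scale plays the role of a global shrinkage parameter, and an
  additional global scale $\tau^2$ with its own half-Cauchy prior is sampled
  by the same mixture trick (`fix_tau = TRUE` freezes it at 1). The local
  prior generalizes to a gamma-gamma family with shapes $(a_0, b_0)$; the
  default $(0.5, 1)$ is the half-Cauchy case and *shares the bilevel code
  path verbatim*, so a one-group bilevel chain and an auto chain with
  $\tau^2$ fixed are bit-for-bit identical under the same seed — the test
  suite asserts this. Other $(a_0, b_0)$ use generalized-inverse-Gaussian
  conditionals; the GIG sampler (`rgig()`, a Devroye-style log-concave
  rejection method) is validated against Bessel-function moments.

## Numerical choices

* **Shrinkage-product cap.** The per-copy prior variance is
  $\tfrac{\sigma^2}{N}\psi_j$ with $\psi_j = \delta^2\lambda^2\tau^2$ clipped
  to $[10^{-12}, 1]$ (`clip_psi`, configurable). The upper cap matters: when
  the variant count is comparable to the GWAS sample size, an unbounded
  product admits an absorbing degenerate mode — shrinkage vanishes,
  $\hat\beta^T[D+\Psi^{-1}]^{-1}\hat\beta$ exceeds 1, the $\sigma^2$ scale
  turns negative, $\sigma^2$ collapses to its floor and the scales explode.
  Capping the product at 1 (prior effect variance at most $\sigma^2/N$) is
  the standard remedy in this model family and removed the mode entirely in
  our experiments.
* **$\sigma^2$ guard.** The data part of the $\sigma^2$ scale can still turn
  non-positive because $\hat\beta$ and $D$ come from different samples; the
  draw then falls back to $\max$ of the prior quadratic form
  $\tfrac{N}{2}\beta^T\Psi^{-1}\beta$ and a floor $10^{-8}N/2$. Falls are
  counted and a warning is raised if more than 1% of iterations clamp.
* **Factorization.** Block Cholesky factors get escalating jitter
  ($10^{-10}$ up to $10^{-6}$) if a reference block is numerically
  indefinite; an optional ridge $(1-\epsilon)D + \epsilon I$ is available for
  small reference panels (default $\epsilon = 0$).
* **Floors.** $\delta^2$ and $\lambda^2$ draws are floored at $10^{-12}$.
* **Binning tie-break.** The ranked-bin comparator sorts by $|$effect$|$
  descending with ties broken by variant order, and closes a bin when the
  running sum of squares reaches the next multiple of total$/L$ (with a
  $10^{-12}$-relative tolerance against float error at exact boundaries).

## Scoring and evaluation

Group-wise scores $PRS_k(i) = \sum_{j: A_j = k} G_{ij}\tilde\beta_{j,k}$ are
combined as $\sum_k \alpha_k PRS_k$ (plus $\gamma \times$ a conventional PRS
for the hybrid variant). The weights are fitted by ordinary least squares
with an intercept under tenfold cross-validation on individual-level
validation data; each fold's held-out tenth receives predictions from the
other nine tenths, reported $\alpha, \gamma$ are across-fold averages, and
binary phenotypes use the same linear working model since only the ranking
matters for AUC. No sign constraints are imposed — the catch-all group
participates like any other. Both the fold-averaged weights and the per-fold
coefficients are returned.

Metrics: AUC is the midrank Mann–Whitney statistic (cross-checked against an
independent ROC implementation in the tests); $R^2$ is the squared Pearson
correlation for quantitative traits and Efron's pseudo-$R^2$,
$1 - \sum(y_i - \hat p_i)^2 / \sum(y_i - \bar y)^2$, for binary ones.
Quantitative phenotypes are binarized for AUC at the top decile by default,
or at an explicit threshold.

The ranked-bin comparator takes per-SNP heritabilities $\sigma_j^2$ as input
(true simulator values in the synthetic studies), calibrates its normalizing
constant by $c\sum_j \sigma_j^2 = h^2$, forms posterior means
$[ND + \tfrac1c\,diag(1/\sigma_j^2)]^{-1}N\hat\beta$ block-wise, ranks them
into $L = 40$ bins of approximately equal sum of squared effects, and reuses
the same cross-validated weighting.

## The synthetic-data engine

`simulate_study()` builds a complete replicate: a shared variant model (MAFs
uniform on $[0.05, 0.5]$, fixed blocks), three disjoint panels (GWAS,
test, LD reference), true effects, phenotypes, marginal summary statistics,
and the annotation map.

* **Genotypes.** Within blocks of `block_size` variants, two latent AR(1)
  Gaussian haplotypes per individual (neighbour correlation $\rho = 0.5$)
  are thresholded at the MAF quantile and summed to Hardy–Weinberg dosages;
  blocks are independent. This emulates local LD decay. It does *not*
  emulate long-range LD, MAF-LD coupling, relatedness, or ascertainment —
  conclusions from passing tests are about the method's behaviour under
  clean block LD, not about any particular cohort.
* **Effects.** Point-Normal per group: causal with probability $p_k$,
  effects $N(0, q_k h^2 / (p_k M_k))$, so group $k$'s expected total effect
  variance equals its heritability share $q_k h^2$ and groups with
  $q_k = 0$ are entirely null. Group labels are randomly interleaved across
  the genome.
* **Phenotypes.** $y = G\beta + \epsilon$ with the error orthogonalized
  against the genetic value and scaled so the in-sample genetic variance
  share equals $h^2 = 0.7$ *exactly*, then re-standardized.
* **Summary statistics.** Marginal least squares on the standardized GWAS
  panel, $\hat\beta = G^T y/N$.
* **Overlap patterns.** Extra memberships are added so chosen group pairs
  reach a target intersection-over-union (pattern I: among the
  zero-heritability groups; pattern II: between the two heritability-carrying
  groups); with pair target $\theta$ the construction shares
  $\lceil\theta(M_{k_1}+M_{k_2})\rceil$ of $k_2$'s variants into $k_1$,
  feasible when $\theta \le M_{k_2}/(M_{k_1}+M_{k_2})$. Defaults
  $\theta_{high} = 0.5$, $\theta_{low} = 0$. Achieved IOUs are reported.
* **Misclassification.** Uniformly random observed groups, truth retained
  for effect generation.

### Scales

The packaged grid of seven settings covers four-group designs with causal
fractions $(0.5, 1, 1.5, 2)\%$ and heritability shares from $(0,0,10,90)\%$
to uniform, a ten-group design with shares $(0^{\times 8}, 10, 90)\%$, and
the two overlap variants. Two problem sizes are built in:

* **desk** — $M = 2{,}000$ variants (group sizes in the full design's
  proportions), $N_{sumstat} = 2{,}000$, $N_{test} = 1{,}000$, LD reference
  of 500 (the size of a typical public reference panel's continental
  subset), blocks of 50. This is the scale the test suite and the
  acceptance script run at; a full two-setting, ten-replicate benchmark
  takes a few minutes.
* **full** — $M = 125{,}000$, $N_{sumstat} = 50{,}000$, $N_{test} = 24{,}000$,
  blocks of 500. Chains at this scale take hours and are not exercised by
  the tests; the presets exist so the full study is one flag away.

Validation folds for $\alpha$ are carved from the test panel by tenfold
cross-validation; no third individual-level panel is drawn.

### Designing the group-scale recovery experiment

A reduced-scale check that the sampler ranks $\delta^2$ correctly (the
dominant-heritability group above the zero-heritability groups) must decide
what to hold fixed when scaling $M$ down. Group-scale identifiability is
governed by the *number* of causal variants in a group, not their fraction:
each causal variant contributes a bounded increment to the $\delta_k^2$
conditional once its local scale has absorbed the effect magnitude, so a
group with ~4 causals (the fraction-preserving scale-down of the sparse
design to $M = 2{,}000$) cannot be separated reliably from null groups —
empirically the ordering holds in only ~6 of 10 replicates, stable across
chain lengths, sampler seeds and exact LD, while the full design carries
~250 causals in that group. The recovery experiment therefore preserves the
causal-count order of magnitude: it keeps $K = 4$, $q = (0, 0, 10, 90)\%$
and scales the causal fractions tenfold (~40–60 causals in the
heritability-carrying groups), under which the ordering holds in 10 of 10
replicates. The benchmark settings themselves keep the original fractions.

## Limitations

* The desk-scale benchmark shows the *ordering* of methods, not the absolute
  AUCs of any real trait; absolute values at $M = 2{,}000$ are far higher
  than genome-wide values because per-variant signal is concentrated.
* $\delta^2$ point estimates are weakly identified when a group holds only a
  handful of causal variants (see above); interpret group scales
  comparatively and at adequate causal counts.
* The sampler assumes one GWAS sample size $N$ for all variants and
  block-diagonal LD; long-range LD and per-variant $N$ heterogeneity are out
  of scope.
* Binary traits are scored with a linear working model; covariate-adjusted
  evaluation is not implemented.
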